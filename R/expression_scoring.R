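#' Reads per kilobase per million mapped reads (RPKM)
#'
#' `count / ((length/1000) * (library_size/1e6))`. Vectorised over genes.
#'
#' @param counts Non-negative read counts.
#' @param gene_lengths_bp Gene lengths in base pairs (> 0).
#' @param library_size Total mapped reads (> 0).
#' @return RPKM values.
#' @export
#' @examples
#' rpkm(1000, 1000, 1e6) # 1000
rpkm <- function(counts, gene_lengths_bp, library_size) {
  stopifnot(all(gene_lengths_bp > 0), length(library_size) == 1L,
            library_size > 0, all(counts >= 0))
  counts / ((gene_lengths_bp / 1000) * (library_size / 1e6))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic FDR step-up: order raw p-values, multiply by `m / rank`, enforce
#' monotonicity from the largest p downwards, cap at 1. Implemented here
#' (rather than delegated) so tests can check it against an independent
#' enumeration of the step-up procedure.
#'
#' @param p Raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p, decreasing = TRUE)
  pmin(1, cummin(m / seq(m, 1) * p[o]))[order(o)]
}

#' Per-gene differential expression between two replicate groups
#'
#' Two-sided two-sample Student's t-test (equal variances) per gene, with
#' Benjamini-Hochberg adjustment across genes. Fold change is the ratio of
#' group means on the linear scale, reported as log2. Convention for
#' degenerate genes: both groups constant and equal gives p = 1; both
#' constant but different gives p = 0 (perfect separation).
#'
#' @param group_a,group_b Numeric matrices, genes x replicates (>= 2
#'   replicates each), identical row sets; linear-scale expression.
#' @return data.frame: gene, log2_fc (B vs A), p, p_adj.
#' @export
differential_expression <- function(group_a, group_b) {
  stopifnot(is.matrix(group_a), is.matrix(group_b),
            nrow(group_a) == nrow(group_b),
            ncol(group_a) >= 2L, ncol(group_b) >= 2L)
  genes <- rownames(group_a)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(group_a)))
  n <- nrow(group_a)
  p <- numeric(n)
  lfc <- numeric(n)
  for (g in seq_len(n)) {
    a <- group_a[g, ]; b <- group_b[g, ]
    lfc[g] <- log2(mean(b) / mean(a))
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      p[g] <- if (mean(a) == mean(b)) 1 else 0
    } else {
      p[g] <- stats::t.test(a, b, var.equal = TRUE)$p.value
    }
  }
  data.frame(gene = genes, log2_fc = lfc, p = p, p_adj = bh_adjust(p),
             stringsAsFactors = FALSE)
}

#' Filter a geneset by reference-condition induction
#'
#' Keeps only genes whose fold change in the reference (global stressor)
#' condition is strictly greater than `min_fold`; genes the stressor does
#' not robustly induce carry no signal about arm-selective activation.
#'
#' @param expr Linear fold-change matrix (genes x conditions).
#' @param genes Gene ids of the geneset.
#' @param reference Reference condition column name (default `"Tg"`).
#' @param min_fold Strict induction floor (default 1.5).
#' @return Character vector of retained gene ids (possibly empty).
#' @export
reference_filter <- function(expr, genes, reference = "Tg",
                             min_fold = 1.5) {
  if (!reference %in% colnames(expr)) {
    stop("reference condition '", reference, "' not in expression table",
         call. = FALSE)
  }
  genes <- intersect(genes, rownames(expr))
  genes[expr[genes, reference] > min_fold]
}

#' Reference-normalised induction (percent of reference)
#'
#' On the default log scale: `100 * log(fc_compound) / log(fc_reference)`.
#' The result is base-invariant (any log base gives the same percent) and
#' may exceed 100 or go negative. The linear alternative
#' (`100 * (fc_compound - 1) / (fc_reference - 1)`, induction as fold
#' increase over baseline) is available via `scale = "linear"`.
#'
#' @param fc_compound Linear fold change under the compound (> 0).
#' @param fc_reference Linear fold change under the reference; must exceed
#'   the reference filter floor, hence > 1.
#' @param scale `"log"` (default) or `"linear"`.
#' @return Percent of reference induction (vectorised).
#' @export
#' @examples
#' tg_normalized_induction(2, 4) # 50
tg_normalized_induction <- function(fc_compound, fc_reference,
                                    scale = c("log", "linear")) {
  scale <- match.arg(scale)
  if (any(fc_compound <= 0)) {
    stop("fold changes must be > 0 on the linear scale", call. = FALSE)
  }
  if (any(fc_reference <= 1)) {
    stop("reference fold change must be > 1 (apply reference_filter first)",
         call. = FALSE)
  }
  if (scale == "log") {
    100 * log(fc_compound) / log(fc_reference)
  } else {
    100 * (fc_compound - 1) / (fc_reference - 1)
  }
}

#' Geneset activation score for one compound
#'
#' Applies the reference filter to the geneset, normalises each retained
#' gene's induction to the reference, and summarises the per-gene percents
#' by median (robust) and mean (also reported, as average-fold-change
#' summaries are common). The per-gene distribution is retained for the
#' statistical classification step.
#'
#' @param expr Linear fold-change matrix (genes x conditions).
#' @param genesets A [geneset_catalog()].
#' @param set_name Geneset to score.
#' @param compound Condition column to score.
#' @param reference Reference condition (default `"Tg"`).
#' @param min_fold Reference filter floor (default 1.5).
#' @param min_genes Minimum retained genes for a usable score (default 3).
#' @param scale Passed to [tg_normalized_induction()].
#' @return Object of class `geneset_score`: list(compound, geneset, genes,
#'   values, median, mean, n, usable).
#' @export
geneset_score <- function(expr, genesets, set_name, compound,
                          reference = "Tg", min_fold = 1.5,
                          min_genes = 3L, scale = "log") {
  stopifnot(inherits(genesets, "geneset_catalog"),
            set_name %in% names(genesets))
  if (!compound %in% colnames(expr)) {
    stop("condition '", compound, "' not in expression table", call. = FALSE)
  }
  keep <- reference_filter(expr, genesets[[set_name]], reference, min_fold)
  vals <- if (length(keep)) {
    tg_normalized_induction(expr[keep, compound], expr[keep, reference],
                            scale = scale)
  } else numeric()
  structure(list(compound = compound, geneset = set_name, genes = keep,
                 values = vals,
                 median = if (length(vals)) stats::median(vals) else NA_real_,
                 mean = if (length(vals)) mean(vals) else NA_real_,
                 n = length(vals),
                 usable = length(vals) >= min_genes),
            class = "geneset_score")
}

#' Classify a compound's UPR activation profile
#'
#' Decision rule over the three UPR-arm geneset score distributions
#' (per-gene percents of reference):
#'
#' * `preferential_ATF6` — one-way ANOVA across the three sets is
#'   significant at `alpha`, both one-sided unpaired t-tests (ATF6 greater
#'   than XBP1s; ATF6 greater than PERK) are significant at `alpha`, and
#'   the ATF6 summary is at least `activity_floor`;
#' * `global` — otherwise, if all three summaries are at least
#'   `global_floor`;
#' * `weak_none` — everything else (including degenerate all-identical
#'   scores, with a warning).
#'
#' @param scores Named list of three [geneset_score()] objects
#'   (`ATF6`, `XBP1s`, `PERK`), each with >= 2 genes.
#' @param alpha Significance level (default 0.05).
#' @param global_floor Percent-of-reference floor for a global call
#'   (default 25).
#' @param activity_floor Minimum ATF6 summary for a preferential call;
#'   also the ceiling under which all-arm scores mean "no activity"
#'   (default 10).
#' @param summary `"median"` (default) or `"mean"` summary statistic.
#' @return List of class `upr_profile_call`: compound, call, anova_p,
#'   p_atf6_vs_xbp1, p_atf6_vs_perk, summaries.
#' @export
classify_upr_profile <- function(scores, alpha = 0.05, global_floor = 25,
                                 activity_floor = 10,
                                 summary = c("median", "mean")) {
  summary <- match.arg(summary)
  need <- c("ATF6", "XBP1s", "PERK")
  stopifnot(all(need %in% names(scores)))
  scores <- scores[need]
  if (any(vapply(scores, function(s) s$n, integer(1)) < 2L)) {
    stop("each geneset score needs >= 2 retained genes", call. = FALSE)
  }
  vals <- lapply(scores, `[[`, "values")
  summ <- vapply(scores, `[[`, numeric(1), summary)
  all_vals <- unlist(vals, use.names = FALSE)

  # essentially-constant scores (e.g. the reference scored against itself,
  # exactly 100 everywhere): no distributional test is possible, so decide
  # on the summaries alone - high flat scores are global activation, low
  # flat scores are no activity
  degenerate <- diff(range(all_vals)) <=
    1e-10 * max(1, mean(abs(all_vals)))
  anova_p <- p_xbp1 <- p_perk <- NA_real_
  if (degenerate) {
    if (all(summ >= global_floor)) {
      call <- "global"
    } else {
      warning("degenerate geneset scores (no variance); calling weak_none",
              call. = FALSE)
      call <- "weak_none"
    }
  } else {
    grp <- factor(rep(need, lengths(vals)))
    anova_p <- stats::oneway.test(all_vals ~ grp,
                                  var.equal = TRUE)$p.value
    one_sided <- function(a, b) {
      if (isTRUE(all.equal(stats::var(a) + stats::var(b), 0))) {
        return(if (mean(a) > mean(b)) 0 else 1)
      }
      tryCatch(stats::t.test(a, b, alternative = "greater")$p.value,
               error = function(e) if (mean(a) > mean(b)) 0 else 1)
    }
    p_xbp1 <- one_sided(vals$ATF6, vals$XBP1s)
    p_perk <- one_sided(vals$ATF6, vals$PERK)
    if (!is.na(anova_p) && anova_p < alpha &&
        p_xbp1 < alpha && p_perk < alpha &&
        summ[["ATF6"]] >= activity_floor) {
      call <- "preferential_ATF6"
    } else if (all(summ >= global_floor)) {
      call <- "global"
    } else {
      call <- "weak_none"
    }
  }
  structure(list(compound = scores$ATF6$compound, call = call,
                 anova_p = anova_p,
                 p_atf6_vs_xbp1 = p_xbp1, p_atf6_vs_perk = p_perk,
                 summaries = summ),
            class = "upr_profile_call")
}

#' Score and classify every compound condition in an expression table
#'
#' Convenience wrapper: computes the three UPR geneset scores per compound
#' and classifies each profile.
#'
#' @param expr Linear fold-change matrix (genes x conditions).
#' @param genesets A [geneset_catalog()].
#' @param compounds Condition columns to classify (default: all except the
#'   reference).
#' @inheritParams classify_upr_profile
#' @inheritParams geneset_score
#' @return data.frame: compound, call, anova_p, p_atf6_vs_xbp1,
#'   p_atf6_vs_perk, score_ATF6, score_XBP1s, score_PERK.
#' @export
classify_all_profiles <- function(expr, genesets,
                                  compounds = setdiff(colnames(expr), "Tg"),
                                  reference = "Tg", min_fold = 1.5,
                                  alpha = 0.05, global_floor = 25,
                                  activity_floor = 10, scale = "log") {
  rows <- lapply(compounds, function(cmp) {
    sc <- lapply(c(ATF6 = "ATF6", XBP1s = "XBP1s", PERK = "PERK"),
                 function(s) geneset_score(expr, genesets, s, cmp,
                                           reference = reference,
                                           min_fold = min_fold,
                                           scale = scale))
    cl <- classify_upr_profile(sc, alpha = alpha,
                               global_floor = global_floor,
                               activity_floor = activity_floor)
    data.frame(compound = cmp, call = cl$call, anova_p = cl$anova_p,
               p_atf6_vs_xbp1 = cl$p_atf6_vs_xbp1,
               p_atf6_vs_perk = cl$p_atf6_vs_perk,
               score_ATF6 = cl$summaries[["ATF6"]],
               score_XBP1s = cl$summaries[["XBP1s"]],
               score_PERK = cl$summaries[["PERK"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Hierarchical clustering of compound expression profiles
#'
#' Ward's method (`hclust` `"ward.D2"`, the Ward criterion for unsquared
#' Euclidean input) on Euclidean distances between log2-transformed
#' condition profiles. Ties in merge order follow `hclust`'s deterministic
#' input-order convention, so permuting compounds can relabel the tree but
#' leaves the multiset of merge heights unchanged.
#'
#' @param expr Linear fold-change matrix (genes x conditions); conditions
#'   are clustered.
#' @param k Optional number of flat clusters to cut.
#' @param log2_transform Log2-transform before clustering (default TRUE;
#'   set FALSE if `expr` is already on a log scale).
#' @return List: `hclust` (the tree), `labels` (named cluster ids, or NULL
#'   if `k` is NULL).
#' @export
cluster_profiles <- function(expr, k = NULL, log2_transform = TRUE) {
  m <- t(if (log2_transform) log2(expr) else expr)
  if (anyNA(m)) stop("expression matrix contains missing values",
                     call. = FALSE)
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "ward.D2")
  labels <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  list(hclust = hc, labels = labels)
}
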