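#' Triage configuration
#'
#' Thresholds for the staged hit-calling funnel. Defaults follow the screen
#' this package models: primary cutoff 25.1% activation, confirmation at 3
#' SD above DMSO, 2-fold ERSE/XBP1 selectivity. All comparisons are strict
#' (`>`), so boundary values fail.
#'
#' @param primary_cutoff Percent activation above which a single-point
#'   primary measurement is a hit.
#' @param confirmation_sd_mult SD multiplier for the DMSO-based
#'   confirmation cutoff.
#' @param selectivity_fold Fold by which ERSE activation must exceed XBP1
#'   activation for a selectivity call.
#' @param blacklist Character vector of compound ids to remove after the
#'   primary stage (e.g. known heat-shock-response activators).
#' @return Object of class `triage_config`.
#' @export
triage_config <- function(primary_cutoff = 25.1,
                          confirmation_sd_mult = 3,
                          selectivity_fold = 2,
                          blacklist = character()) {
  stopifnot(primary_cutoff > 0, confirmation_sd_mult >= 0,
            selectivity_fold > 0)
  structure(list(primary_cutoff = primary_cutoff,
                 confirmation_sd_mult = confirmation_sd_mult,
                 selectivity_fold = selectivity_fold,
                 blacklist = as.character(blacklist)),
            class = "triage_config")
}

#' Assemble per-compound records from the three screening stages
#'
#' Joins the single-point primary activations with replicate confirmation
#' (ERSE-FLuc) and counterscreen (XBP1-RLuc) tables into one record table,
#' summarising replicates by mean, SD and count. Compounds absent from a
#' stage get NA summaries and simply cannot progress past that stage.
#'
#' @param primary data.frame with `compound_id` and `pct_activation`
#'   (the [normalize_plate_set()] output).
#' @param confirmation,counterscreen data.frames with `compound_id`,
#'   `replicate`, `pct`.
#' @return data.frame: compound_id, primary_pct, confirm_mean, confirm_sd,
#'   confirm_n, counter_mean, counter_sd, counter_n, plus all-FALSE flag
#'   columns (primary_hit, blacklisted, confirmed, stringent, selective).
#' @export
build_compound_records <- function(primary, confirmation = NULL,
                                   counterscreen = NULL) {
  stopifnot(all(c("compound_id", "pct_activation") %in% names(primary)))
  rec <- data.frame(compound_id = primary$compound_id,
                    primary_pct = primary$pct_activation,
                    stringsAsFactors = FALSE)
  summarise <- function(tbl) {
    if (is.null(tbl)) {
      return(data.frame(compound_id = character(), m = numeric(),
                        s = numeric(), n = integer()))
    }
    stopifnot(all(c("compound_id", "pct") %in% names(tbl)))
    agg <- split(tbl$pct, tbl$compound_id)
    data.frame(compound_id = names(agg),
               m = vapply(agg, mean, numeric(1)),
               s = vapply(agg, stats::sd, numeric(1)),
               n = lengths(agg), stringsAsFactors = FALSE)
  }
  cf <- summarise(confirmation)
  cs <- summarise(counterscreen)
  i <- match(rec$compound_id, cf$compound_id)
  rec$confirm_mean <- cf$m[i]; rec$confirm_sd <- cf$s[i]
  rec$confirm_n <- cf$n[i]
  j <- match(rec$compound_id, cs$compound_id)
  rec$counter_mean <- cs$m[j]; rec$counter_sd <- cs$s[j]
  rec$counter_n <- cs$n[j]
  rec$primary_hit <- FALSE
  rec$blacklisted <- FALSE
  rec$confirmed <- FALSE
  rec$stringent <- FALSE
  rec$selective <- FALSE
  rec
}

#' Call primary hits at a strict percent-activation cutoff
#'
#' A compound is a primary hit iff its single-point percent activation is
#' strictly greater than the cutoff (a value exactly at the cutoff fails).
#'
#' @param records Record table from [build_compound_records()].
#' @param cutoff Percent cutoff (default 25.1).
#' @return `records` with `primary_hit` set.
#' @export
call_primary_hits <- function(records, cutoff = 25.1) {
  records$primary_hit <- !is.na(records$primary_pct) &
    records$primary_pct > cutoff
  records
}

#' Remove blacklisted compounds from the funnel
#'
#' Flags blacklisted compounds; they are excluded from every later stage.
#' Blacklist ids absent from the record table are ignored with a warning.
#' The number of removals among current primary hits is attached as
#' attribute `n_removed`.
#'
#' @param records Record table with `primary_hit` set.
#' @param blacklist Character vector of compound ids.
#' @return `records` with `blacklisted` set (and attr `n_removed`).
#' @export
apply_blacklist <- function(records, blacklist = character()) {
  unknown <- setdiff(blacklist, records$compound_id)
  if (length(unknown)) {
    warning(length(unknown), " blacklist id(s) not present in records",
            call. = FALSE)
  }
  records$blacklisted <- records$compound_id %in% blacklist
  attr(records, "n_removed") <- sum(records$blacklisted & records$primary_hit)
  records
}

#' Confirmation cutoff from DMSO control wells
#'
#' `mean(dmso) + sd_mult * sd(dmso)` with the sample SD (n - 1 denominator).
#' With the default multiplier of 3 this is the "3 standard deviations
#' above the DMSO control" rule.
#'
#' @param dmso_pcts Percent activations of >= 2 DMSO wells.
#' @param sd_mult SD multiplier (default 3).
#' @return Percent cutoff.
#' @export
#' @examples
#' confirmation_cutoff(c(-2, -1, 0, 1, 2)) # ~4.743
confirmation_cutoff <- function(dmso_pcts, sd_mult = 3) {
  if (length(dmso_pcts) < 2L) {
    stop("need >= 2 DMSO values for a confirmation cutoff", call. = FALSE)
  }
  mean(dmso_pcts) + sd_mult * stats::sd(dmso_pcts)
}

#' Call confirmed hits from replicate means
#'
#' A compound is confirmed iff it is a primary hit, not blacklisted, and
#' the mean of its confirmation replicates strictly exceeds the cutoff.
#' The funnel invariant (confirmed implies primary hit and not
#' blacklisted) is enforced here, not assumed.
#'
#' @param records Record table with `primary_hit` and `blacklisted` set.
#' @param cutoff Confirmation cutoff (see [confirmation_cutoff()]).
#' @return `records` with `confirmed` set.
#' @export
call_confirmed <- function(records, cutoff) {
  records$confirmed <- records$primary_hit & !records$blacklisted &
    !is.na(records$confirm_mean) & records$confirm_mean > cutoff
  records
}

#' Re-apply primary-screen stringency to confirmed hits
#'
#' Narrows the confirmed list to compounds whose confirmation replicate
#' mean also strictly exceeds the (higher) primary cutoff.
#'
#' @param records Record table with `confirmed` set.
#' @param cutoff Stringent cutoff (default 25.1, the primary cutoff).
#' @return `records` with `stringent` set.
#' @export
apply_stringency <- function(records, cutoff = 25.1) {
  records$stringent <- records$confirmed &
    !is.na(records$confirm_mean) & records$confirm_mean > cutoff
  records
}

#' Dual-reporter selectivity call
#'
#' A compound is ERSE-selective iff its ERSE-FLuc activation strictly
#' exceeds `fold` times its XBP1-RLuc activation. Negative XBP1 values are
#' floored at 0 before the comparison: a compound with ERSE 30% and XBP1
#' -5% is selective (the fold ratio would otherwise be sign-flipped).
#' Vectorised.
#'
#' @param erse_pct,xbp1_pct Percent activations on the same Tg-normalised
#'   scale.
#' @param fold Selectivity fold (default 2).
#' @return Logical vector.
#' @export
#' @examples
#' selectivity_call(63.2, 17.5) # TRUE
#' selectivity_call(68.2, 61.1) # FALSE
selectivity_call <- function(erse_pct, xbp1_pct, fold = 2) {
  stopifnot(fold > 0)
  erse_pct > fold * pmax(xbp1_pct, 0)
}

#' Run the full three-tier triage funnel
#'
#' Applies, in order: primary cutoff, blacklist, confirmation at
#' `mean(DMSO) + k * sd(DMSO)`, stringency re-application of the primary
#' cutoff, and dual-reporter selectivity (only defined for stringent
#' compounds; ERSE = confirmation replicate mean, XBP1 = counterscreen
#' replicate mean). Stage counts are non-increasing by construction.
#'
#' @param records Record table from [build_compound_records()].
#' @param dmso_pcts DMSO percent activations from the confirmation screen.
#' @param config A [triage_config()].
#' @return List of class `triage_report`: `records` (flag trail),
#'   `counts` (named integer vector: screened, primary_hits,
#'   post_blacklist, confirmed, stringent, selective),
#'   `confirmation_cutoff`, `confirmation_rate_pct`
#'   (100 * confirmed / post_blacklist), `n_blacklist_removed`.
#' @export
run_funnel <- function(records, dmso_pcts, config = triage_config()) {
  stopifnot(inherits(config, "triage_config"))
  records <- call_primary_hits(records, config$primary_cutoff)
  records <- apply_blacklist(records, config$blacklist)
  n_removed <- attr(records, "n_removed")
  cut_conf <- confirmation_cutoff(dmso_pcts, config$confirmation_sd_mult)
  records <- call_confirmed(records, cut_conf)
  records <- apply_stringency(records, config$primary_cutoff)
  sel <- records$stringent & !is.na(records$counter_mean) &
    selectivity_call(records$confirm_mean,
                     ifelse(is.na(records$counter_mean), 0,
                            records$counter_mean),
                     config$selectivity_fold)
  records$selective <- sel
  post_blacklist <- sum(records$primary_hit & !records$blacklisted)
  counts <- c(screened = nrow(records),
              primary_hits = sum(records$primary_hit),
              post_blacklist = post_blacklist,
              confirmed = sum(records$confirmed),
              stringent = sum(records$stringent),
              selective = sum(records$selective))
  structure(list(records = records,
                 counts = counts,
                 confirmation_cutoff = cut_conf,
                 confirmation_rate_pct =
                   if (post_blacklist > 0) {
                     100 * counts[["confirmed"]] / post_blacklist
                   } else NA_real_,
                 n_blacklist_removed = n_removed,
                 config = config),
            class = "triage_report")
}

#' @export
print.triage_report <- function(x, ...) {
  cat("Triage funnel report\n")
  cat(sprintf("  %-14s %d\n", names(x$counts), x$counts), sep = "")
  cat(sprintf("  confirmation cutoff: %.2f%%\n", x$confirmation_cutoff))
  if (!is.na(x$confirmation_rate_pct)) {
    cat(sprintf("  confirmation rate:   %.1f%%\n", x$confirmation_rate_pct))
  }
  invisible(x)
}
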