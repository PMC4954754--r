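#' Synthetic screening data with planted ground truth
#'
#' The generators in this file emulate every input table the triage pipeline
#' consumes: raw 1536-well-style luminescence plates, replicate reporter
#' activations, gene-expression fold-change matrices, per-cell nuclear/ER
#' intensity tables, pulse-chase compartment series and dose-response
#' curves. Each generator plants a known truth (compound class, activated
#' fraction, kinetic rates) and returns it alongside the data so downstream
#' modules can be tested by recovery.
#'
#' The distributional shapes are stand-ins: no raw-measurement distributions
#' are published for assays of this kind at this scale, so luminescence noise
#' is modelled as log-normal (positive, multiplicative — typical of
#' plate-reader data and analytically convenient for Z'), per-cell ratios as
#' a two-component log-normal mixture, and percent-scale replicates as
#' Gaussian. See the methods vignette for the rationale behind each default.
#'
#' @name synthetic_data
NULL

#' Simulation configuration for a reporter screen
#'
#' Bundles plate geometry, control placement, noise level and the planted
#' compound-class mixture for [generate_plate_set()] and
#' [generate_replicate_activations()].
#'
#' `class_effects` gives, per class, the true mean percent activation of the
#' ERSE-FLuc (primary/confirmation) and XBP1-RLuc (counterscreen) reporters
#' on the Tg-normalised scale where the high control is 100%.
#'
#' @param n_plates Number of plates.
#' @param wells_per_plate Total wells per plate (controls + compounds).
#' @param n_high_controls,n_low_controls Control wells per plate. High
#'   controls model the global ER stressor (100% activation); low controls
#'   model vehicle (0%).
#' @param high_mean,low_mean True mean raw luminescence of high/low control
#'   wells (arbitrary units); must satisfy `high_mean > low_mean > 0`.
#' @param cv Coefficient of variation of raw luminescence (log-normal noise).
#' @param class_fractions Named fractions over
#'   `c("global", "atf6_preferential", "inactive")`; must sum to 1.
#' @param class_effects Named list mapping each class to
#'   `c(erse = <pct>, xbp1 = <pct>)` true mean activations.
#' @param sd_pct Gaussian SD (percent points) of replicate percent-activation
#'   measurements in confirmation/counterscreen tables.
#' @param n_replicates Replicates per compound in those tables.
#' @param seed Master seed; per-table streams are derived via [derive_seed()].
#' @return An object of class `screen_sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- screen_sim_config(n_plates = 2, wells_per_plate = 96,
#'                          n_high_controls = 8, n_low_controls = 8)
screen_sim_config <- function(n_plates = 6L,
                              wells_per_plate = 384L,
                              n_high_controls = 16L,
                              n_low_controls = 16L,
                              high_mean = 100,
                              low_mean = 1,
                              cv = 0.05,
                              class_fractions = c(global = 0.02,
                                                  atf6_preferential = 0.05,
                                                  inactive = 0.93),
                              class_effects = default_class_effects(),
                              sd_pct = 2,
                              n_replicates = 3L,
                              seed = 1L) {
  if (!is.numeric(cv) || length(cv) != 1L || cv < 0) {
    stop("`cv` must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(high_mean) || !is.numeric(low_mean) ||
      low_mean <= 0 || high_mean <= low_mean) {
    stop("need `high_mean` > `low_mean` > 0", call. = FALSE)
  }
  cls <- c("global", "atf6_preferential", "inactive")
  if (!setequal(names(class_fractions), cls)) {
    stop("`class_fractions` must be named over: ",
         paste(cls, collapse = ", "), call. = FALSE)
  }
  class_fractions <- class_fractions[cls]
  if (abs(sum(class_fractions) - 1) > 1e-9 || any(class_fractions < 0)) {
    stop("`class_fractions` must be non-negative and sum to 1 (+/- 1e-9)",
         call. = FALSE)
  }
  if (!setequal(names(class_effects), cls) ||
      !all(vapply(class_effects,
                  function(e) all(c("erse", "xbp1") %in% names(e)),
                  logical(1)))) {
    stop("`class_effects` must map each class to c(erse=, xbp1=)",
         call. = FALSE)
  }
  n_ctl <- n_high_controls + n_low_controls
  if (n_high_controls < 2L || n_low_controls < 2L ||
      wells_per_plate <= n_ctl) {
    stop("each plate needs >= 2 controls of each kind and >= 1 compound well",
         call. = FALSE)
  }
  structure(list(n_plates = as.integer(n_plates),
                 wells_per_plate = as.integer(wells_per_plate),
                 n_high_controls = as.integer(n_high_controls),
                 n_low_controls = as.integer(n_low_controls),
                 high_mean = high_mean, low_mean = low_mean, cv = cv,
                 class_fractions = class_fractions,
                 class_effects = class_effects[cls],
                 sd_pct = sd_pct, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "screen_sim_config")
}

#' Default true reporter activations per planted compound class
#'
#' Percent activation on the Tg-normalised scale: global UPR activators
#' drive both reporters strongly; ATF6-preferential compounds drive the
#' ERSE reporter (60%) far above the XBP1 splicing reporter (10%);
#' inactive compounds drive neither.
#'
#' @return Named list of `c(erse=, xbp1=)` vectors.
#' @export
default_class_effects <- function() {
  list(global            = c(erse = 80, xbp1 = 70),
       atf6_preferential = c(erse = 60, xbp1 = 10),
       inactive          = c(erse = 0,  xbp1 = 0))
}

# Log-normal draws with prescribed arithmetic mean and coefficient of
# variation; cv = 0 degenerates to the mean exactly.
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Exact planted class counts: floor the expected counts, hand remaining
# slots to the classes with the largest fractional parts.
planted_class_counts <- function(n, fractions) {
  exp_n <- fractions * n
  base <- floor(exp_n)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(exp_n - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

#' Generate a raw-luminescence plate set with planted compound classes
#'
#' Lays out each plate with high-control wells (global stressor, 100%
#' activation), low-control wells (vehicle, 0%) and compound wells. A
#' compound of true activation `a` (percent) has raw-signal mean
#' `low_mean + a/100 * (high_mean - low_mean)`; raw signals are log-normal
#' with coefficient of variation `cv` so all values are positive and the
#' generating Z' is analytically available.
#'
#' @param config A [screen_sim_config()].
#' @return List with `plates` (data.frame: plate_id, well_id, row, col, role,
#'   compound_id, raw_signal) and `truth` (data.frame: compound_id, class,
#'   true_erse_pct, true_xbp1_pct).
#' @export
generate_plate_set <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  n_comp_per_plate <- config$wells_per_plate -
    config$n_high_controls - config$n_low_controls
  n_comp <- n_comp_per_plate * config$n_plates

  counts <- planted_class_counts(n_comp, config$class_fractions)
  classes <- rep(names(counts), counts)

  with_seed(derive_seed(config$seed, "plates"), {
    classes <- sample(classes)
    compound_id <- sprintf("cmpd_%05d", seq_len(n_comp))
    effects <- vapply(config$class_effects, `[[`, numeric(1), "erse")
    act <- effects[classes]

    ncols <- ceiling(sqrt(config$wells_per_plate * 1.5))
    plates <- vector("list", config$n_plates)
    for (p in seq_len(config$n_plates)) {
      role <- c(rep("high_control", config$n_high_controls),
                rep("low_control", config$n_low_controls),
                rep("compound", n_comp_per_plate))
      idx <- (p - 1L) * n_comp_per_plate + seq_len(n_comp_per_plate)
      cid <- c(rep(NA_character_,
                   config$n_high_controls + config$n_low_controls),
               compound_id[idx])
      mu <- ifelse(role == "high_control", config$high_mean,
                   ifelse(role == "low_control", config$low_mean,
                          config$low_mean +
                            c(rep(0, config$wells_per_plate -
                                    n_comp_per_plate), act[idx]) / 100 *
                            (config$high_mean - config$low_mean)))
      w <- seq_len(config$wells_per_plate)
      plates[[p]] <- data.frame(
        plate_id = sprintf("plate_%03d", p),
        well_id = sprintf("P%03dW%04d", p, w),
        row = ((w - 1L) %/% ncols) + 1L,
        col = ((w - 1L) %% ncols) + 1L,
        role = role,
        compound_id = cid,
        raw_signal = rlnorm_mean_cv(length(mu), 1, config$cv) * mu,
        stringsAsFactors = FALSE)
    }
    truth <- data.frame(
      compound_id = compound_id,
      class = classes,
      true_erse_pct = vapply(config$class_effects, `[[`, numeric(1),
                             "erse")[classes],
      true_xbp1_pct = vapply(config$class_effects, `[[`, numeric(1),
                             "xbp1")[classes],
      stringsAsFactors = FALSE)
    list(plates = do.call(rbind, plates), truth = truth)
  })
}

#' Generate replicate percent-activation tables (confirmation/counterscreen)
#'
#' Draws `n_replicates` percent activations per compound around its true
#' class effect for the requested reporter, plus a set of DMSO (vehicle)
#' wells around 0%, all with Gaussian noise of SD `sd_pct` percent points.
#' Used as the confirmation screen (`assay = "erse"`) and the XBP1-RLuc
#' counterscreen (`assay = "xbp1"`).
#'
#' @param truth Truth table from [generate_plate_set()].
#' @param config The same [screen_sim_config()].
#' @param assay `"erse"` or `"xbp1"`.
#' @param n_dmso Number of DMSO control wells.
#' @return List with `compounds` (data.frame: compound_id, replicate, pct)
#'   and `dmso` (numeric vector of DMSO percent activations).
#' @export
generate_replicate_activations <- function(truth, config,
                                           assay = c("erse", "xbp1"),
                                           n_dmso = 32L) {
  assay <- match.arg(assay)
  stopifnot(inherits(config, "screen_sim_config"))
  with_seed(derive_seed(config$seed, paste0("replicates_", assay)), {
    n <- nrow(truth)
    k <- config$n_replicates
    eff <- if (assay == "erse") truth$true_erse_pct else truth$true_xbp1_pct
    pct <- rep(eff, each = k) + stats::rnorm(n * k, 0, config$sd_pct)
    list(compounds = data.frame(
           compound_id = rep(truth$compound_id, each = k),
           replicate = rep(seq_len(k), times = n),
           pct = pct, stringsAsFactors = FALSE),
         dmso = stats::rnorm(n_dmso, 0, config$sd_pct))
  })
}

#' Geneset catalog constructor
#'
#' A catalog maps geneset names to gene-id vectors. No gene may belong to
#' two genesets, and each of the three UPR-arm genesets (ATF6, XBP1s, PERK)
#' must contain at least 5 genes.
#'
#' @param sets Named list of character vectors (geneset -> gene ids).
#' @return Object of class `geneset_catalog`.
#' @export
geneset_catalog <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  all_genes <- unlist(sets, use.names = FALSE)
  dup <- unique(all_genes[duplicated(all_genes)])
  if (length(dup)) {
    stop("gene(s) present in two genesets: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  for (s in intersect(c("ATF6", "XBP1s", "PERK"), names(sets))) {
    if (length(sets[[s]]) < 5L) {
      stop("UPR geneset ", s, " has < 5 genes", call. = FALSE)
    }
  }
  structure(sets, class = "geneset_catalog")
}

#' Default synthetic geneset catalog
#'
#' Sixteen synthetic target genes per UPR arm (ATF6, XBP1s, PERK) and eight
#' per off-pathway stress program (HSR, Nrf2, NFkB). Gene ids are synthetic
#' placeholders, not curated gene symbols.
#'
#' @param n_upr,n_off Genes per UPR-arm / off-pathway geneset.
#' @return A [geneset_catalog()].
#' @export
default_geneset_catalog <- function(n_upr = 16L, n_off = 8L) {
  mk <- function(prefix, n) sprintf("%s_g%02d", prefix, seq_len(n))
  geneset_catalog(list(
    ATF6  = mk("ATF6", n_upr),
    XBP1s = mk("XBP1s", n_upr),
    PERK  = mk("PERK", n_upr),
    HSR   = mk("HSR", n_off),
    Nrf2  = mk("NRF2", n_off),
    NFkB  = mk("NFKB", n_off)))
}

#' Default per-class geneset effect sizes (fraction of reference induction)
#'
#' On the log-fold-change scale, a class-`c` compound induces each gene of
#' geneset `s` by `effects[[c]][s]` times the reference (Tg-like) induction.
#' Global activators reproduce the full reference induction on all three UPR
#' arms; ATF6-preferential compounds induce the ATF6 set at half the
#' reference and barely touch the others; inactive compounds induce nothing.
#'
#' @return Named list of named numeric vectors.
#' @export
default_class_geneset_effects <- function() {
  list(global            = c(ATF6 = 1.0, XBP1s = 1.0, PERK = 1.0),
       atf6_preferential = c(ATF6 = 0.5, XBP1s = 0.05, PERK = 0.05),
       inactive          = c(ATF6 = 0.0, XBP1s = 0.0, PERK = 0.0))
}

#' Generate expression fold-change profiles with planted class effects
#'
#' Builds a genes x conditions matrix of linear fold changes (vs vehicle).
#' The reference condition `"Tg"` induces every UPR-arm gene by a per-gene
#' log fold change drawn around `log(ref_induction)`; a compound of class
#' `c` induces gene `g` of geneset `s` by `effects[[c]][s]` times that
#' gene's reference log induction, with additive Gaussian noise of SD
#' `sd_log` on the log scale (multiplicative on the linear scale).
#' Off-pathway genesets stay at baseline for every condition.
#'
#' @param classes Character vector of planted classes, one per compound
#'   condition (values must name entries of `effects`).
#' @param genesets A [geneset_catalog()].
#' @param effects Per-class geneset effects; see
#'   [default_class_geneset_effects()].
#' @param sd_log Log-scale noise SD (0 = noise-free).
#' @param ref_induction Geometric-mean reference fold change of UPR genes
#'   under the global stressor.
#' @param ref_sd_log SD of per-gene reference log inductions.
#' @param seed Integer seed.
#' @return List with `expr` (matrix, linear fold changes; columns are
#'   compound conditions plus `"Tg"`), `conditions` (data.frame: condition,
#'   class, is_reference), `truth` and `genesets`.
#' @export
generate_expression_profiles <- function(classes,
                                         genesets = default_geneset_catalog(),
                                         effects = default_class_geneset_effects(),
                                         sd_log = 0.1,
                                         ref_induction = 4,
                                         ref_sd_log = 0.25,
                                         seed = 1L) {
  stopifnot(inherits(genesets, "geneset_catalog"))
  if (!all(classes %in% names(effects))) {
    stop("every class must name an entry of `effects`", call. = FALSE)
  }
  genes <- unlist(unclass(genesets), use.names = FALSE)
  set_of <- rep(names(genesets), lengths(genesets))
  upr <- c("ATF6", "XBP1s", "PERK")

  with_seed(derive_seed(seed, "expression"), {
    ref_log <- ifelse(set_of %in% upr,
                      stats::rnorm(length(genes), log(ref_induction),
                                   ref_sd_log),
                      0)
    n <- length(classes)
    cond <- sprintf("cmpd_%05d", seq_len(n))
    expr <- matrix(NA_real_, nrow = length(genes), ncol = n + 1L,
                   dimnames = list(genes, c(cond, "Tg")))
    for (i in seq_len(n)) {
      eff <- effects[[classes[i]]]
      mult <- numeric(length(genes))
      in_eff <- set_of %in% names(eff)
      mult[in_eff] <- eff[set_of[in_eff]]
      lfc <- mult * ref_log
      if (sd_log > 0) lfc <- lfc + stats::rnorm(length(genes), 0, sd_log)
      expr[, i] <- exp(lfc)
    }
    ref_col <- ref_log
    if (sd_log > 0) ref_col <- ref_col + stats::rnorm(length(genes), 0, sd_log)
    expr[, n + 1L] <- exp(ref_col)

    list(expr = expr,
         conditions = data.frame(
           condition = c(cond, "Tg"),
           class = c(classes, "reference"),
           is_reference = c(rep(FALSE, n), TRUE),
           stringsAsFactors = FALSE),
         truth = data.frame(condition = cond, class = classes,
                            stringsAsFactors = FALSE),
         genesets = genesets)
  })
}

#' Generate per-cell nuclear/ER intensity tables
#'
#' Per-cell nuclear:ER GFP ratios are drawn from a two-component log-normal
#' mixture: a resting component (median < 1; cytosolic/ER-localised ATF6)
#' and an activated component (median > 1; nuclear-translocated ATF6). Each
#' cell is activated with probability `activated_fraction + contamination`.
#' ER intensities are log-normal around `er_mean`; nuclear intensity is
#' ratio x ER intensity, so `cell_ratio()` recovers the planted ratio.
#'
#' @param n_wells Number of replicate wells.
#' @param cells_per_well Cells per well.
#' @param activated_fraction Planted activated fraction in `[0, 1]`.
#' @param ratio_params List with `resting_median`, `activated_median`,
#'   `sdlog` of the two mixture components.
#' @param contamination Extra activation probability added to vehicle-like
#'   wells (spontaneous translocation).
#' @param treatment Treatment label stored on every row.
#' @param well_prefix Prefix for generated well ids.
#' @param er_mean,er_sdlog ER-intensity log-normal parameters.
#' @param seed Integer seed.
#' @return List with `cells` (data.frame: cell_id, well_id, treatment,
#'   nuc_intensity, er_intensity) and `truth` (list: activated logical
#'   vector, activated_fraction, per-well planted fractions).
#' @export
generate_cell_ratios <- function(n_wells, cells_per_well, activated_fraction,
                                 ratio_params = list(resting_median = 0.7,
                                                     activated_median = 1.6,
                                                     sdlog = 0.2),
                                 contamination = 0,
                                 treatment = "compound",
                                 well_prefix = treatment,
                                 er_mean = 100, er_sdlog = 0.1,
                                 seed = 1L) {
  if (activated_fraction < 0 || activated_fraction > 1) {
    stop("`activated_fraction` must be in [0, 1]", call. = FALSE)
  }
  p <- min(1, activated_fraction + contamination)
  with_seed(derive_seed(seed, paste0("cells_", well_prefix)), {
    n <- n_wells * cells_per_well
    activated <- stats::runif(n) < p
    mlog <- ifelse(activated, log(ratio_params$activated_median),
                   log(ratio_params$resting_median))
    ratio <- stats::rlnorm(n, meanlog = mlog, sdlog = ratio_params$sdlog)
    er <- stats::rlnorm(n, meanlog = log(er_mean), sdlog = er_sdlog)
    wells <- rep(sprintf("%s_w%02d", well_prefix, seq_len(n_wells)),
                 each = cells_per_well)
    cells <- data.frame(
      cell_id = sprintf("%s_c%06d", well_prefix, seq_len(n)),
      well_id = wells,
      treatment = treatment,
      nuc_intensity = ratio * er,
      er_intensity = er,
      stringsAsFactors = FALSE)
    list(cells = cells,
         truth = list(activated = activated,
                      activated_fraction = activated_fraction,
                      per_well = tapply(activated, wells, mean)))
  })
}

#' Closed-form two-compartment chase model
#'
#' Irreversible first-order kinetics for a pulse-labelled protein pool:
#' the intracellular pool is secreted at rate `ks` and degraded at rate
#' `kd` (degradation acts only on the intracellular pool), so
#' `I(t) = label0 * exp(-(ks+kd) t)` and
#' `E(t) = label0 * ks/(ks+kd) * (1 - exp(-(ks+kd) t))` (0 when
#' `ks + kd = 0`).
#'
#' @param ks,kd Secretion / degradation rate constants (per hour, >= 0).
#' @param t Time points (hours).
#' @param label0 Labelled pool at `t = 0`.
#' @return List with numeric vectors `I` and `E`.
#' @export
#' @examples
#' chase_model(0.3, 0.1, c(0, 4))
chase_model <- function(ks, kd, t, label0 = 100) {
  stopifnot(ks >= 0, kd >= 0)
  k <- ks + kd
  I <- label0 * exp(-k * t)
  E <- if (k == 0) rep(0, length(t)) else label0 * ks / k * (1 - exp(-k * t))
  list(I = I, E = E)
}

#' Generate pulse-chase compartment series from the two-compartment model
#'
#' @param ks,kd Rate constants (per hour).
#' @param t_points Chase time points (hours); must include 0.
#' @param label0 Initial labelled pool.
#' @param noise_cv Multiplicative (log-normal) measurement noise CV;
#'   0 = noise-free.
#' @param n_replicates Replicates per time point.
#' @param series_id Series label (construct x treatment).
#' @param seed Integer seed.
#' @return List with `series` (data.frame: series_id, replicate, t_hours,
#'   compartment in lysate/media, signal) and `truth`
#'   (list: ks, kd, label0).
#' @export
generate_chase_data <- function(ks, kd, t_points, label0 = 100,
                                noise_cv = 0, n_replicates = 1L,
                                series_id = "series1", seed = 1L) {
  stopifnot(ks >= 0, kd >= 0, 0 %in% t_points)
  m <- chase_model(ks, kd, t_points, label0)
  with_seed(derive_seed(seed, paste0("chase_", series_id)), {
    rows <- expand.grid(replicate = seq_len(n_replicates),
                        t_hours = t_points,
                        compartment = c("lysate", "media"),
                        stringsAsFactors = FALSE)
    mu <- ifelse(rows$compartment == "lysate",
                 m$I[match(rows$t_hours, t_points)],
                 m$E[match(rows$t_hours, t_points)])
    sig <- if (noise_cv > 0) {
      mu * rlnorm_mean_cv(nrow(rows), 1, noise_cv)
    } else mu
    list(series = data.frame(series_id = series_id,
                             replicate = rows$replicate,
                             t_hours = rows$t_hours,
                             compartment = rows$compartment,
                             signal = sig,
                             stringsAsFactors = FALSE),
         truth = list(ks = ks, kd = kd, label0 = label0))
  })
}

#' Generate dose-response observations from a 4PL curve
#'
#' Evaluates the four-parameter logistic
#' `R(d) = bottom + (top - bottom) / (1 + (d / ec50)^slope)` at each dose
#' and adds multiplicative log-normal noise.
#'
#' @param doses Dose vector (> 0, same units as `ec50`).
#' @param bottom,top,ec50,slope 4PL parameters.
#' @param noise_cv Multiplicative noise CV (0 = exact curve).
#' @param n_replicates Replicates per dose.
#' @param seed Integer seed.
#' @return List with `dr` (data.frame: dose, replicate, response) and
#'   `truth` (the 4PL parameters).
#' @export
generate_dose_response <- function(doses, bottom = 0, top = 100,
                                   ec50 = 1e-6, slope = 1,
                                   noise_cv = 0, n_replicates = 3L,
                                   seed = 1L) {
  stopifnot(all(doses > 0), ec50 > 0)
  mu <- four_pl(doses, bottom, top, ec50, slope)
  with_seed(derive_seed(seed, "dose_response"), {
    rows <- expand.grid(replicate = seq_len(n_replicates), dose = doses)
    m <- mu[match(rows$dose, doses)]
    resp <- if (noise_cv > 0) m * rlnorm_mean_cv(nrow(rows), 1, noise_cv)
            else m
    list(dr = data.frame(dose = rows$dose, replicate = rows$replicate,
                         response = resp),
         truth = list(bottom = bottom, top = top, ec50 = ec50,
                      slope = slope))
  })
}
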