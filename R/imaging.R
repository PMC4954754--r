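#' Per-cell nuclear:ER intensity ratio
#'
#' @param nuc_intensity Nuclear GFP mean intensity (>= 0).
#' @param er_intensity ER GFP mean intensity (> 0).
#' @return `nuc_intensity / er_intensity` (vectorised).
#' @export
cell_ratio <- function(nuc_intensity, er_intensity) {
  if (any(er_intensity <= 0)) {
    stop("ER intensity must be > 0", call. = FALSE)
  }
  stopifnot(all(nuc_intensity >= 0))
  nuc_intensity / er_intensity
}

#' Adaptive activation threshold from stressed vs vehicle ratio histograms
#'
#' Histograms both samples on identical bins (left-closed, right-open, bin
#' edges at integer multiples of `bin_width`) and returns the left edge of
#' the lowest bin whose left edge is greater than 1 and whose stressed-cell
#' count strictly exceeds the vehicle count. This is the minimum
#' nuclear:ER ratio above 1 at which stressed cells outnumber unstressed
#' ones — the operational definition of an "activated" cell. Computed per
#' plate, from that plate's stressor and vehicle wells.
#'
#' @param stressed_ratios Ratios of cells from global-stressor wells.
#' @param vehicle_ratios Ratios of cells from vehicle wells.
#' @param bin_width Histogram bin width in ratio units (default 0.05).
#' @return Object of class `activation_threshold`: list(threshold,
#'   bin_width, breaks, stressed_counts, vehicle_counts).
#' @export
activation_threshold <- function(stressed_ratios, vehicle_ratios,
                                 bin_width = 0.05) {
  if (!length(stressed_ratios) || !length(vehicle_ratios)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  stopifnot(bin_width > 0)
  all_r <- c(stressed_ratios, vehicle_ratios)
  lo <- floor(min(all_r) / bin_width)
  hi <- floor(max(all_r) / bin_width) + 1L
  breaks <- seq(lo, hi) * bin_width
  nbins <- length(breaks) - 1L
  bin_of <- function(r) pmin(pmax(floor(r / bin_width) - lo + 1, 1L), nbins)
  s_counts <- tabulate(bin_of(stressed_ratios), nbins)
  v_counts <- tabulate(bin_of(vehicle_ratios), nbins)
  left <- breaks[-length(breaks)]
  cand <- which(left > 1 + 1e-12 & s_counts > v_counts)
  if (!length(cand)) {
    stop("no separation: stressed cells never outnumber vehicle above ",
         "ratio 1 (assay failed)", call. = FALSE)
  }
  structure(list(threshold = left[min(cand)], bin_width = bin_width,
                 breaks = breaks, stressed_counts = s_counts,
                 vehicle_counts = v_counts),
            class = "activation_threshold")
}

#' Percent of cells above the activation threshold
#'
#' `100 * |{ratio > threshold}| / n` with a strict comparison.
#'
#' @param well_ratios Per-cell ratios of one well (non-empty).
#' @param threshold Numeric threshold or an [activation_threshold()].
#' @return Percent activated.
#' @export
percent_activated <- function(well_ratios, threshold) {
  if (!length(well_ratios)) stop("empty well", call. = FALSE)
  if (inherits(threshold, "activation_threshold")) {
    threshold <- threshold$threshold
  }
  100 * sum(well_ratios > threshold) / length(well_ratios)
}

#' Per-well percent activation for a cell table
#'
#' @param cells data.frame with columns `well_id`, `treatment`,
#'   `nuc_intensity`, `er_intensity` (or a precomputed `ratio` column).
#' @param threshold Numeric threshold or an [activation_threshold()].
#' @return data.frame: well_id, treatment, n_cells, pct_activated.
#' @export
percent_activated_by_well <- function(cells, threshold) {
  ratio <- if ("ratio" %in% names(cells)) cells$ratio else
    cell_ratio(cells$nuc_intensity, cells$er_intensity)
  sp <- split(seq_len(nrow(cells)), cells$well_id)
  rows <- lapply(sp, function(idx) {
    data.frame(well_id = cells$well_id[idx[1]],
               treatment = cells$treatment[idx[1]],
               n_cells = length(idx),
               pct_activated = percent_activated(ratio[idx], threshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call imaging hits against the vehicle 3-SD cutoff
#'
#' Cutoff is `mean(vehicle well percents) + sd_mult * sd(...)` (sample SD);
#' a treatment is a hit iff its mean percent activation over its replicate
#' wells strictly exceeds the cutoff. One-sided by design: nuclear
#' translocation (activation) is the direction of interest.
#'
#' @param well_pcts data.frame of per-well percents for test treatments
#'   (columns `treatment`, `pct_activated`), e.g. from
#'   [percent_activated_by_well()].
#' @param vehicle_pcts Numeric vector of vehicle well percents (>= 2).
#' @param sd_mult SD multiplier (default 3).
#' @return List of class `imaging_hit_report`: `cutoff`, `vehicle_mean`,
#'   `vehicle_sd`, `calls` (data.frame: treatment, mean_pct, n_wells, hit).
#' @export
imaging_hit_call <- function(well_pcts, vehicle_pcts, sd_mult = 3) {
  if (length(vehicle_pcts) < 2L) {
    stop("need >= 2 vehicle wells", call. = FALSE)
  }
  vm <- mean(vehicle_pcts)
  vs <- stats::sd(vehicle_pcts)
  cutoff <- vm + sd_mult * vs
  agg <- split(well_pcts$pct_activated, well_pcts$treatment)
  calls <- data.frame(treatment = names(agg),
                      mean_pct = vapply(agg, mean, numeric(1)),
                      n_wells = lengths(agg),
                      stringsAsFactors = FALSE)
  calls$hit <- calls$mean_pct > cutoff
  rownames(calls) <- NULL
  structure(list(cutoff = cutoff, vehicle_mean = vm, vehicle_sd = vs,
                 calls = calls),
            class = "imaging_hit_report")
}

#' Quantify an imaging experiment end to end
#'
#' From a per-cell table containing vehicle wells, global-stressor wells
#' and test-compound wells: derives ratios, computes the plate's adaptive
#' threshold from the stressor and vehicle cells, the per-well percent
#' activation, and the 3-SD hit calls for all non-control treatments.
#'
#' @param cells Per-cell data.frame (cell_id, well_id, treatment,
#'   nuc_intensity, er_intensity).
#' @param stressor_label,vehicle_label Treatment labels of the global
#'   stressor and vehicle wells.
#' @param bin_width Histogram bin width (default 0.05).
#' @param sd_mult Hit-call SD multiplier (default 3).
#' @return List: `threshold` ([activation_threshold()]), `wells` (per-well
#'   percents), `hits` ([imaging_hit_call()] report).
#' @export
quantify_translocation <- function(cells, stressor_label = "Tg",
                                   vehicle_label = "vehicle",
                                   bin_width = 0.05, sd_mult = 3) {
  stopifnot(all(c("well_id", "treatment", "nuc_intensity",
                  "er_intensity") %in% names(cells)))
  cells$ratio <- cell_ratio(cells$nuc_intensity, cells$er_intensity)
  thr <- activation_threshold(cells$ratio[cells$treatment == stressor_label],
                              cells$ratio[cells$treatment == vehicle_label],
                              bin_width = bin_width)
  wells <- percent_activated_by_well(cells, thr)
  veh <- wells$pct_activated[wells$treatment == vehicle_label]
  test <- wells[!wells$treatment %in% c(stressor_label, vehicle_label), ,
                drop = FALSE]
  hits <- imaging_hit_call(test, veh, sd_mult = sd_mult)
  list(threshold = thr, wells = wells, hits = hits)
}
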