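#' Percent activation relative to in-plate controls
#'
#' Normalises a raw test-compound signal against the plate's own control
#' medians:
#' `100 * (test - median(low)) / (median(high) - median(low))`,
#' where the low control is vehicle (0% activation) and the high control the
#' global ER stressor (100%). Values below 0 or above 100 are preserved —
#' inhibitors and super-activators carry information and are flagged
#' downstream, never clamped.
#'
#' @param test_signal Raw signal(s) of test wells (vectorised).
#' @param low_median,high_median Plate control medians; must differ.
#' @return Percent activation (same length as `test_signal`).
#' @export
#' @examples
#' percent_activation(55, 10, 110) # 45
percent_activation <- function(test_signal, low_median, high_median) {
  if (!is.finite(low_median) || !is.finite(high_median) ||
      high_median == low_median) {
    stop("degenerate plate: high and low control medians are equal",
         call. = FALSE)
  }
  100 * (test_signal - low_median) / (high_median - low_median)
}

#' Z'-factor (screening-window coefficient)
#'
#' `Z' = 1 - 3 * (sd_pos + sd_neg) / |mean_pos - mean_neg|`. Equals 1 only
#' for noiseless, separated controls; values above ~0.5 indicate an
#' excellent screening window.
#'
#' @param pos_mean,pos_sd High (positive) control mean and SD.
#' @param neg_mean,neg_sd Low (negative) control mean and SD.
#' @return Z' (dimensionless, <= 1).
#' @export
#' @examples
#' z_prime(100, 10, 0, 5) # 0.55
z_prime <- function(pos_mean, pos_sd, neg_mean, neg_sd) {
  if (pos_mean == neg_mean) {
    stop("Z' undefined: control means are equal", call. = FALSE)
  }
  stopifnot(pos_sd >= 0, neg_sd >= 0)
  1 - 3 * (pos_sd + neg_sd) / abs(pos_mean - neg_mean)
}

#' Signal-to-background ratio of plate controls
#'
#' Mean high-control signal over mean low-control signal (mean/mean; the
#' median/median alternative is not used — see the methods vignette).
#'
#' @param pos_mean,neg_mean Control means; `neg_mean` must be > 0.
#' @return Ratio (> 0).
#' @export
signal_background <- function(pos_mean, neg_mean) {
  if (neg_mean <= 0) stop("background mean must be > 0", call. = FALSE)
  pos_mean / neg_mean
}

#' Per-plate control statistics and quality report
#'
#' Computes, per plate, the high/low control medians, means and SDs, Z',
#' and signal/background. Plates missing either control class are reported
#' with `status = "error"` and NA statistics; remaining plates are
#' unaffected.
#'
#' @param plates Plate data.frame (columns plate_id, role, raw_signal; the
#'   `synthetic_data` dialect).
#' @param zprime_floor Plates with Z' below this are flagged
#'   (`plate_pass = FALSE`) but never dropped.
#' @return data.frame, one row per plate: plate_id, n_high, n_low,
#'   high_median, low_median, high_mean, low_mean, high_sd, low_sd,
#'   z_prime, signal_background, plate_pass, status.
#' @export
plate_qc_report <- function(plates, zprime_floor = 0.4) {
  stopifnot(all(c("plate_id", "role", "raw_signal") %in% names(plates)))
  out <- lapply(split(plates, plates$plate_id), function(pl) {
    hi <- pl$raw_signal[pl$role == "high_control"]
    lo <- pl$raw_signal[pl$role == "low_control"]
    row <- data.frame(plate_id = pl$plate_id[1],
                      n_high = length(hi), n_low = length(lo),
                      high_median = NA_real_, low_median = NA_real_,
                      high_mean = NA_real_, low_mean = NA_real_,
                      high_sd = NA_real_, low_sd = NA_real_,
                      z_prime = NA_real_, signal_background = NA_real_,
                      plate_pass = NA, status = "ok",
                      stringsAsFactors = FALSE)
    if (length(hi) < 2L || length(lo) < 2L) {
      row$status <- "error: missing controls"
      return(row)
    }
    row$high_median <- stats::median(hi)
    row$low_median <- stats::median(lo)
    row$high_mean <- mean(hi)
    row$low_mean <- mean(lo)
    row$high_sd <- stats::sd(hi)
    row$low_sd <- stats::sd(lo)
    row$z_prime <- z_prime(row$high_mean, row$high_sd,
                           row$low_mean, row$low_sd)
    row$signal_background <- signal_background(row$high_mean, row$low_mean)
    row$plate_pass <- row$z_prime >= zprime_floor
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Normalise a plate set to percent activation with per-plate QC
#'
#' Every compound well is normalised against its own plate's control
#' medians via [percent_activation()], so gain differences between plates
#' cancel and activations are comparable across the screen. Compounds on
#' plates whose Z' falls below `zprime_floor` are flagged
#' (`plate_pass = FALSE`), not dropped. A plate missing a control class
#' yields an error entry in the QC report and NA activations for its
#' compounds; all other plates are processed normally.
#'
#' @param plates Plate data.frame (plate_id, well_id, role, compound_id,
#'   raw_signal).
#' @param zprime_floor Plate-quality floor (default 0.4).
#' @return List with `activations` (data.frame: compound_id, plate_id,
#'   pct_activation, plate_pass) and `qc` (the [plate_qc_report()]).
#' @export
normalize_plate_set <- function(plates, zprime_floor = 0.4) {
  qc <- plate_qc_report(plates, zprime_floor = zprime_floor)
  comp <- plates[plates$role == "compound", , drop = FALSE]
  i <- match(comp$plate_id, qc$plate_id)
  ok <- qc$status[i] == "ok"
  pct <- rep(NA_real_, nrow(comp))
  for (p in unique(comp$plate_id[ok])) {
    q <- qc[qc$plate_id == p, ]
    sel <- comp$plate_id == p
    pct[sel] <- percent_activation(comp$raw_signal[sel],
                                   q$low_median, q$high_median)
  }
  list(activations = data.frame(compound_id = comp$compound_id,
                                plate_id = comp$plate_id,
                                pct_activation = pct,
                                plate_pass = qc$plate_pass[i],
                                stringsAsFactors = FALSE),
       qc = qc)
}
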