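#' Fraction secreted at chase time t
#'
#' `E(t) / (E(0) + I(0))`: the share of the pulse-labelled pool found in
#' the media at time t, relative to the total labelled pool at the start of
#' the chase. Not clamped at 1 — measurement noise can push it above, and
#' that is worth seeing; values > 1 should be flagged by callers.
#'
#' @param E_t Extracellular signal at time t.
#' @param E_0,I_0 Extracellular/intracellular signal at t = 0;
#'   `E_0 + I_0` must be > 0.
#' @return Fraction (>= 0), vectorised over `E_t`.
#' @export
fraction_secreted <- function(E_t, E_0, I_0) {
  if (E_0 + I_0 <= 0) stop("E_0 + I_0 must be > 0", call. = FALSE)
  stopifnot(all(E_t >= 0))
  E_t / (E_0 + I_0)
}

#' Fraction remaining at chase time t
#'
#' `(E(t) + I(t)) / (E(0) + I(0))`: the share of the labelled pool not yet
#' degraded. Equals 1 at t = 0 and stays at 1 when there is no
#' degradation.
#'
#' @param E_t,I_t Extracellular/intracellular signal at time t.
#' @param E_0,I_0 Signals at t = 0; `E_0 + I_0` must be > 0.
#' @return Fraction, vectorised.
#' @export
fraction_remaining <- function(E_t, I_t, E_0, I_0) {
  if (E_0 + I_0 <= 0) stop("E_0 + I_0 must be > 0", call. = FALSE)
  (E_t + I_t) / (E_0 + I_0)
}

#' Normalise a secretion metric to the vehicle condition
#'
#' `metric_treated / metric_vehicle`; 1 means no treatment effect, 0.55
#' means a 45% reduction.
#'
#' @param metric_treated,metric_vehicle Metric values; vehicle must be > 0.
#' @return Ratio, vectorised over `metric_treated`.
#' @export
normalize_to_vehicle <- function(metric_treated, metric_vehicle) {
  if (any(metric_vehicle <= 0)) {
    stop("vehicle metric must be > 0", call. = FALSE)
  }
  metric_treated / metric_vehicle
}

#' Cycloheximide-chase fractions
#'
#' With the common denominator `media_0 + lysate_0`:
#' fraction secreted `= media_t / denom`, intracellular fraction
#' `= lysate_t / denom`, fraction remaining `= (lysate_t + media_t) /
#' denom`. The identity remaining = secreted + intracellular holds exactly
#' on all inputs.
#'
#' @param lysate_t,media_t Signals at chase time t.
#' @param lysate_0,media_0 Signals at t = 0; sum must be > 0.
#' @return Named list: fraction_secreted, intracellular_fraction,
#'   fraction_remaining.
#' @export
#' @examples
#' chx_fractions(20, 50, 90, 10) # 0.5, 0.2, 0.7
chx_fractions <- function(lysate_t, media_t, lysate_0, media_0) {
  denom <- media_0 + lysate_0
  if (denom <= 0) stop("media_0 + lysate_0 must be > 0", call. = FALSE)
  list(fraction_secreted = media_t / denom,
       intracellular_fraction = lysate_t / denom,
       fraction_remaining = (lysate_t + media_t) / denom)
}

#' Evaluate the four-parameter logistic
#'
#' `R(d) = bottom + (top - bottom) / (1 + (d / ec50)^slope)`. With
#' `slope > 0` the curve falls from `top` (low dose) to `bottom` (high
#' dose); a negative slope rises.
#'
#' @param dose Dose vector (> 0).
#' @param bottom,top,ec50,slope Parameters.
#' @return Response values.
#' @export
four_pl <- function(dose, bottom, top, ec50, slope) {
  bottom + (top - bottom) / (1 + (dose / ec50)^slope)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of [four_pl()] with the EC50 parameterised as
#' log10(EC50). Initial values come from the data: bottom/top from the
#' response extremes, EC50 from the dose whose mean response is nearest
#' mid-range, slope from the sign of the dose-response trend. Fitting uses
#' `nls` (port algorithm); on failure a Nelder-Mead `optim` refinement of
#' the same SSE is used. `constrain` fixes parameters (e.g.
#' `list(bottom = 0, top = 100)`).
#'
#' A flat response (range below `degenerate_tol` of the mean absolute
#' response) yields a degenerate result: EC50 is unidentifiable and no fit
#' is attempted. A fitted EC50 outside the observed dose range is flagged
#' `extrapolated` — such values should not be trusted (for standard-curve
#' inversion, re-dilute into range instead of extrapolating).
#'
#' @param doses Dose vector (> 0), replicated entries allowed.
#' @param responses Response vector, same length.
#' @param constrain Optional named list fixing any of bottom/top/ec50/slope.
#' @param degenerate_tol Relative response-range floor (default 1e-8).
#' @return Object of class `dose_response`: list(bottom, top, ec50, slope,
#'   sse, extrapolated, degenerate, n_doses, dose_range).
#' @export
fit_4pl <- function(doses, responses, constrain = NULL,
                    degenerate_tol = 1e-8) {
  stopifnot(length(doses) == length(responses), all(doses > 0),
            all(is.finite(responses)))
  n_doses <- length(unique(doses))
  if (n_doses < 5L) {
    stop("need >= 5 distinct doses for a 4PL fit", call. = FALSE)
  }
  rng <- range(doses)
  span <- diff(range(responses))
  if (span <= degenerate_tol * max(mean(abs(responses)), 1)) {
    return(structure(list(bottom = mean(responses), top = mean(responses),
                          ec50 = NA_real_, slope = NA_real_,
                          sse = sum((responses - mean(responses))^2),
                          extrapolated = NA, degenerate = TRUE,
                          n_doses = n_doses, dose_range = rng),
                     class = "dose_response"))
  }
  l10d <- log10(doses)

  # data-driven starts
  means <- tapply(responses, doses, mean)
  d_u <- as.numeric(names(means))
  lo0 <- min(responses); hi0 <- max(responses)
  mid <- (lo0 + hi0) / 2
  e0 <- log10(d_u[which.min(abs(means - mid))])
  trend <- stats::cor(l10d, responses)
  s0 <- if (is.na(trend) || trend < 0) 1 else -1 # slope>0 => falling curve

  fixed <- constrain %||% list()
  start <- list(bottom = lo0, top = hi0, l10e = e0, slope = s0)
  if ("ec50" %in% names(fixed)) {
    fixed$l10e <- log10(fixed$ec50)
    fixed$ec50 <- NULL
  }
  start[names(fixed)] <- NULL
  free <- names(start)

  sse_fun <- function(par) {
    p <- c(as.list(par), fixed)
    sum((responses - four_pl(doses, p$bottom, p$top, 10^p$l10e,
                             p$slope))^2)
  }

  est <- NULL
  form_rhs <- "bottom + (top - bottom) / (1 + 10^(slope * (l10d - l10e)))"
  fit <- tryCatch({
    env <- list2env(c(list(responses = responses, l10d = l10d), fixed))
    stats::nls(stats::as.formula(paste("responses ~", form_rhs)),
               start = start, algorithm = "port",
               control = stats::nls.control(maxiter = 500,
                                            scaleOffset = 1,
                                            warnOnly = FALSE),
               data = env)
  }, error = function(e) NULL)
  if (!is.null(fit)) est <- as.list(stats::coef(fit))
  if (is.null(est) || sse_fun(unlist(est)) > span^2) {
    opt <- stats::optim(unlist(start), sse_fun, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
    opt2 <- tryCatch(
      stats::optim(opt$par, sse_fun, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-14)),
      error = function(e) opt)
    if (is.null(est) || opt2$value < sse_fun(unlist(est))) {
      est <- as.list(opt2$par)
    }
  }
  if (is.null(est)) {
    stop("4PL fit failed to converge (", n_doses, " doses, response span ",
         signif(span, 3), ")", call. = FALSE)
  }
  p <- c(est, fixed)
  ec50 <- 10^p$l10e
  structure(list(bottom = p$bottom, top = p$top, ec50 = ec50,
                 slope = p$slope,
                 sse = sse_fun(unlist(est)),
                 extrapolated = ec50 < rng[1] || ec50 > rng[2],
                 degenerate = FALSE, n_doses = n_doses, dose_range = rng),
            class = "dose_response")
}

#' Invert a fitted standard curve within its calibrated range
#'
#' Solves `four_pl(d) = response` for dose. Responses mapping outside the
#' standards' dose range are returned as NA and flagged for re-dilution
#' rather than extrapolated.
#'
#' @param fit A non-degenerate [fit_4pl()] result.
#' @param response Observed responses.
#' @return data.frame: response, dose, in_range.
#' @export
invert_4pl <- function(fit, response) {
  stopifnot(inherits(fit, "dose_response"), !fit$degenerate)
  # (top - R)/(R - bottom) = (d/ec50)^slope
  ratio <- (fit$top - response) / (response - fit$bottom)
  dose <- ifelse(ratio > 0, fit$ec50 * ratio^(1 / fit$slope), NA_real_)
  in_range <- !is.na(dose) & dose >= fit$dose_range[1] &
    dose <= fit$dose_range[2]
  data.frame(response = response,
             dose = ifelse(in_range, dose, NA_real_),
             in_range = in_range)
}

#' Estimate secretion and degradation rates from chase series
#'
#' Nonlinear least squares of the two-compartment closed forms
#' `I(t) = label0 exp(-(ks+kd) t)`,
#' `E(t) = label0 ks/(ks+kd) (1 - exp(-(ks+kd) t))` against the lysate and
#' media signals jointly, with `ks, kd >= 0` (port algorithm). Starting
#' values come from a log-linear regression of the lysate decay and the
#' late-time media/lysate split. Optional bootstrap over replicates gives
#' percentile confidence intervals.
#'
#' @param series Chase data.frame (series_id, replicate, t_hours,
#'   compartment in lysate/media, signal) with >= 3 time points
#'   including 0.
#' @param n_boot Bootstrap resamples over replicates (0 = none; requires
#'   at least 2 replicates).
#' @param conf Confidence level for bootstrap intervals.
#' @param seed Seed for the bootstrap resampling.
#' @return List of class `rate_estimate`: ks, kd, label0, sse, and (if
#'   bootstrapped) `ci` (2 x 2 matrix of percentile intervals).
#' @export
estimate_rates <- function(series, n_boot = 0L, conf = 0.95, seed = 1L) {
  stopifnot(all(c("t_hours", "compartment", "signal") %in% names(series)))
  tp <- sort(unique(series$t_hours))
  if (length(tp) < 3L || !(0 %in% tp)) {
    stop("need >= 3 time points including t = 0", call. = FALSE)
  }

  fit_one <- function(df) {
    lys <- df[df$compartment == "lysate", ]
    med <- df[df$compartment == "media", ]
    label0 <- mean(lys$signal[lys$t_hours == 0]) +
      mean(med$signal[med$t_hours == 0])
    pos <- lys$signal > 0
    k0 <- if (sum(pos) >= 2L) {
      max(1e-3, -stats::coef(stats::lm(log(lys$signal[pos]) ~
                                         lys$t_hours[pos]))[[2]])
    } else 0.1
    tl <- max(df$t_hours)
    e_late <- mean(med$signal[med$t_hours == tl])
    i_late <- mean(lys$signal[lys$t_hours == tl])
    frac_s <- min(0.99, max(0.01,
      e_late / max(label0 - i_late, label0 * 1e-3)))
    start <- list(ks = max(1e-4, k0 * frac_s),
                  kd = max(1e-4, k0 * (1 - frac_s)), label0 = label0)
    pred <- function(ks, kd, l0, t, comp) {
      k <- ks + kd
      I <- l0 * exp(-k * t)
      E <- ifelse(rep(k, length(t)) == 0, 0,
                  l0 * ks / max(k, .Machine$double.eps) * (1 - exp(-k * t)))
      ifelse(comp == "lysate", I, E)
    }
    env <- list2env(list(signal = df$signal, t_hours = df$t_hours,
                         compartment = df$compartment, pred = pred))
    fit <- stats::nls(
      signal ~ pred(ks, kd, label0, t_hours, compartment),
      start = start, algorithm = "port",
      lower = c(ks = 0, kd = 0, label0 = .Machine$double.eps),
      control = stats::nls.control(maxiter = 500, scaleOffset = 1),
      data = env)
    co <- stats::coef(fit)
    list(ks = co[["ks"]], kd = co[["kd"]], label0 = co[["label0"]],
         sse = sum(stats::resid(fit)^2))
  }

  est <- fit_one(series)
  ci <- NULL
  if (n_boot > 0L) {
    reps <- unique(series$replicate)
    if (length(reps) < 2L) {
      warning("bootstrap needs >= 2 replicates; skipping intervals",
              call. = FALSE)
    } else {
      boots <- with_seed(derive_seed(seed, "rate_bootstrap"), {
        vapply(seq_len(n_boot), function(b) {
          pick <- sample(reps, length(reps), replace = TRUE)
          df <- do.call(rbind, lapply(seq_along(pick), function(i) {
            d <- series[series$replicate == pick[i], ]
            d$replicate <- i
            d
          }))
          e <- tryCatch(fit_one(df), error = function(err) NULL)
          if (is.null(e)) c(NA_real_, NA_real_) else c(e$ks, e$kd)
        }, numeric(2))
      })
      a <- (1 - conf) / 2
      ci <- rbind(ks = stats::quantile(boots[1, ], c(a, 1 - a),
                                       na.rm = TRUE),
                  kd = stats::quantile(boots[2, ], c(a, 1 - a),
                                       na.rm = TRUE))
    }
  }
  structure(c(est, list(ci = ci)), class = "rate_estimate")
}

#' Tabulate chase fractions for every series and replicate
#'
#' For each (series, replicate), computes [fraction_secreted()] and
#' [fraction_remaining()] at every chase time against that replicate's
#' t = 0 signals, with a QC flag for fractions above 1. If `vehicle` names
#' one of the series, both fractions are additionally normalised to the
#' vehicle series' replicate-mean value at the same time point.
#'
#' @param series Chase data.frame (series_id, replicate, t_hours,
#'   compartment, signal).
#' @param vehicle Optional vehicle `series_id` for normalisation.
#' @return data.frame: series_id, replicate, t_hours, fraction_secreted,
#'   fraction_remaining, qc_over_unity, and (if `vehicle` is given)
#'   norm_fraction_secreted, norm_fraction_remaining.
#' @export
chase_fraction_table <- function(series, vehicle = NULL) {
  key <- interaction(series$series_id, series$replicate, drop = TRUE)
  rows <- lapply(split(series, key), function(df) {
    e0 <- df$signal[df$compartment == "media" & df$t_hours == 0]
    i0 <- df$signal[df$compartment == "lysate" & df$t_hours == 0]
    t_all <- sort(unique(df$t_hours))
    fs <- fr <- numeric(length(t_all))
    for (k in seq_along(t_all)) {
      et <- df$signal[df$compartment == "media" & df$t_hours == t_all[k]]
      it <- df$signal[df$compartment == "lysate" & df$t_hours == t_all[k]]
      fs[k] <- fraction_secreted(mean(et), mean(e0), mean(i0))
      fr[k] <- fraction_remaining(mean(et), mean(it), mean(e0), mean(i0))
    }
    data.frame(series_id = df$series_id[1], replicate = df$replicate[1],
               t_hours = t_all, fraction_secreted = fs,
               fraction_remaining = fr,
               qc_over_unity = fs > 1 | fr > 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(vehicle)) {
    if (!vehicle %in% out$series_id) {
      stop("vehicle series '", vehicle, "' not found", call. = FALSE)
    }
    veh <- out[out$series_id == vehicle, ]
    vm_s <- tapply(veh$fraction_secreted, veh$t_hours, mean)
    vm_r <- tapply(veh$fraction_remaining, veh$t_hours, mean)
    tkey <- as.character(out$t_hours)
    # vehicle fraction secreted is legitimately 0 at t = 0: NA, not error
    out$norm_fraction_secreted <-
      ifelse(vm_s[tkey] > 0, out$fraction_secreted / vm_s[tkey], NA_real_)
    out$norm_fraction_remaining <-
      ifelse(vm_r[tkey] > 0, out$fraction_remaining / vm_r[tkey], NA_real_)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
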