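#' Pipeline run configuration
#'
#' One object carries every stage's parameters and thresholds plus the
#' master seed; per-stage seeds are derived with [derive_seed()] so stages
#' are independently reproducible. The object round-trips losslessly
#' through JSON ([write_run_config()] / [read_run_config()]).
#'
#' @param seed Master seed (integer).
#' @param stages Named logical vector enabling stages
#'   (simulate, qc, triage, expression, imaging, kinetics).
#' @param screen Overrides for [screen_sim_config()] fields.
#' @param triage Overrides: primary_cutoff, confirmation_sd_mult,
#'   selectivity_fold, blacklist, zprime_floor.
#' @param expression Overrides: min_fold, alpha, global_floor,
#'   activity_floor, sd_log, profile_max (cap on conditions profiled).
#' @param imaging Overrides: n_wells, cells_per_well, bin_width,
#'   stressor_fraction, contamination, class_fractions (named activated
#'   fractions per compound class), n_compounds.
#' @param kinetics Overrides: vehicle/treated (ks, kd), t_points, noise_cv,
#'   n_replicates, dose-response truth (dr_bottom, dr_top, dr_ec50,
#'   dr_slope, doses).
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       stages = c(simulate = TRUE, qc = TRUE, triage = TRUE,
                                  expression = TRUE, imaging = TRUE,
                                  kinetics = TRUE),
                       screen = list(),
                       triage = list(),
                       expression = list(),
                       imaging = list(),
                       kinetics = list()) {
  def_stages <- c(simulate = TRUE, qc = TRUE, triage = TRUE,
                  expression = TRUE, imaging = TRUE, kinetics = TRUE)
  def_stages[names(stages)] <- stages
  cfg <- list(
    seed = as.integer(seed),
    stages = as.list(def_stages),
    screen = utils::modifyList(
      list(n_plates = 6L, wells_per_plate = 384L, n_high_controls = 16L,
           n_low_controls = 16L, high_mean = 100, low_mean = 1, cv = 0.05,
           class_fractions = list(global = 0.02, atf6_preferential = 0.05,
                                  inactive = 0.93),
           sd_pct = 2, n_replicates = 3L, n_dmso = 32L),
      screen),
    triage = utils::modifyList(
      list(primary_cutoff = 25.1, confirmation_sd_mult = 3,
           selectivity_fold = 2, blacklist = character(),
           zprime_floor = 0.4),
      triage),
    expression = utils::modifyList(
      list(min_fold = 1.5, alpha = 0.05, global_floor = 25,
           activity_floor = 10, sd_log = 0.1, profile_max = 400L),
      expression),
    imaging = utils::modifyList(
      list(n_wells = 3L, cells_per_well = 500L, bin_width = 0.05,
           stressor_fraction = 0.7, contamination = 0.01,
           class_fractions = list(global = 0.6, atf6_preferential = 0.5,
                                  inactive = 0), n_compounds = 8L),
      imaging),
    kinetics = utils::modifyList(
      list(vehicle = list(ks = 0.3, kd = 0.1),
           treated = list(ks = 0.15, kd = 0.25),
           t_points = c(0, 1, 2, 4), noise_cv = 0.02, n_replicates = 4L,
           label0 = 100,
           dr_bottom = 0.4, dr_top = 1, dr_ec50 = 1.1e-6, dr_slope = 1,
           doses = 10^seq(-8, -4.5, by = 0.5)),
      kinetics))
  stopifnot(cfg$triage$primary_cutoff > 0, cfg$expression$min_fold > 0,
            cfg$imaging$bin_width > 0)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$kinetics$t_points <- as.numeric(raw$kinetics$t_points)
  raw$kinetics$doses <- as.numeric(raw$kinetics$doses)
  # empty character vectors serialise as [] and come back as lists
  raw$triage$blacklist <- as.character(unlist(raw$triage$blacklist))
  do.call(run_config, raw)
}

# FNV-1a 32-bit hash of a string, as 8 hex digits; used to stamp artifacts
# with a config fingerprint without a hashing dependency. Arithmetic is done
# in doubles split into 16-bit halves so every step stays exact.
fnv1a32 <- function(s) {
  mul32 <- function(a, b) {
    ((a %/% 65536 * b) %% 65536 * 65536 + a %% 65536 * b) %% 4294967296
  }
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    h <- mul32(h, 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_fingerprint <- function(config) {
  fnv1a32(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                           digits = NA))
}

#' Cross-walk triage flags with UPR profile calls into a priority table
#'
#' Joins the funnel flag trail with the expression classification by
#' compound id. Compounds that are both funnel-selective and classified
#' `preferential_ATF6` rank first; within tiers, compounds are ordered by
#' descending ATF6 geneset score, ties broken by compound id. An empty key
#' intersection yields an empty table with a warning.
#'
#' @param records Triage record table (from [run_funnel()]`$records`).
#' @param upr_calls Classification table (from [classify_all_profiles()],
#'   column `compound` matching record `compound_id`).
#' @return data.frame sorted by rank: compound_id, selective,
#'   preferential_atf6, priority, score_ATF6, call, rank.
#' @export
crosswalk <- function(records, upr_calls) {
  keys <- intersect(records$compound_id, upr_calls$compound)
  if (!length(keys)) {
    warning("no compound ids shared between triage records and UPR calls",
            call. = FALSE)
    return(data.frame(compound_id = character(), selective = logical(),
                      preferential_atf6 = logical(), priority = logical(),
                      score_ATF6 = numeric(), call = character(),
                      rank = integer(), stringsAsFactors = FALSE))
  }
  r <- records[match(keys, records$compound_id), ]
  u <- upr_calls[match(keys, upr_calls$compound), ]
  out <- data.frame(compound_id = keys,
                    selective = r$selective,
                    preferential_atf6 = u$call == "preferential_ATF6",
                    score_ATF6 = u$score_ATF6,
                    call = u$call,
                    stringsAsFactors = FALSE)
  out$priority <- out$selective & out$preferential_atf6
  ord <- order(-out$priority, -out$score_ATF6, out$compound_id)
  out <- out[ord, c("compound_id", "selective", "preferential_atf6",
                    "priority", "score_ATF6", "call")]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Run the full pipeline on synthetic data
#'
#' Executes simulate -> qc -> triage -> expression -> imaging -> kinetics
#' in dependency order, then cross-walks triage and expression results
#' into a priority table. A stage failure is recorded and halts its
#' downstream dependents only; independent stages still run, and a partial
#' report is returned. Identical config and seed give an identical report.
#'
#' Stage wiring: expression profiles are generated for (up to
#' `profile_max`) funnel-stringent compounds using their planted classes;
#' imaging simulates the top crosswalk compounds (plus vehicle and
#' stressor wells) with class-keyed planted activated fractions; kinetics
#' simulates a vehicle and a treated chase series plus one dose-response
#' curve, and recovers rates/EC50.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, per-stage CSV/JSON
#'   artifacts and a consolidated `report.json` + `report.md` are written.
#' @return List of class `run_report`; elements `qc`, `triage`,
#'   `expression`, `imaging`, `kinetics`, `crosswalk`, `errors`,
#'   `fingerprint`, `seed`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  fp <- config_fingerprint(config)
  on_stage <- as.logical(unlist(config$stages))
  names(on_stage) <- names(config$stages)
  report <- list(fingerprint = fp, seed = config$seed, errors = list())
  failed <- character()

  run_stage <- function(name, deps, fn) {
    if (!isTRUE(on_stage[[name]])) return(NULL)
    if (any(deps %in% failed)) {
      report$errors[[name]] <<- paste("skipped: upstream failure in",
                                      paste(intersect(deps, failed),
                                            collapse = ", "))
      failed <<- c(failed, name)
      return(NULL)
    }
    tryCatch(fn(), error = function(e) {
      report$errors[[name]] <<- conditionMessage(e)
      failed <<- c(failed, name)
      NULL
    })
  }

  sc <- config$screen
  sim <- run_stage("simulate", character(), function() {
    cfg <- screen_sim_config(
      n_plates = sc$n_plates, wells_per_plate = sc$wells_per_plate,
      n_high_controls = sc$n_high_controls,
      n_low_controls = sc$n_low_controls,
      high_mean = sc$high_mean, low_mean = sc$low_mean, cv = sc$cv,
      class_fractions = unlist(sc$class_fractions),
      sd_pct = sc$sd_pct, n_replicates = sc$n_replicates,
      seed = derive_seed(config$seed, "screen"))
    ps <- generate_plate_set(cfg)
    conf <- generate_replicate_activations(ps$truth, cfg, "erse",
                                           n_dmso = sc$n_dmso)
    ctr <- generate_replicate_activations(ps$truth, cfg, "xbp1",
                                          n_dmso = sc$n_dmso)
    list(cfg = cfg, plates = ps$plates, truth = ps$truth,
         confirmation = conf, counterscreen = ctr)
  })

  qc <- run_stage("qc", "simulate", function() {
    normalize_plate_set(sim$plates,
                        zprime_floor = config$triage$zprime_floor)
  })
  report$qc <- qc$qc

  tri <- run_stage("triage", "qc", function() {
    rec <- build_compound_records(qc$activations,
                                  sim$confirmation$compounds,
                                  sim$counterscreen$compounds)
    run_funnel(rec, sim$confirmation$dmso,
               triage_config(config$triage$primary_cutoff,
                             config$triage$confirmation_sd_mult,
                             config$triage$selectivity_fold,
                             config$triage$blacklist))
  })
  report$triage <- if (!is.null(tri)) {
    tri[c("counts", "confirmation_cutoff", "confirmation_rate_pct")]
  }

  expr_res <- run_stage("expression", "triage", function() {
    ids <- tri$records$compound_id[tri$records$stringent]
    ids <- utils::head(ids, config$expression$profile_max)
    if (!length(ids)) stop("no stringent compounds to profile")
    classes <- sim$truth$class[match(ids, sim$truth$compound_id)]
    prof <- generate_expression_profiles(
      classes, sd_log = config$expression$sd_log,
      seed = derive_seed(config$seed, "expression_stage"))
    calls <- classify_all_profiles(
      prof$expr, prof$genesets,
      min_fold = config$expression$min_fold,
      alpha = config$expression$alpha,
      global_floor = config$expression$global_floor,
      activity_floor = config$expression$activity_floor)
    # generated condition ids are positional; map back to screen compounds
    calls$compound <- ids[match(calls$compound, prof$truth$condition)]
    list(calls = calls, truth_class = classes)
  })
  report$expression <- expr_res$calls

  cw <- NULL
  if (!is.null(tri) && !is.null(expr_res)) {
    cw <- crosswalk(tri$records, expr_res$calls)
  }
  report$crosswalk <- cw

  img <- run_stage("imaging", c("triage", "expression"), function() {
    im <- config$imaging
    top <- utils::head(cw$compound_id, im$n_compounds)
    if (!length(top)) stop("no compounds to image")
    classes <- sim$truth$class[match(top, sim$truth$compound_id)]
    fracs <- unlist(im$class_fractions)[classes]
    seed_i <- derive_seed(config$seed, "imaging_stage")
    mk <- function(label, frac, contam) {
      generate_cell_ratios(im$n_wells, im$cells_per_well, frac,
                           contamination = contam, treatment = label,
                           seed = seed_i)$cells
    }
    cells <- rbind(mk("vehicle", 0, im$contamination),
                   mk("Tg", im$stressor_fraction, 0))
    for (i in seq_along(top)) {
      cells <- rbind(cells, mk(top[i], fracs[i], im$contamination))
    }
    q <- quantify_translocation(cells, "Tg", "vehicle",
                                bin_width = im$bin_width)
    list(threshold = q$threshold$threshold, wells = q$wells,
         cutoff = q$hits$cutoff, calls = q$hits$calls,
         truth = data.frame(compound_id = top, class = classes,
                            planted_fraction = fracs,
                            stringsAsFactors = FALSE))
  })
  report$imaging <- img[c("threshold", "cutoff", "calls")]

  kin <- run_stage("kinetics", character(), function() {
    kc <- config$kinetics
    seed_k <- derive_seed(config$seed, "kinetics_stage")
    veh <- generate_chase_data(kc$vehicle$ks, kc$vehicle$kd, kc$t_points,
                               kc$label0, kc$noise_cv, kc$n_replicates,
                               "vehicle", seed = seed_k)
    trt <- generate_chase_data(kc$treated$ks, kc$treated$kd, kc$t_points,
                               kc$label0, kc$noise_cv, kc$n_replicates,
                               "treated", seed = seed_k + 1L)
    series <- rbind(veh$series, trt$series)
    fr <- chase_fraction_table(series, vehicle = "vehicle")
    rates <- lapply(list(vehicle = veh$series, treated = trt$series),
                    estimate_rates)
    dr <- generate_dose_response(kc$doses, kc$dr_bottom, kc$dr_top,
                                 kc$dr_ec50, kc$dr_slope,
                                 noise_cv = kc$noise_cv,
                                 seed = seed_k + 2L)
    fit <- fit_4pl(dr$dr$dose, dr$dr$response)
    list(fractions = fr,
         rates = lapply(rates, function(r) r[c("ks", "kd", "label0")]),
         ec50 = fit$ec50, dr_fit = fit[c("bottom", "top", "ec50",
                                         "slope", "extrapolated")])
  })
  report$kinetics <- kin[c("rates", "ec50")]

  out <- structure(report, class = "run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stamp <- function(df) { df$config_fingerprint <- fp; df }
    if (!is.null(sim)) write_plate_csv(sim$plates,
                                       file.path(out_dir, "plates.csv"))
    if (!is.null(qc)) {
      utils::write.csv(stamp(qc$activations),
                       file.path(out_dir, "activations.csv"),
                       row.names = FALSE)
      utils::write.csv(stamp(qc$qc), file.path(out_dir, "plate_qc.csv"),
                       row.names = FALSE)
    }
    if (!is.null(tri)) {
      utils::write.csv(stamp(tri$records),
                       file.path(out_dir, "triage_flags.csv"),
                       row.names = FALSE)
    }
    if (!is.null(expr_res)) {
      utils::write.csv(stamp(expr_res$calls),
                       file.path(out_dir, "upr_calls.csv"),
                       row.names = FALSE)
    }
    if (!is.null(cw)) {
      utils::write.csv(stamp(cw), file.path(out_dir, "priority.csv"),
                       row.names = FALSE)
    }
    if (!is.null(img)) {
      utils::write.csv(stamp(img$wells),
                       file.path(out_dir, "imaging_wells.csv"),
                       row.names = FALSE)
    }
    if (!is.null(kin)) {
      utils::write.csv(stamp(kin$fractions),
                       file.path(out_dir, "chase_fractions.csv"),
                       row.names = FALSE)
    }
    write_json_report(report_to_json(out), file.path(out_dir,
                                                     "report.json"))
    writeLines(format_report_md(out), file.path(out_dir, "report.md"))
  }
  out
}

# Flatten a run_report into JSON-friendly plain lists.
report_to_json <- function(report) {
  list(fingerprint = report$fingerprint, seed = report$seed,
       funnel_counts = as.list(report$triage$counts),
       confirmation_cutoff = report$triage$confirmation_cutoff,
       confirmation_rate_pct = report$triage$confirmation_rate_pct,
       n_priority = if (!is.null(report$crosswalk)) {
         sum(report$crosswalk$priority)
       },
       imaging_cutoff = report$imaging$cutoff,
       imaging_threshold = report$imaging$threshold,
       kinetics = report$kinetics,
       errors = report$errors)
}

format_report_md <- function(report) {
  c("# Pipeline run report",
    sprintf("- config fingerprint: `%s`; seed: %d", report$fingerprint,
            report$seed),
    if (!is.null(report$triage)) c(
      "## Funnel",
      sprintf("- %s: %d", names(report$triage$counts),
              report$triage$counts),
      sprintf("- confirmation rate: %.1f%%",
              report$triage$confirmation_rate_pct)),
    if (!is.null(report$crosswalk)) sprintf(
      "## Priority compounds: %d", sum(report$crosswalk$priority)),
    if (length(report$errors)) c("## Errors",
                                 sprintf("- %s: %s", names(report$errors),
                                         unlist(report$errors))))
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report (fingerprint", x$fingerprint, ", seed",
      x$seed, ")\n")
  if (!is.null(x$triage)) {
    cat("  funnel:", paste(names(x$triage$counts), x$triage$counts,
                           sep = "=", collapse = " "), "\n")
  }
  if (!is.null(x$crosswalk)) {
    cat("  priority compounds:", sum(x$crosswalk$priority), "\n")
  }
  if (length(x$errors)) {
    cat("  errors:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}
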