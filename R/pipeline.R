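#' Pipeline configuration
#'
#' Collects every analysis constant in one place so sensitivity analyses
#' are configuration-only: the synthetic profile, seed, analysis channel,
#' the canonical frequency bands (delta 1--4, theta 4--7, alpha 8--12,
#' beta 13--30 Hz), the post-cue ROI window, the pre-cue baseline window,
#' the TFR crop window, and per-stage toggles.
#'
#' @param profile A [synthetic_profile()] (default [profile_paper_default()]).
#' @param seed Seed recorded in every output (default: profile seed).
#' @param channel Analysis channel (default "Cz").
#' @param bands Named list of `c(f_lo, f_hi)` Hz bands.
#' @param roi_window `c(lo, hi)` seconds post-cue (default 0.3--0.4).
#' @param baseline `c(lo, hi)` seconds pre-cue (default -0.3..-0.2).
#' @param tfr_window TFR output crop, seconds (default -0.5..1.5; analyses
#'   here only read the baseline and ROI windows).
#' @param out_dir Output directory.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "behavior", "spectral", "erp", "stats", "report")`.
#' @return A `tf_config` list.
#' @export
pipeline_config <- function(profile = profile_paper_default(),
                            seed = NULL,
                            channel = "Cz",
                            bands = list(delta = c(1, 4), theta = c(4, 7),
                                         alpha = c(8, 12), beta = c(13, 30)),
                            roi_window = c(0.3, 0.4),
                            baseline = c(-0.3, -0.2),
                            tfr_window = c(-0.5, 1.5),
                            out_dir = tempfile("timefront-run-"),
                            stages = c("simulate", "behavior", "spectral",
                                       "erp", "stats", "report")) {
  structure(list(profile = profile, seed = seed %||% profile$seed,
                 channel = channel, bands = bands, roi_window = roi_window,
                 baseline = baseline, tfr_window = tfr_window,
                 out_dir = out_dir, stages = stages),
            class = "tf_config")
}

#' Validate a pipeline configuration
#'
#' Checks every config invariant and returns the violations (an empty
#' character vector means the config is valid): band bounds ordered, bands
#' non-overlapping as listed, baseline strictly pre-event, ROI ordered,
#' profile named, seed present.
#'
#' @param config A [pipeline_config()].
#' @return Character vector of violation messages (empty if ok).
#' @export
validate_config <- function(config) {
  v <- character()
  if (is.null(config$profile) || !inherits(config$profile, "tf_profile")) {
    v <- c(v, "missing or invalid profile")
  } else if (!nzchar(config$profile$name %||% "")) {
    v <- c(v, "missing profile name")
  }
  if (is.null(config$seed) || !is.finite(config$seed)) {
    v <- c(v, "missing seed")
  }
  for (nm in names(config$bands)) {
    b <- config$bands[[nm]]
    if (b[1] >= b[2]) v <- c(v, sprintf("band '%s' bounds reversed", nm))
  }
  bs <- config$bands[order(vapply(config$bands, `[`, 0, 1))]
  if (length(bs) > 1) {
    for (i in seq_len(length(bs) - 1)) {
      if (bs[[i]][2] > bs[[i + 1]][1]) {
        v <- c(v, sprintf("bands '%s' and '%s' overlap",
                          names(bs)[i], names(bs)[i + 1]))
      }
    }
  }
  if (config$baseline[1] >= config$baseline[2] || config$baseline[2] > 0) {
    v <- c(v, "baseline window must be ordered and precede the event")
  }
  if (config$roi_window[1] >= config$roi_window[2]) {
    v <- c(v, "roi window bounds reversed")
  }
  unknown <- setdiff(config$stages, c("simulate", "behavior", "spectral",
                                      "erp", "stats", "report"))
  if (length(unknown)) {
    v <- c(v, paste("unknown stage(s):", paste(unknown, collapse = ", ")))
  }
  v
}

write_stage_csv <- function(x, dir, name) {
  path <- file.path(dir, name)
  write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Chains simulate -> behavior -> spectral -> erp -> stats -> report on the
#' configured profile and writes each stage's tables as CSV plus a manifest
#' (JSON) listing every output file with an MD5 hash, the seed, and the
#' package version. Stages can be toggled off via `config$stages`; a stage
#' failure halts the run after writing a partial manifest naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of stage results (`cohort`, `trials`,
#'   `behavior`, `spectral`, `erp`, `stats`) plus the `manifest`.
#' @export
run_pipeline <- function(config) {
  violations <- validate_config(config)
  if (length(violations)) {
    abort(paste0("invalid config: ", paste(violations, collapse = "; ")))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  profile <- config$profile
  seed <- config$seed
  res <- list()
  files <- character()
  stage_log <- list()
  current <- NA_character_

  run_stage <- function(name, fun) {
    current <<- name
    t0 <- Sys.time()
    out <- fun()
    stage_log[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }
  finalize <- function(status) {
    manifest <- list(
      profile = profile$name, seed = seed, status = status,
      package_version = as.character(utils::packageVersion("timefront")),
      stages = stage_log,
      files = lapply(files, function(f) {
        list(path = basename(f), md5 = unname(tools::md5sum(f)))
      }))
    mpath <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
    manifest
  }

  tryCatch({
    intervals <- sort(unique(profile$behavior$interval))
    on <- function(s) s %in% config$stages

    if (on("simulate")) {
      res$cohort <- run_stage("simulate", function() {
        simulate_cohort(profile, seed = seed)
      })
      res$trials <- purrr::map_dfr(intervals, function(iv) {
        simulate_behavior(res$cohort, profile, iv, seed = seed)
      })
      files <- c(files,
                 write_stage_csv(res$cohort, config$out_dir, "subjects.csv"),
                 write_stage_csv(res$trials, config$out_dir, "trials.csv"))
    }

    if (on("behavior")) {
      res$behavior <- run_stage("behavior", function() {
        filter_subjects(keypress_summary(res$trials))
      })
      files <- c(files, write_stage_csv(res$behavior, config$out_dir,
                                        "behavior_summary.csv"))
    }

    bank <- morlet_bank(fs = profile$fs)
    droi <- roi_spec(config$bands$delta, config$roi_window)
    if (on("spectral") || on("erp") || on("stats")) {
      spec_out <- run_stage("spectral", function() {
        pipeline_eeg_stage(res, profile, config, bank, droi,
                           do_erp = on("erp"))
      })
      if (on("spectral")) {
        res$spectral <- spec_out$roi
        files <- c(files, write_stage_csv(spec_out$roi, config$out_dir,
                                          "roi_power.csv"))
      }
      if (on("erp")) {
        current <- "erp"
        res$erp <- spec_out$erp
        # ERP features are computed alongside the spectral pass (one
        # epoch simulation per subject); logged as their own stage
        stage_log[["erp"]] <- list(seconds = 0,
                                   note = "computed with spectral stage")
        files <- c(files, write_stage_csv(spec_out$erp, config$out_dir,
                                          "erp_features.csv"))
      }
      res$trial_power <- spec_out$trial_power
    }

    if (on("stats")) {
      res$stats <- run_stage("stats", function() {
        pipeline_stats_stage(res, profile, config)
      })
      files <- c(files,
                 write_stage_csv(res$stats$group_tests, config$out_dir,
                                 "stats_group_tests.csv"),
                 write_stage_csv(res$stats$correlations, config$out_dir,
                                 "stats_correlations.csv"),
                 write_stage_csv(res$stats$lmm_terms, config$out_dir,
                                 "stats_lmm_terms.csv"))
    }

    if (on("report")) {
      run_stage("report", function() {
        summary_path <- file.path(config$out_dir, "summary.txt")
        writeLines(pipeline_summary_lines(res, profile, seed), summary_path)
        files <<- c(files, summary_path)
        NULL
      })
    }
    res$manifest <- finalize("ok")
    invisible(res)
  }, error = function(e) {
    finalize(paste0("failed at stage '", current, "': ",
                    conditionMessage(e)))
    abort(sprintf("pipeline stage '%s' failed: %s", current,
                  conditionMessage(e)), parent = e)
  })
}

# EEG stage: per subject and interval, simulate epochs, TFR at the analysis
# channel, per-trial and mean ROI dB, and ERP features. Subjects are
# processed one at a time to bound memory.
pipeline_eeg_stage <- function(res, profile, config, bank, droi,
                               do_erp = TRUE) {
  intervals <- sort(unique(res$trials$interval))
  roi_rows <- list()
  erp_rows <- list()
  tp_rows <- list()
  for (iv in intervals) {
    tr_iv <- dplyr::filter(res$trials, .data$interval == iv)
    for (id in unique(tr_iv$subject)) {
      sub <- res$cohort[res$cohort$id == id, ]
      tr <- dplyr::filter(tr_iv, .data$subject == id)
      ep <- simulate_eeg_epochs(sub, tr, profile,
                                seed = child_seed(config$seed, 100 + iv))[[1]]
      if (length(ep$channels) > 1) ep <- average_reference(ep)
      tfr <- morlet_tfr(ep, bank, channel = config$channel,
                        window = config$tfr_window)
      dbm <- db_normalize(tfr, config$baseline)
      band_db <- vapply(config$bands, function(b) {
        tf_roi_mean(dbm, roi_spec(b, config$roi_window))
      }, 0)
      roi_rows[[length(roi_rows) + 1L]] <- tibble(
        subject = id, group = sub$group, interval = iv,
        band = names(band_db), roi_db = unname(band_db))
      tp_rows[[length(tp_rows) + 1L]] <- tibble(
        subject = id, group = sub$group, interval = iv, trial = tr$trial,
        keypress = tr$keypress, moca = sub$moca,
        delta = tf_roi_trials(tfr, droi, config$baseline))
      if (do_erp) {
        erp <- erp_average(ep, channel = config$channel)
        erp_rows[[length(erp_rows) + 1L]] <- dplyr::bind_rows(
          peak_to_trough(erp, c(0.15, 0.3), c(0.2, 0.35),
                         component = "P2-N2"),
          cnv_amplitude(erp, iv)) |>
          dplyr::mutate(subject = id, group = sub$group, interval = iv,
                        alignment = "cue")
      }
    }
  }
  list(roi = dplyr::bind_rows(roi_rows),
       erp = if (do_erp) dplyr::bind_rows(erp_rows) else NULL,
       trial_power = dplyr::bind_rows(tp_rows))
}

# run one statistic, recording a note instead of halting the stage when the
# cohort is too small for it (e.g. mediation needs >= 20 complete cases)
try_stat <- function(name, notes_env, expr) {
  tryCatch(expr, error = function(e) {
    notes_env$notes <- c(notes_env$notes,
                         sprintf("%s skipped: %s", name,
                                 conditionMessage(e)))
    NULL
  })
}

# statistics stage over the behavioral + spectral tables
pipeline_stats_stage <- function(res, profile, config) {
  beh <- dplyr::left_join(
    res$behavior,
    dplyr::select(res$cohort, "id", "moca", "mupdrs"),
    by = c(subject = "id"))
  ivs <- sort(unique(beh$interval))
  long_iv <- max(ivs)

  gt <- purrr::map_dfr(ivs, function(iv) {
    b <- dplyr::filter(beh, .data$interval == iv)
    dplyr::mutate(
      group_ttest(b$cv[b$group == "CTL"], b$cv[b$group == "PD"]),
      measure = "cv", interval = iv)
  })
  roi_d <- dplyr::filter(res$spectral, .data$band == "delta")
  gt <- dplyr::bind_rows(gt, purrr::map_dfr(ivs, function(iv) {
    r <- dplyr::filter(roi_d, .data$interval == iv)
    dplyr::mutate(
      group_ttest(r$roi_db[r$group == "CTL"], r$roi_db[r$group == "PD"]),
      measure = "delta_db", interval = iv)
  }))

  bl <- dplyr::filter(beh, .data$interval == long_iv)
  pd <- dplyr::filter(bl, .data$group == "PD")
  ctl <- dplyr::filter(bl, .data$group == "CTL")
  notes <- new.env()
  notes$notes <- character()
  cors <- dplyr::bind_rows(
    try_stat("PD moca~cv correlation", notes,
             dplyr::mutate(spearman_cor(pd$moca, pd$cv),
                           pair = "moca~cv", group = "PD")),
    try_stat("CTL moca~cv correlation", notes,
             dplyr::mutate(spearman_cor(ctl$moca, ctl$cv),
                           pair = "moca~cv", group = "CTL")))
  rz <- if (nrow(cors) == 2) {
    fisher_rz_compare(cors$rho[1], cors$n[1], cors$rho[2], cors$n[2])
  }

  hreg <- try_stat("hierarchical regression", notes,
                   hierarchical_regression(pd))

  delta_l <- dplyr::filter(roi_d, .data$interval == long_iv)
  med_d <- dplyr::inner_join(
    dplyr::select(delta_l, "subject", power = "roi_db"),
    dplyr::select(bl, "subject", "cv", "moca"), by = "subject")
  med <- try_stat("mediation", notes,
                  mediation_boot(med_d, "power", "cv", "moca",
                                 seed = child_seed(config$seed, 900)))

  lmm <- lmm_trialwise(res$trial_power)
  slopes <- subject_slopes(
    dplyr::filter(res$trial_power, .data$interval == long_iv))

  list(group_tests = gt, correlations = cors, fisher = rz,
       hierarchical = hreg, mediation = med, lmm = lmm,
       lmm_terms = lmm$fixed, slopes = slopes, notes = notes$notes)
}

pipeline_summary_lines <- function(res, profile, seed) {
  c(sprintf("timefront pipeline report - profile '%s', seed %s",
            profile$name, format(seed)),
    sprintf("subjects: %d, trials: %d", nrow(res$cohort),
            nrow(res$trials)),
    if (!is.null(res$stats)) c(
      "group tests (CTL vs PD):",
      utils::capture.output(as.data.frame(res$stats$group_tests)),
      "correlations:",
      utils::capture.output(as.data.frame(res$stats$correlations)),
      sprintf("LMM: R^2 = %.2f, full-model AIC = %.1f",
              res$stats$lmm$r_squared,
              res$stats$lmm$aic$aic[res$stats$lmm$aic$model == "full"])))
}
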