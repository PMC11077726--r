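# End-to-end orchestration: simulate cohort -> preprocess -> ERP + ITPC
# tables -> statistical battery -> CSV/JSON outputs with a hashed manifest.

#' Analyse one subject's ERP session
#'
#' Down-samples, epochs on the stimulus-onset events, baseline-corrects over
#' the 250 ms pre-stimulus window, detrends, screens artifacts, averages and
#' extracts P1/N1/P2 peaks for each channel.
#'
#' @param recording the subject's ERP `eeg_recording`.
#' @param target_rate_hz analysis rate (default 1024).
#' @param window_ms epoch window, ms around sound onset.
#' @param baseline_ms baseline window, ms.
#' @param peak_windows see [detect_peaks()].
#' @param strict exclude artifact-flagged trials from averages.
#' @return list with `peaks` and `erps` per channel.
#' @export
analyze_subject_erp <- function(recording, target_rate_hz = 1024,
                                window_ms = c(-250, 750),
                                baseline_ms = c(-250, 0),
                                peak_windows = default_peak_windows(),
                                strict = FALSE) {
  rec <- downsample_recording(recording, target_rate_hz)
  ep <- extract_epochs(rec, erp_events(rec), window_ms)
  ep <- baseline_correct(ep, baseline_ms)
  ep <- detrend_epochs(ep)
  ep <- screen_artifacts(ep)
  erps <- lapply(names(ep$channels), function(ch)
    average_erp(ep, ch, strict = strict))
  names(erps) <- names(ep$channels)
  peaks <- lapply(erps, detect_peaks, windows = peak_windows)
  list(peaks = peaks, erps = erps)
}

#' Analyse one subject's gap-ASSR session
#'
#' Down-samples, epochs on the gapped-segment onsets (the 250 ms segment
#' plus 100 ms context each side for wavelet edge handling), screens
#' artifacts and computes the mean 40 Hz ITPC per parametric pair.
#'
#' @param recording the subject's gap-ASSR `eeg_recording`.
#' @param target_rate_hz analysis rate (default 1024).
#' @param window_ms epoch window, ms around gapped-segment onset.
#' @param params [morlet_params()] for the transform.
#' @param summary_window_ms 40 Hz averaging window, ms.
#' @param strict exclude artifact-flagged trials.
#' @param min_trials_warn warn for pairs below this trial count.
#' @return list of `itpc_summary` tables per channel.
#' @export
analyze_subject_itpc <- function(recording, target_rate_hz = 1024,
                                 window_ms = c(-100, 350),
                                 params = morlet_params(),
                                 summary_window_ms = c(50, 250),
                                 strict = FALSE, min_trials_warn = 100) {
  rec <- downsample_recording(recording, target_rate_hz)
  ep <- extract_epochs(rec, assr_events(rec), window_ms)
  ep <- screen_artifacts(ep)
  out <- lapply(names(ep$channels), function(ch)
    itpc_by_pair(ep, channel = ch, params = params,
                 window_ms = summary_window_ms, strict = strict,
                 min_trials_warn = min_trials_warn))
  names(out) <- names(ep$channels)
  out
}

#' Build group tables for a simulated cohort
#'
#' Runs the per-subject ERP and/or ITPC analyses across a cohort and
#' assembles the long-format group tables consumed by
#' [run_paper_contrasts()].
#'
#' @param cohort an [simulate_cohort()] result.
#' @param target_rate_hz analysis rate (default 1024).
#' @param itpc_params [morlet_params()] used for the ITPC analysis.
#' @param summary_window_ms 40 Hz ITPC averaging window.
#' @param peak_windows ERP peak search windows.
#' @param min_trials_warn see [itpc_by_pair()].
#' @return list with `erp_table`, `itpc_table` (either may be NULL) and the
#'   per-subject grand-average `erps`.
#' @export
cohort_tables <- function(cohort, target_rate_hz = 1024,
                          itpc_params = morlet_params(),
                          summary_window_ms = c(50, 250),
                          peak_windows = default_peak_windows(),
                          min_trials_warn = 100) {
  erp_res <- list()
  itpc_res <- list()
  erps <- list()
  for (s in cohort) {
    if (!is.null(s$erp)) {
      a <- analyze_subject_erp(s$erp, target_rate_hz,
                               peak_windows = peak_windows)
      erp_res[[length(erp_res) + 1L]] <- list(spec = s$spec, peaks = a$peaks)
      erps[[s$spec$subject_id]] <- a$erps
    }
    if (!is.null(s$assr)) {
      it <- analyze_subject_itpc(s$assr, target_rate_hz,
                                 params = itpc_params,
                                 summary_window_ms = summary_window_ms,
                                 min_trials_warn = min_trials_warn)
      itpc_res[[length(itpc_res) + 1L]] <- list(spec = s$spec, itpc = it)
    }
  }
  list(erp_table = if (length(erp_res)) erp_group_table(erp_res),
       itpc_table = if (length(itpc_res)) itpc_group_table(itpc_res),
       erps = erps)
}

#' Pipeline run configuration
#'
#' @param out_dir output directory.
#' @param seed master seed recorded in every output.
#' @param design cohort design (default: the female study cells).
#' @param sessions sessions to simulate and analyse.
#' @param n_trials_per_pair gapped segments per parametric pair.
#' @param sim_rate_hz native simulation rate.
#' @param target_rate_hz analysis rate (default: 1024 Hz, capped at the
#'   simulation rate).
#' @param itpc_params,summary_window_ms,peak_windows analysis parameters.
#' @param make_figures write figures (requires ggplot2).
#' @param resume skip stages whose output files already exist.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1, design = default_cohort_design(),
                       sessions = c("erp", "assr"), n_trials_per_pair = 101,
                       sim_rate_hz = 4096, target_rate_hz = NULL,
                       itpc_params = morlet_params(),
                       summary_window_ms = c(50, 250),
                       peak_windows = default_peak_windows(),
                       make_figures = FALSE, resume = FALSE) {
  target_rate_hz <- target_rate_hz %||% min(1024, sim_rate_hz)
  structure(list(out_dir = out_dir, seed = seed, design = design,
                 sessions = sessions, n_trials_per_pair = n_trials_per_pair,
                 sim_rate_hz = sim_rate_hz, target_rate_hz = target_rate_hz,
                 itpc_params = itpc_params,
                 summary_window_ms = summary_window_ms,
                 peak_windows = peak_windows, make_figures = make_figures,
                 resume = resume),
            class = "run_config")
}

write_csv_out <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' simulate -> preprocess -> ERP + ITPC tables -> statistics -> outputs.
#' Writes the cohort manifest, group tables, ANOVA/contrast/diagnostic
#' tables, the serialized configuration and a manifest JSON listing every
#' output file with its MD5 hash.  Deterministic under the configured seed.
#' With `resume = TRUE`, stages whose table outputs already exist on disk
#' are reloaded instead of recomputed.
#'
#' @param config a [run_config()].
#' @return the manifest list, invisibly; stage results in `$results`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character(0)
  status <- list()

  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- expr
    status[[stage]] <<- list(ok = TRUE,
                             elapsed_s = proc.time()[["elapsed"]] - t0)
    message(sprintf("[%s] done in %.1f s", stage, status[[stage]]$elapsed_s))
    res
  }

  have <- function(f) config$resume && file.exists(out(f))

  # stage 1-2: simulate + tables
  if (have("itpc_table.csv") || have("erp_table.csv")) {
    tables <- list(
      erp_table = if (file.exists(out("erp_table.csv")))
        utils::read.csv(out("erp_table.csv")),
      itpc_table = if (file.exists(out("itpc_table.csv")))
        utils::read.csv(out("itpc_table.csv")))
    cohort <- NULL
    message("[simulate/tables] reloaded from checkpoint")
  } else {
    cohort <- tick("simulate", simulate_cohort(
      config$design, seed = config$seed, sessions = config$sessions,
      n_trials_per_pair = config$n_trials_per_pair,
      sample_rate_hz = config$sim_rate_hz))
    files <- c(files, write_csv_out(cohort_manifest(cohort),
                                    out("cohort_manifest.csv")))
    tables <- tick("tables", cohort_tables(
      cohort, target_rate_hz = config$target_rate_hz,
      itpc_params = config$itpc_params,
      summary_window_ms = config$summary_window_ms,
      peak_windows = config$peak_windows,
      min_trials_warn = if (config$n_trials_per_pair > 100) 100 else 0))
    if (!is.null(tables$erp_table))
      files <- c(files, write_csv_out(tables$erp_table, out("erp_table.csv")))
    if (!is.null(tables$itpc_table)) {
      files <- c(files, write_csv_out(tables$itpc_table, out("itpc_table.csv")))
      files <- c(files, write_csv_out(collapse_gaps(tables$itpc_table),
                                      out("itpc_collapsed.csv")))
    }
  }

  # stage 3: statistics
  report <- tick("stats", run_paper_contrasts(tables$erp_table,
                                              tables$itpc_table))
  if (!is.null(report$contrasts))
    files <- c(files, write_csv_out(report$contrasts, out("contrasts.csv")))
  if (!is.null(report$diagnostics))
    files <- c(files, write_csv_out(report$diagnostics, out("diagnostics.csv")))
  if (length(report$anovas)) {
    anova_tab <- do.call(rbind, lapply(names(report$anovas), function(k) {
      a <- report$anovas[[k]]
      df <- as.data.frame(a)
      if (is.null(df$stratum)) {
        df <- data.frame(effect = df$effect, stratum = NA, df1 = df$df,
                         df2 = NA, sum_sq = df$sum_sq, F = df$F, p = df$p,
                         p_gg = NA, p_reported = df$p_reported)
      }
      cbind(analysis = k, df,
            epsilon_gg = attr(a, "epsilon_gg") %||% NA,
            mauchly_p = attr(a, "mauchly_p") %||% NA)
    }))
    files <- c(files, write_csv_out(anova_tab, out("anovas.csv")))
  }

  # stage 4: figures (optional)
  if (isTRUE(config$make_figures) &&
      requireNamespace("ggplot2", quietly = TRUE) &&
      !is.null(tables$itpc_table)) {
    p <- plot_itpc_curves(tables$itpc_table)
    f <- out("itpc_curves.png")
    ggplot2::ggsave(f, p, width = 8, height = 6, dpi = 150)
    files <- c(files, f)
  }

  # config + manifest
  cfg <- config[setdiff(names(config), "itpc_params")]
  cfg$itpc_freqs_hz <- config$itpc_params$freqs_hz
  jsonlite::write_json(cfg, out("config.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  files <- c(files, out("config.json"))
  manifest <- list(seed = config$seed,
                   files = data.frame(file = basename(files),
                                      md5 = unname(tools::md5sum(files))),
                   stages = status)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  manifest$results <- list(tables = tables, report = report)
  invisible(manifest)
}
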