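# Directional pattern-recovery simulation: does the full pipeline, run on
# cohorts drawn from the documented presets, reproduce the qualitative
# group-level pattern (frontal-cortex genotype deficit at p21 in females,
# clean auditory cortex, no WT sex differences)?

#' Qualitative pattern-recovery study
#'
#' For each replicate seed, simulates a gap-ASSR cohort (female WT/KO cells
#' at the study sizes plus WT males), runs the ITPC pipeline and the
#' repeated-measures battery, and scores three directional outcomes:
#' a significant FC genotype contrast at p21 in females at both modulation
#' depths (`fc_p21`), no significant AC genotype contrast in females at any
#' age or depth (`ac_clean`), and no significant WT sex contrast anywhere
#' (`wt_sex_clean`).  Problem sizes default to a scaled-down configuration
#' (60 trials per pair -- enough that the ITPC small-sample bias floor sits
#' well below the weakly locked conditions -- and native 1024 Hz
#' simulation) chosen for desk-scale replicate counts; this is directional
#' emulation, not reproduction of any particular F or p value.
#'
#' @param n_seeds number of replicate cohorts.
#' @param seed master seed; replicate r uses `seed + r - 1`.
#' @param design cohort design; default female study cells plus WT males.
#' @param n_trials_per_pair gapped segments per parametric pair.
#' @param sim_rate_hz native simulation rate.
#' @param target_rate_hz analysis rate.
#' @param alpha significance level.
#' @param verbose print one line per replicate.
#' @return data frame with one row per seed and logical columns `fc_p21`,
#'   `ac_clean`, `wt_sex_clean`, `pattern` (all three); success rates in
#'   attribute `"rates"`.
#' @export
pattern_recovery_study <- function(n_seeds = 20, seed = 1, design = NULL,
                                   n_trials_per_pair = 60,
                                   sim_rate_hz = 1024, target_rate_hz = 1024,
                                   alpha = 0.05, verbose = FALSE) {
  if (is.null(design)) {
    design <- rbind(default_cohort_design("F"),
                    default_cohort_design("M")[
                      default_cohort_design("M")$genotype == "WT", ])
  }
  rows <- vector("list", n_seeds)
  for (r in seq_len(n_seeds)) {
    cohort <- simulate_cohort(design, seed = seed + r - 1, sessions = "assr",
                              n_trials_per_pair = n_trials_per_pair,
                              sample_rate_hz = sim_rate_hz)
    tabs <- suppressWarnings(cohort_tables(
      cohort, target_rate_hz = target_rate_hz,
      itpc_params = morlet_params(freqs_hz = 40), min_trials_warn = 0))
    rep_ <- run_paper_contrasts(itpc_table = tabs$itpc_table, alpha = alpha)
    ct <- rep_$contrasts
    gdev <- ct[ct$analysis == "itpc_genotype_dev" & ct$cohort == "sex=F", ]
    fc_p21 <- all(gdev$significant[gdev$channel == "FC" & gdev$by == "p21"]) &&
      any(gdev$channel == "FC" & gdev$by == "p21")
    ac_clean <- !any(gdev$significant[gdev$channel == "AC"])
    wt_sex <- ct[ct$analysis == "itpc_sex" & ct$cohort == "genotype=WT", ]
    wt_sex_clean <- !any(wt_sex$significant)
    rows[[r]] <- data.frame(seed = seed + r - 1, fc_p21 = fc_p21,
                            ac_clean = ac_clean, wt_sex_clean = wt_sex_clean,
                            pattern = fc_p21 && ac_clean && wt_sex_clean)
    if (verbose)
      message(sprintf("seed %d: fc_p21=%s ac_clean=%s wt_sex_clean=%s",
                      seed + r - 1, fc_p21, ac_clean, wt_sex_clean))
  }
  out <- do.call(rbind, rows)
  structure(out, rates = colMeans(out[, c("fc_p21", "ac_clean",
                                          "wt_sex_clean", "pattern")]))
}
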