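# The full grid of group-level analyses: repeated-measures ANOVAs with
# Sidak contrasts for the gap-ASSR ITPC tables, and factorial ANOVAs with
# Tukey/Bonferroni post hocs for the ERP peak tables.  Cortical regions and
# modulation depths are analysed separately throughout.

has_cells <- function(tab, factor, min_n = 2) {
  cnt <- table(unique(tab[, c("subject", factor, "age_group")])[[factor]],
               unique(tab[, c("subject", factor, "age_group")])$age_group)
  nrow(cnt) == 2 && ncol(cnt) == 3 && all(cnt >= min_n)
}

# is any ANOVA effect involving `factor` significant (reported p)?
omnibus_gate <- function(an, factor, alpha) {
  sel <- grepl(factor, an$effect, fixed = TRUE) & !grepl("Error", an$effect)
  ps <- an$p_reported[sel]
  list(p = suppressWarnings(min(ps, na.rm = TRUE)),
       significant = any(ps <= alpha, na.rm = TRUE))
}

#' Run the group-level analysis battery
#'
#' Executes, for every cortical region and modulation depth separately:
#' three-way repeated-measures ANOVAs (genotype x age between, gap duration
#' within) on the ITPC tables per sex, two-way repeated-measures ANOVAs
#' (sex x gap duration) per genotype and age, with Sidak-corrected
#' age-wise contrasts on gap-collapsed ITPC (each age tested against its
#' own error variance, since ITPC estimation noise shrinks as ITPC grows);
#' and two-way factorial ANOVAs
#' (genotype x age, or sex x age) on every ERP wave amplitude and latency
#' with Tukey (age pairs within group) and Bonferroni (group within age)
#' post hocs, plus residual normality diagnostics.  Post hoc contrasts are
#' protected: a contrast is flagged significant only when the ANOVA shows a
#' significant effect involving the contrasted factor (after any
#' Greenhouse-Geisser correction) and the adjusted contrast p is below
#' `alpha`.
#'
#' @param erp_table output of [erp_group_table()] (or NULL to skip).
#' @param itpc_table output of [itpc_group_table()] (or NULL to skip).
#' @param alpha significance level.
#' @param gg_policy sphericity policy passed to [rm_anova()].
#' @param posthoc_itpc adjustment for ITPC contrasts (default Sidak).
#' @param posthoc_erp_group,posthoc_erp_age adjustments for the ERP
#'   group-within-age and age-within-group contrasts.
#' @return an object of class `contrast_report`: `anovas` (named list of
#'   `anova_result`s), `contrasts` (flat data frame), `diagnostics`.
#' @export
run_paper_contrasts <- function(erp_table = NULL, itpc_table = NULL,
                                alpha = 0.05, gg_policy = "if_necessary",
                                posthoc_itpc = "sidak",
                                posthoc_erp_group = "bonferroni",
                                posthoc_erp_age = "tukey") {
  anovas <- list()
  contrasts <- list()
  diags <- list()

  add_contrasts <- function(ct, analysis, channel, depth = NA, wave = NA,
                            measure = NA, cohort = NA, gate) {
    contrasts[[length(contrasts) + 1L]] <<- data.frame(
      analysis = analysis, channel = channel, mod_depth_pct = depth,
      wave = wave, measure = measure, cohort = cohort,
      by = ct$by, comparison = ct$comparison, estimate = ct$estimate,
      p_raw = ct$p_raw, p_adj = ct$p_adj, method = ct$method,
      omnibus_p = gate$p, omnibus_significant = gate$significant,
      significant = gate$significant & ct$p_adj <= alpha)
  }

  # ---- gap-ASSR ITPC -----------------------------------------------------
  if (!is.null(itpc_table)) {
    collapsed <- collapse_gaps(itpc_table)
    for (ch in unique(itpc_table$channel)) {
      for (depth in unique(itpc_table$mod_depth_pct)) {
        tab <- itpc_table[itpc_table$channel == ch &
                          itpc_table$mod_depth_pct == depth, , drop = FALSE]
        col <- collapsed[collapsed$channel == ch &
                         collapsed$mod_depth_pct == depth, , drop = FALSE]

        # genotype development, per sex
        for (sx in unique(tab$sex)) {
          sub <- tab[tab$sex == sx, , drop = FALSE]
          if (!has_cells(sub, "genotype")) next
          an <- rm_anova(sub, "itpc", within = "gap_width_ms",
                         subject = "subject",
                         between = c("genotype", "age_group"),
                         gg_policy = gg_policy)
          key <- sprintf("itpc_genotype_dev.%s.%g.%s", ch, depth, sx)
          anovas[[key]] <- an
          gate <- omnibus_gate(an, "genotype", alpha)
          ct <- posthoc(col[col$sex == sx, ], "itpc", "genotype",
                        by = "age_group", method = posthoc_itpc,
                        family = "all", error = "by")
          add_contrasts(ct, "itpc_genotype_dev", ch, depth,
                        cohort = paste0("sex=", sx), gate = gate)
        }

        # sex comparison, per genotype and age
        for (gt in unique(tab$genotype)) {
          sub <- tab[tab$genotype == gt, , drop = FALSE]
          if (length(unique(sub$sex)) < 2) next
          gates <- list()
          ok <- TRUE
          for (ag in c("p21", "p30", "p60")) {
            aa <- sub[sub$age_group == ag, , drop = FALSE]
            if (length(unique(aa$subject)) < 4 ||
                length(unique(aa$sex)) < 2) { ok <- FALSE; break }
            an <- rm_anova(aa, "itpc", within = "gap_width_ms",
                           subject = "subject", between = "sex",
                           gg_policy = gg_policy)
            key <- sprintf("itpc_sex.%s.%g.%s.%s", ch, depth, gt, ag)
            anovas[[key]] <- an
            gates[[ag]] <- omnibus_gate(an, "sex", alpha)
          }
          if (!ok) next
          ct <- posthoc(col[col$genotype == gt, ], "itpc", "sex",
                        by = "age_group", method = posthoc_itpc,
                        family = "all", error = "by")
          for (i in seq_len(nrow(ct))) {
            add_contrasts(ct[i, ], "itpc_sex", ch, depth,
                          cohort = paste0("genotype=", gt),
                          gate = gates[[ct$by[i]]])
          }
        }
      }
    }
  }

  # ---- ERP peaks ---------------------------------------------------------
  if (!is.null(erp_table)) {
    measures <- c(amplitude = "amplitude_uv", latency = "latency_ms")
    for (ch in unique(erp_table$channel)) {
      for (wv in unique(erp_table$wave)) {
        tab <- erp_table[erp_table$channel == ch & erp_table$wave == wv, ,
                         drop = FALSE]
        for (mi in seq_along(measures)) {
          resp <- measures[[mi]]
          mname <- names(measures)[mi]

          # genotype x age, per sex
          for (sx in unique(tab$sex)) {
            sub <- tab[tab$sex == sx, , drop = FALSE]
            if (!has_cells(sub, "genotype")) next
            an <- anova_twoway(sub, resp, "genotype", "age_group")
            key <- sprintf("erp_genotype_dev.%s.%s.%s.%s", ch, wv, mname, sx)
            anovas[[key]] <- an
            dg <- diagnostics(attr(an, "residuals"))
            diags[[key]] <- data.frame(analysis = key,
                                       shapiro_p = dg$shapiro_p,
                                       skewness = dg$skewness,
                                       kurtosis_excess = dg$kurtosis_excess,
                                       within_pm2 = dg$within_pm2)
            gate_g <- omnibus_gate(an, "genotype", alpha)
            gate_a <- omnibus_gate(an, "age_group", alpha)
            ct <- posthoc(sub, resp, "genotype", by = "age_group",
                          method = posthoc_erp_group, family = "all")
            add_contrasts(ct, "erp_genotype_dev", ch, wave = wv,
                          measure = mname, cohort = paste0("sex=", sx),
                          gate = gate_g)
            ct <- posthoc(sub, resp, "age_group", by = "genotype",
                          method = posthoc_erp_age)
            add_contrasts(ct, "erp_age_dev", ch, wave = wv,
                          measure = mname, cohort = paste0("sex=", sx),
                          gate = gate_a)
          }

          # sex x age, per genotype
          for (gt in unique(tab$genotype)) {
            sub <- tab[tab$genotype == gt, , drop = FALSE]
            if (!has_cells(sub, "sex")) next
            an <- anova_twoway(sub, resp, "sex", "age_group")
            key <- sprintf("erp_sex_dev.%s.%s.%s.%s", ch, wv, mname, gt)
            anovas[[key]] <- an
            gate_s <- omnibus_gate(an, "sex", alpha)
            ct <- posthoc(sub, resp, "sex", by = "age_group",
                          method = posthoc_erp_group, family = "all")
            add_contrasts(ct, "erp_sex_dev", ch, wave = wv,
                          measure = mname, cohort = paste0("genotype=", gt),
                          gate = gate_s)
          }
        }
      }
    }
  }

  structure(list(anovas = anovas,
                 contrasts = if (length(contrasts)) do.call(rbind, contrasts),
                 diagnostics = if (length(diags)) do.call(rbind, diags),
                 alpha = alpha),
            class = "contrast_report")
}

#' @export
print.contrast_report <- function(x, ...) {
  cat(sprintf("<contrast_report: %d ANOVAs, %d contrasts (%d significant at alpha = %g)>\n",
              length(x$anovas),
              if (is.null(x$contrasts)) 0 else nrow(x$contrasts),
              if (is.null(x$contrasts)) 0 else sum(x$contrasts$significant),
              x$alpha))
  invisible(x)
}
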