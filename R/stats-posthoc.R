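# Pairwise post hoc contrasts (Tukey / Bonferroni / Sidak) and residual
# normality diagnostics.

#' Multiplicity adjustment of p values
#'
#' Closed forms: Sidak `1 - (1 - p)^m`, Bonferroni `min(1, m p)`; the Tukey
#' adjustment is applied from the studentized range at contrast level (see
#' [posthoc()]).
#'
#' @param p raw p values.
#' @param m number of comparisons in the family.
#' @param method `"bonferroni"` or `"sidak"`.
#' @return adjusted p values.
#' @export
adjust_p <- function(p, m, method = c("bonferroni", "sidak")) {
  method <- match.arg(method)
  switch(method,
         bonferroni = pmin(1, m * p),
         sidak = 1 - (1 - p)^m)
}

#' Pairwise post hoc contrasts between factor-level cell means
#'
#' All pairwise comparisons of the levels of `factor`, optionally within
#' each level of a slicing factor `by`; the error term is the pooled
#' within-cell mean square over all `factor` x `by` cells (Tukey-Kramer
#' standard errors `sqrt(MSE (1/n1 + 1/n2))` accommodate unbalanced cells).
#' The family for adjustment is the set of comparisons within one `by`
#' level; Tukey p values come from the studentized range with `nmeans`
#' equal to the number of `factor` levels.
#'
#' @param data data frame in long format.
#' @param response name of the response column.
#' @param factor name of the factor whose levels are compared.
#' @param by optional name of a slicing factor.
#' @param method `"tukey"`, `"bonferroni"` or `"sidak"`.
#' @param family `"by"` (default): the family for Bonferroni/Sidak is the
#'   set of comparisons within one `by` level; `"all"`: every comparison
#'   returned by the call counts (e.g. one 2-level contrast repeated across
#'   ages forms one family of size 3).
#' @param error `"pooled"` (default): one mean square pooled over all
#'   cells; `"by"`: the error term is estimated within each `by` slice
#'   only, for responses whose variance differs across slices (e.g. ITPC,
#'   whose estimation variance shrinks as the ITPC grows).
#' @return an object of class `contrast_result`: one row per comparison
#'   with `estimate`, `se`, `df`, `statistic`, `p_raw`, `p_adj`.
#' @export
posthoc <- function(data, response, factor, by = NULL,
                    method = c("tukey", "bonferroni", "sidak"),
                    family = c("by", "all"),
                    error = c("pooled", "by")) {
  method <- match.arg(method)
  family <- match.arg(family)
  error <- match.arg(error)
  y <- data[[response]]
  f <- base::factor(data[[factor]])
  g <- if (is.null(by)) base::factor(rep("all", length(y)))
       else base::factor(data[[by]])
  cells <- interaction(f, g, drop = TRUE)
  ncell <- nlevels(cells)
  cell_mean <- tapply(y, cells, mean)
  cell_n <- tapply(y, cells, length)
  resid2 <- (y - cell_mean[cells])^2
  df_all <- length(y) - ncell
  if (df_all <= 0) stop_invalid("no residual degrees of freedom for the error term")
  mse_all <- sum(resid2) / df_all

  rows <- list()
  for (lev in levels(g)) {
    fl <- levels(droplevels(f[g == lev]))
    if (length(fl) < 2) next
    if (error == "by") {
      sel <- g == lev
      df_res <- sum(sel) - length(fl)
      if (df_res <= 0) stop_invalid("no residual df in slice ", lev)
      mse <- sum(resid2[sel]) / df_res
    } else {
      df_res <- df_all
      mse <- mse_all
    }
    cmb <- utils::combn(fl, 2)
    m <- ncol(cmb)
    for (ci in seq_len(m)) {
      k1 <- paste(cmb[1, ci], lev, sep = ".")
      k2 <- paste(cmb[2, ci], lev, sep = ".")
      est <- cell_mean[[k1]] - cell_mean[[k2]]
      se <- sqrt(mse * (1 / cell_n[[k1]] + 1 / cell_n[[k2]]))
      tstat <- est / se
      p_raw <- 2 * stats::pt(-abs(tstat), df_res)
      p_adj <- switch(method,
                      tukey = stats::ptukey(sqrt(2) * abs(tstat),
                                            nmeans = length(fl), df = df_res,
                                            lower.tail = FALSE),
                      adjust_p(p_raw, m, method))
      rows[[length(rows) + 1L]] <- data.frame(
        by = if (is.null(by)) NA_character_ else lev,
        comparison = paste(cmb[1, ci], "-", cmb[2, ci]),
        estimate = est, se = se, df = df_res, statistic = tstat,
        p_raw = p_raw, p_adj = p_adj, method = method)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (family == "all" && method != "tukey") {
    out$p_adj <- adjust_p(out$p_raw, nrow(out), method)
  }
  structure(out, class = c("contrast_result", "data.frame"))
}

#' Residual normality diagnostics
#'
#' Shapiro-Wilk test, sample skewness and kurtosis (both the raw fourth
#' standardized moment and its excess form; the +/- 2 screening rule is
#' applied to skewness and excess kurtosis), and quantile-quantile point
#' pairs.
#'
#' @param residuals numeric vector (n >= 3, non-constant).
#' @return an object of class `residual_diagnostics` with fields
#'   `shapiro_w`, `shapiro_p`, `skewness`, `kurtosis`, `kurtosis_excess`,
#'   `within_pm2` and `qq` (sorted theoretical/empirical quantile pairs).
#' @export
diagnostics <- function(residuals) {
  residuals <- residuals[is.finite(residuals)]
  n <- length(residuals)
  if (n < 3) stop_invalid("need at least 3 residuals")
  if (stats::sd(residuals) == 0) stop_invalid("residuals are constant")
  sw <- stats::shapiro.test(if (n > 5000) residuals[seq_len(5000)] else residuals)
  m <- residuals - mean(residuals)
  m2 <- mean(m^2)
  skew <- mean(m^3) / m2^1.5
  kurt <- mean(m^4) / m2^2
  qq <- stats::qqnorm(residuals, plot.it = FALSE)
  ord <- order(qq$x)
  structure(list(shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
                 skewness = skew, kurtosis = kurt,
                 kurtosis_excess = kurt - 3,
                 within_pm2 = abs(skew) <= 2 && abs(kurt - 3) <= 2,
                 n = n,
                 qq = data.frame(theoretical = qq$x[ord],
                                 empirical = qq$y[ord])),
            class = "residual_diagnostics")
}

#' @export
print.residual_diagnostics <- function(x, ...) {
  cat(sprintf(paste0("Residual diagnostics (n = %d)\n",
                     "  Shapiro-Wilk W = %.4f (p = %.4g)\n",
                     "  skewness = %.3f, excess kurtosis = %.3f (|.| <= 2: %s)\n"),
              x$n, x$shapiro_w, x$shapiro_p, x$skewness, x$kurtosis_excess,
              if (x$within_pm2) "yes" else "no"))
  invisible(x)
}
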