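# Factorial and repeated-measures ANOVA, implemented from matrix algebra.
# Type III sums of squares (sum-to-zero contrasts, each effect adjusted for
# all others) accommodate the unbalanced cells; the repeated-measures
# decomposition follows the classical split-plot strata with Mauchly's
# sphericity test and the Greenhouse-Geisser epsilon-hat correction.

# residual sum of squares of y on X (X may have zero columns)
rss_of <- function(X, y) {
  if (ncol(X) == 0) return(sum(y^2))
  sum(stats::lm.fit(X, y)$residuals^2)
}

# Type III SS for each term of a design matrix with sum-to-zero contrasts:
# drop the term's columns, keep all others.
type3_ss <- function(X, y, assign, terms_idx) {
  full <- rss_of(X, y)
  ss <- vapply(terms_idx, function(t) {
    rss_of(X[, assign != t, drop = FALSE], y) - full
  }, numeric(1))
  list(ss = pmax(ss, 0), rss = full)
}

#' Two-way factorial ANOVA (Type III)
#'
#' Least-squares decomposition with sum-to-zero contrasts; main effects,
#' interaction and residual.  Unbalanced cells are allowed; every cell must
#' contain at least one observation.  With zero within-cell variance the F
#' statistics are reported as `Inf` with p = 0.
#'
#' @param data data frame in long format.
#' @param response name of the response column.
#' @param factor_a,factor_b names of the two factor columns.
#' @return an object of class `anova_result`: one row per effect plus the
#'   residual row, with the model residuals attached as an attribute.
#' @export
anova_twoway <- function(data, response, factor_a, factor_b) {
  y <- data[[response]]
  A <- factor(data[[factor_a]])
  B <- factor(data[[factor_b]])
  if (any(table(A, B) == 0))
    stop_invalid("empty cell(s): every ", factor_a, " x ", factor_b,
                 " combination needs at least one observation")
  mf <- data.frame(A = A, B = B)
  X <- stats::model.matrix(~ A * B, mf,
                           contrasts.arg = list(A = "contr.sum", B = "contr.sum"))
  assign <- attr(X, "assign")
  dec <- type3_ss(X, y, assign, 1:3)
  df_eff <- vapply(1:3, function(t) sum(assign == t), numeric(1))
  df_res <- length(y) - ncol(X)
  ms_res <- dec$rss / df_res
  total_ss <- sum((y - mean(y))^2)
  degenerate <- dec$rss <= 1e-12 * max(total_ss, 1)
  f <- if (degenerate) rep(Inf, 3) else (dec$ss / df_eff) / ms_res
  f[dec$ss == 0 & degenerate] <- 0
  p <- ifelse(is.infinite(f), 0, stats::pf(f, df_eff, df_res, lower.tail = FALSE))
  out <- data.frame(
    effect = c(factor_a, factor_b, paste(factor_a, factor_b, sep = ":"),
               "Residuals"),
    df = c(df_eff, df_res),
    sum_sq = c(dec$ss, dec$rss),
    F = c(f, NA),
    p = c(p, NA))
  out$p_reported <- out$p
  fit_res <- stats::lm.fit(X, y)$residuals
  structure(out, class = c("anova_result", "data.frame"),
            residuals = fit_res, type = "III", kind = "factorial")
}

# orthonormal contrast matrix spanning the within-level differences
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

#' Repeated-measures (split-plot) ANOVA with sphericity handling
#'
#' One within-subject factor with `k` levels (one observation per subject
#' per level) and zero or more crossed between-subject factors.  Between
#' effects are tested against the between-subject stratum, within effects
#' (the within main effect and its interactions with between factors)
#' against the within stratum.  Type III sums of squares throughout.
#' Mauchly's W tests sphericity of the within-level differences; the
#' Greenhouse-Geisser epsilon-hat (bounded by `1/(k-1)` and 1) shrinks the
#' within degrees of freedom.  Under the default policy the correction is
#' applied only when Mauchly's test rejects at `sphericity_alpha`.
#'
#' @param data data frame in long format.
#' @param response name of the response column.
#' @param within name of the within-subject factor column.
#' @param subject name of the subject identifier column.
#' @param between character vector of between-subject factor columns (may be
#'   empty).
#' @param gg_policy `"if_necessary"` (default), `"always"` or `"never"`.
#' @param sphericity_alpha Mauchly rejection level gating the correction.
#' @return an object of class `anova_result` with columns `effect`,
#'   `stratum`, `df1`, `df2`, `sum_sq`, `F`, `p`, `p_gg`, `p_reported`, and
#'   attributes `epsilon_gg`, `mauchly_w`, `mauchly_p`, `gg_applied`.
#' @export
rm_anova <- function(data, response, within, subject, between = NULL,
                     gg_policy = c("if_necessary", "always", "never"),
                     sphericity_alpha = 0.05) {
  gg_policy <- match.arg(gg_policy)
  w <- factor(data[[within]])
  s <- factor(data[[subject]])
  k <- nlevels(w)
  if (k < 2) stop_invalid("within factor needs at least 2 levels")
  tab <- table(s, w)
  if (any(tab != 1))
    stop_invalid("incomplete design: every subject needs exactly one ",
                 "observation at every level of ", within)
  # subjects x levels response matrix
  Y <- matrix(NA_real_, nlevels(s), k,
              dimnames = list(levels(s), levels(w)))
  Y[cbind(as.integer(s), as.integer(w))] <- data[[response]]
  n <- nrow(Y)

  # per-subject between-factor frame
  if (length(between)) {
    bt <- unique(data[, c(subject, between), drop = FALSE])
    if (nrow(bt) != n)
      stop_invalid("between factors must be constant within subject")
    bt <- bt[match(levels(s), as.character(bt[[subject]])), , drop = FALSE]
    bf <- lapply(bt[between], factor)
    form <- stats::as.formula(paste("~", paste(between, collapse = "*")))
    Xb <- stats::model.matrix(form, data.frame(bf),
                              contrasts.arg = lapply(bf, function(.) "contr.sum"))
    bterms <- attr(stats::terms(form), "term.labels")
  } else {
    Xb <- matrix(1, n, 1)
    attr(Xb, "assign") <- 0L
    bterms <- character(0)
  }
  assign <- attr(Xb, "assign")
  pb <- ncol(Xb)
  if (n <= pb) stop_invalid("not enough subjects for the between design")

  # ---- between stratum: subject means (scaled by k) -----------------------
  ybar <- rowMeans(Y)
  rows <- list()
  if (length(bterms)) {
    dec_b <- type3_ss(Xb, ybar, assign, seq_along(bterms))
    df_b <- vapply(seq_along(bterms), function(t) sum(assign == t), numeric(1))
    ss_b <- k * dec_b$ss
    rss_b <- k * dec_b$rss
  } else {
    rss_b <- k * rss_of(Xb, ybar)
    ss_b <- numeric(0)
    df_b <- numeric(0)
  }
  df_res_b <- n - pb
  ms_res_b <- rss_b / df_res_b
  for (i in seq_along(bterms)) {
    f <- (ss_b[i] / df_b[i]) / ms_res_b
    rows[[length(rows) + 1L]] <- data.frame(
      effect = bterms[i], stratum = "between", df1 = df_b[i], df2 = df_res_b,
      sum_sq = ss_b[i], F = f,
      p = stats::pf(f, df_b[i], df_res_b, lower.tail = FALSE), p_gg = NA_real_)
  }

  # ---- within stratum: orthonormal contrasts ------------------------------
  Cn <- orthonormal_contrasts(k)
  Z <- Y %*% Cn                                    # n x (k-1)
  fitZ <- stats::lm.fit(Xb, Z)
  E <- as.matrix(fitZ$residuals)
  rss_w_full <- colSums(E^2)
  df_res_w <- (n - pb) * (k - 1)
  ms_res_w <- sum(rss_w_full) / df_res_w

  within_terms <- c(0L, seq_along(bterms))         # 0 = intercept = within main
  within_names <- c(within,
                    if (length(bterms)) paste(bterms, within, sep = ":"))
  eps <- NA_real_
  S <- crossprod(E) / (n - pb)
  d <- k - 1
  eps <- (sum(diag(S)))^2 / (d * sum(S^2))
  eps <- min(max(eps, 1 / d), 1)
  # Mauchly's test for sphericity of the contrast covariance; p value from
  # the standard two-term asymptotic chi-square expansion
  mauchly_w <- det(S) / ((sum(diag(S)) / d)^d)
  mauchly_p <- NA_real_
  if (is.finite(mauchly_w) && mauchly_w > 0 && d > 1 && (n - pb) > d) {
    ne <- n - pb
    rho <- 1 - (2 * d^2 + d + 2) / (6 * d * ne)
    dfc <- d * (d + 1) / 2 - 1
    w2 <- (d + 2) * (d - 1) * (d - 2) * (2 * d^3 + 6 * d^2 + 3 * d + 2) /
      (288 * d^2 * ne^2 * rho^2)
    stat <- -ne * rho * log(mauchly_w)
    mauchly_p <- stats::pchisq(stat, dfc, lower.tail = FALSE) +
      w2 * (stats::pchisq(stat, dfc + 4, lower.tail = FALSE) -
              stats::pchisq(stat, dfc, lower.tail = FALSE))
    mauchly_p <- min(max(mauchly_p, 0), 1)
  }

  for (j in seq_along(within_terms)) {
    t <- within_terms[j]
    ss <- sum(vapply(seq_len(ncol(Z)), function(col) {
      rss_of(Xb[, assign != t, drop = FALSE], Z[, col]) - rss_w_full[col]
    }, numeric(1)))
    ss <- max(ss, 0)
    df1 <- (if (t == 0) 1 else sum(assign == t)) * (k - 1)
    f <- (ss / df1) / ms_res_w
    p <- stats::pf(f, df1, df_res_w, lower.tail = FALSE)
    p_gg <- stats::pf(f, eps * df1, eps * df_res_w, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      effect = within_names[j], stratum = "within", df1 = df1, df2 = df_res_w,
      sum_sq = ss, F = f, p = p, p_gg = p_gg)
  }

  out <- do.call(rbind, rows)
  gg_applied <- switch(gg_policy,
                       always = TRUE,
                       never = FALSE,
                       if_necessary = is.finite(mauchly_p) &&
                         mauchly_p < sphericity_alpha)
  out$p_reported <- ifelse(out$stratum == "within" & gg_applied,
                           out$p_gg, out$p)
  err <- data.frame(effect = c("Error(between)", "Error(within)"),
                    stratum = c("between", "within"),
                    df1 = c(df_res_b, df_res_w), df2 = NA,
                    sum_sq = c(rss_b, sum(rss_w_full)),
                    F = NA, p = NA, p_gg = NA, p_reported = NA)
  out <- rbind(out, err)
  rownames(out) <- NULL
  structure(out, class = c("anova_result", "data.frame"),
            epsilon_gg = eps, mauchly_w = mauchly_w, mauchly_p = mauchly_p,
            gg_applied = gg_applied, k = k, type = "III",
            kind = "repeated-measures",
            residuals_within = E, residuals_between = ybar -
              drop(Xb %*% stats::lm.fit(Xb, ybar)$coefficients))
}

#' @export
print.anova_result <- function(x, ...) {
  kind <- attr(x, "kind") %||% "anova"
  cat(sprintf("%s ANOVA (Type %s SS)\n", kind, attr(x, "type") %||% "III"))
  print.data.frame(cbind(x), digits = 4)
  if (!is.null(attr(x, "epsilon_gg"))) {
    cat(sprintf("Greenhouse-Geisser epsilon = %.4f; Mauchly W = %.4f (p = %.4g); GG %s\n",
                attr(x, "epsilon_gg"), attr(x, "mauchly_w"),
                attr(x, "mauchly_p"),
                if (isTRUE(attr(x, "gg_applied"))) "applied" else "not applied"))
  }
  invisible(x)
}
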