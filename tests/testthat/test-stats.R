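# ANOVA machinery, post hoc adjustments and residual diagnostics, checked
# against independent matrix-algebra oracles and base-R references.

rand_2x3 <- function(seed, n_per_cell = 4, effect = 0) {
  set.seed(seed)
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2", "b3"))
  d <- d[rep(seq_len(6), each = n_per_cell), ]
  d$y <- stats::rnorm(nrow(d)) + effect * (d$A == "a2") * (d$B == "b3")
  d
}

test_that("Type III SS match a projection-matrix oracle and car::Anova", {
  d <- rand_2x3(1)
  d <- d[-c(2, 9), ]  # unbalance the cells
  res <- anova_twoway(d, "y", "A", "B")

  # oracle: explicit hat-matrix quadratic forms with sum contrasts
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  X <- model.matrix(~ A * B, d)
  hat <- function(M) M %*% solve(crossprod(M)) %*% t(M)
  assign <- attr(X, "assign")
  for (t in 1:3) {
    Pf <- hat(X)
    Pr <- hat(X[, assign != t, drop = FALSE])
    ss_oracle <- drop(t(d$y) %*% (Pf - Pr) %*% d$y)
    expect_equal(res$sum_sq[t], ss_oracle, tolerance = 1e-10)
  }
  skip_if_not_installed("car")
  ref <- car::Anova(stats::lm(y ~ A * B, d), type = 3)
  expect_equal(res$sum_sq[1:3], ref$`Sum Sq`[2:4], tolerance = 1e-10)
  expect_equal(res$p[1:3], ref$`Pr(>F)`[2:4], tolerance = 1e-10)
})

test_that("degenerate and null factorial cases behave as documented", {
  # zero within-cell variance: F reported as Inf with p = 0
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2", "b3"))
  d <- d[rep(seq_len(6), each = 3), ]
  d$y <- as.numeric(interaction(d$A, d$B))
  res <- anova_twoway(d, "y", "A", "B")
  expect_true(all(is.infinite(res$F[1:3])))
  expect_equal(res$p[1:3], c(0, 0, 0))

  # identical cell means: all effects stay non-significant
  d2 <- rand_2x3(2, n_per_cell = 60)
  res2 <- anova_twoway(d2, "y", "A", "B")
  expect_true(all(res2$p[1:3] > 0.01))

  d3 <- rand_2x3(3)
  d3 <- d3[!(d3$A == "a1" & d3$B == "b2"), ]
  expect_error(anova_twoway(d3, "y", "A", "B"), "empty cell")
})

rm_long <- function(seed, n = 18, k = 6, rho = 0.3, effect = 0) {
  set.seed(seed)
  grp <- rep(c("WT", "KO"), each = n / 2)
  age <- rep(rep(c("p21", "p30", "p60"), each = n / 6), 2)
  S <- rho + (1 - rho) * diag(k)
  Y <- matrix(stats::rnorm(n * k), n, k) %*% chol(S) +
    effect * (grp == "KO")
  data.frame(subject = rep(sprintf("s%02d", 1:n), each = k),
             genotype = rep(grp, each = k), age_group = rep(age, each = k),
             gap = rep(sprintf("g%02d", 1:k), n), y = as.vector(t(Y)))
}

test_that("RM-ANOVA matches aov, anova.mlm and mauchly.test", {
  long <- rm_long(7)
  mine <- rm_anova(long, "y", within = "gap", subject = "subject",
                   between = c("genotype", "age_group"))

  av <- summary(stats::aov(y ~ genotype * age_group * gap +
                             Error(subject / gap), long))
  btab <- av[["Error: subject"]][[1]]
  wtab <- av[["Error: subject:gap"]][[1]]
  rownames(btab) <- trimws(rownames(btab))
  rownames(wtab) <- trimws(rownames(wtab))
  expect_equal(mine$sum_sq[mine$effect == "genotype"], btab["genotype", "Sum Sq"],
               tolerance = 1e-9)
  expect_equal(mine$F[mine$effect == "genotype:age_group"],
               btab["genotype:age_group", "F value"], tolerance = 1e-9)
  expect_equal(mine$F[mine$effect == "gap"], wtab["gap", "F value"],
               tolerance = 1e-9)
  expect_equal(mine$sum_sq[mine$effect == "genotype:age_group:gap"],
               wtab["genotype:age_group:gap", "Sum Sq"], tolerance = 1e-9)

  # epsilon-hat and Mauchly against the multivariate machinery in stats
  Y <- matrix(long$y, ncol = 6, byrow = TRUE)
  info <- unique(long[, c("subject", "genotype", "age_group")])
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  ml <- stats::lm(Y ~ genotype * age_group, info)
  idata <- data.frame(gap = factor(sprintf("g%02d", 1:6)))
  # eigenvalue-form epsilon oracle from the multivariate residual SSD
  ssd <- stats::SSD(ml)
  C <- stats::contr.helmert(6)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  lam <- eigen(t(C) %*% (ssd$SSD / ssd$df) %*% C,
               symmetric = TRUE, only.values = TRUE)$values
  eps_oracle <- sum(lam)^2 / (5 * sum(lam^2))
  expect_equal(attr(mine, "epsilon_gg"), eps_oracle, tolerance = 1e-9)
  mt <- stats::mauchly.test(ml, idata = idata, X = ~1)
  expect_equal(attr(mine, "mauchly_w"), unname(mt$statistic),
               tolerance = 1e-9)
  expect_equal(attr(mine, "mauchly_p"), mt$p.value, tolerance = 1e-3)
})

test_that("GG epsilon respects its bounds and shrinks the rejection region", {
  for (seed in 1:8) {
    long <- rm_long(seed + 20)
    res <- rm_anova(long, "y", within = "gap", subject = "subject",
                    between = c("genotype", "age_group"),
                    gg_policy = "always")
    eps <- attr(res, "epsilon_gg")
    expect_gte(eps, 1 / 5)
    expect_lte(eps, 1)
    wi <- res$stratum == "within" & !grepl("Error", res$effect)
    # standard formula throughout, and conservative wherever F >= 1 (the
    # correction is one-sided in the rejection-relevant regime)
    expect_equal(res$p_gg[wi],
                 stats::pf(res$F[wi], eps * res$df1[wi], eps * res$df2[wi],
                           lower.tail = FALSE), tolerance = 1e-12)
    big <- wi & res$F >= 2
    expect_true(all(res$p_gg[big] >= res$p[big] - 1e-12))
    expect_equal(res$p_reported[wi], res$p_gg[wi])
  }
})

test_that("compound-symmetric data look spherical to Mauchly and epsilon", {
  eps <- p_m <- numeric(20)
  for (i in 1:20) {
    set.seed(400 + i)
    Y <- matrix(stats::rnorm(20 * 4), 20, 4) %*%
      chol(0.4 + 0.6 * diag(4)) # compound symmetry => spherical differences
    long <- data.frame(subject = rep(sprintf("s%02d", 1:20), each = 4),
                       gap = rep(paste0("g", 1:4), 20),
                       y = as.vector(t(Y)))
    res <- rm_anova(long, "y", within = "gap", subject = "subject")
    eps[i] <- attr(res, "epsilon_gg")
    p_m[i] <- attr(res, "mauchly_p")
  }
  expect_gt(mean(eps), 0.8)        # epsilon near its upper bound
  expect_lte(mean(p_m < 0.05), 0.2) # Mauchly mostly non-significant
})

test_that("zero between-subject variance reduces to one-way RM by formula", {
  set.seed(55)
  n <- 10; k <- 4
  Y <- matrix(stats::rnorm(n * k), n, k)
  Y <- Y - rowMeans(Y)  # remove all between-subject variance
  long <- data.frame(subject = rep(sprintf("s%02d", 1:n), each = k),
                     gap = rep(paste0("g", 1:k), n), y = as.vector(t(Y)))
  res <- rm_anova(long, "y", within = "gap", subject = "subject")
  # direct textbook formula for the one-way repeated ANOVA
  ss_w <- n * sum((colMeans(Y) - mean(Y))^2)
  ss_err <- sum(sweep(sweep(Y, 2, colMeans(Y)), 1, rowMeans(Y) - mean(Y))^2)
  f_direct <- (ss_w / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  expect_equal(res$F[res$effect == "gap"], f_direct, tolerance = 1e-9)
})

test_that("RM-ANOVA rejects incomplete and inconsistent designs", {
  long <- rm_long(9)
  expect_error(rm_anova(long[-1, ], "y", within = "gap",
                        subject = "subject",
                        between = c("genotype", "age_group")),
               "incomplete")
  bad <- long
  bad$genotype[bad$subject == "s01"][1] <- "KO"
  expect_error(rm_anova(bad, "y", within = "gap", subject = "subject",
                        between = c("genotype", "age_group")),
               "constant")
})

test_that("post hoc adjustments follow their closed forms", {
  set.seed(71)
  d <- data.frame(g = rep(paste0("g", 1:4), each = 6),
                  y = stats::rnorm(24))
  sid <- posthoc(d, "y", "g", method = "sidak")
  expect_equal(nrow(sid), 6)
  expect_equal(sid$p_adj, 1 - (1 - sid$p_raw)^6, tolerance = 1e-12)
  bon <- posthoc(d, "y", "g", method = "bonferroni")
  expect_equal(bon$p_adj, pmin(1, 6 * bon$p_raw), tolerance = 1e-12)
  tuk <- posthoc(d, "y", "g", method = "tukey")
  # inequality chain: bonferroni >= sidak >= raw
  expect_true(all(bon$p_adj >= sid$p_adj - 1e-12))
  expect_true(all(sid$p_adj >= sid$p_raw - 1e-12))
  expect_true(all(tuk$p_adj >= tuk$p_raw - 1e-6))

  # single comparison: adjusted equals raw for every method
  d2 <- data.frame(g = rep(c("g1", "g2"), each = 6), y = stats::rnorm(12))
  for (m in c("tukey", "bonferroni", "sidak")) {
    ph <- posthoc(d2, "y", "g", method = m)
    expect_equal(ph$p_adj, ph$p_raw, tolerance = 1e-6)
  }
  expect_error(posthoc(d, "y", "g", method = "scheffe"))

  # Tukey matches stats::TukeyHSD on a balanced one-way layout
  hsd <- stats::TukeyHSD(stats::aov(y ~ g, d))$g
  expect_equal(sort(tuk$p_adj), sort(unname(hsd[, "p adj"])),
               tolerance = 1e-6)

  # family = "all" pools one contrast repeated across slices
  d3 <- data.frame(g = rep(c("g1", "g2"), each = 9),
                   a = rep(rep(c("x", "y", "z"), each = 3), 2),
                   y = stats::rnorm(18))
  ph3 <- posthoc(d3, "y", "g", by = "a", method = "sidak", family = "all")
  expect_equal(ph3$p_adj, 1 - (1 - ph3$p_raw)^3, tolerance = 1e-12)
})

test_that("residual diagnostics report moments, W and the +/-2 screen", {
  set.seed(81)
  x <- stats::rnorm(5000)
  dg <- diagnostics(x)
  expect_lt(abs(dg$skewness), 0.1)
  expect_lt(abs(dg$kurtosis_excess), 0.2)
  expect_true(dg$within_pm2)
  expect_equal(nrow(dg$qq), 5000)
  expect_true(!is.unsorted(dg$qq$theoretical))

  skewed <- stats::rlnorm(400, 0, 1)
  dgs <- diagnostics(skewed)
  expect_gt(dgs$skewness, 2)
  expect_false(dgs$within_pm2)

  expect_error(diagnostics(rep(1, 10)), "constant")
  expect_error(diagnostics(c(1, 2)), "at least 3")

  # Shapiro-Wilk calibration under the null
  set.seed(82)
  rej <- mean(vapply(1:2000, function(i)
    stats::shapiro.test(stats::rnorm(50))$p.value < 0.05, logical(1)))
  dg50 <- diagnostics(stats::rnorm(50))
  expect_equal(dg50$shapiro_p,
               stats::shapiro.test(dg50$qq$empirical)$p.value)
  expect_gt(rej, 0.035)
  expect_lt(rej, 0.065)
})
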