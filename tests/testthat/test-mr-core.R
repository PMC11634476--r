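# Closed-form MR estimators against arithmetic and regression oracles.

test_that("Wald ratio arithmetic and degenerate cases", {
  est <- wald_ratio(0.5, 0.01, 0.1, 0.02)
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.04)
  expect_equal(est$ci_high - est$beta, qnorm(0.975) * 0.04, tolerance = 1e-12)
  z <- wald_ratio(0.5, 0.01, 0, 0.02)
  expect_equal(z$beta, 0)
  expect_equal(z$pval, 1)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.02), "undefined ratio")
  # arithmetic oracle on random inputs (sign of gamma included)
  for (s in 1:20) {
    set.seed(s)
    g <- rnorm(1); G <- rnorm(1); sg <- runif(1, 0.01, 1); sG <- runif(1, 0.01, 1)
    e <- wald_ratio(g, sg, G, sG)
    expect_equal(e$beta, G / g, tolerance = 1e-14)
    expect_equal(e$se, sG / abs(g), tolerance = 1e-14)
    expect_equal(e$pval, 2 * pnorm(-abs((G / g) / (sG / abs(g)))), tolerance = 1e-12)
  }
})

test_that("IVW equals the weighted-regression-through-origin oracle", {
  for (s in 1:20) {
    h <- make_hset(8, beta_true = 0.4, seed = s, het_sd = 0.02)
    w <- 1 / h$se_Gamma^2
    fit <- mr_ivw(h, "fixed")
    expect_equal(fit$estimate$beta, wls_oracle(h$gamma, h$Gamma, w),
                 tolerance = 1e-10)
    expect_equal(fit$estimate$se, 1 / sqrt(sum(w * h$gamma^2)), tolerance = 1e-12)
    # independent loop recomputation of Q
    Q <- 0
    for (j in seq_len(nrow(h))) {
      Q <- Q + (h$Gamma[j] - fit$estimate$beta * h$gamma[j])^2 / h$se_Gamma[j]^2
    }
    expect_equal(fit$heterogeneity$Q, Q, tolerance = 1e-10)
    # random-effects SE never shrinks below the fixed one
    expect_gte(mr_ivw(h, "random")$estimate$se, fit$estimate$se)
  }
})

test_that("IVW agrees with a fixed-effect meta-analysis of Wald ratios", {
  skip_if_not_installed("metafor")
  h <- make_hset(12, beta_true = -0.25, seed = 3, het_sd = 0.01)
  fit <- mr_ivw(h, "fixed")$estimate
  yi <- h$Gamma / h$gamma
  sei <- h$se_Gamma / abs(h$gamma)
  rma <- metafor::rma(yi = yi, sei = sei, method = "FE")
  expect_equal(fit$beta, as.numeric(rma$beta), tolerance = 1e-8)
  expect_equal(fit$se, rma$se, tolerance = 1e-8)
})

test_that("IVW degenerate and single-instrument behaviour", {
  # identical duplicated instrument: estimate equals its Wald ratio
  h <- harmonized_set(rep(0.5, 2), rep(0.01, 2), rep(0.1, 2), rep(0.02, 2))
  fit <- mr_ivw(h, "fixed")
  expect_equal(fit$estimate$beta, 0.2, tolerance = 1e-14)
  expect_equal(fit$heterogeneity$Q, 0, tolerance = 1e-20)
  # equal Wald ratios: Q = 0 and fixed SE = random SE
  h2 <- harmonized_set(c(0.2, 0.4, 0.8), rep(0.01, 3),
                       0.3 * c(0.2, 0.4, 0.8), rep(0.02, 3))
  f2 <- mr_ivw(h2, "fixed"); r2 <- mr_ivw(h2, "random")
  expect_equal(f2$heterogeneity$Q, 0, tolerance = 1e-20)
  expect_equal(f2$estimate$se, r2$estimate$se)
  # single instrument delegates to the Wald ratio
  h1 <- harmonized_set(0.5, 0.01, 0.1, 0.02)
  w1 <- wald_ratio(0.5, 0.01, 0.1, 0.02)
  i1 <- mr_ivw(h1)
  expect_equal(i1$estimate$beta, w1$beta)
  expect_equal(i1$estimate$se, w1$se)
  expect_error(mr_ivw(harmonized_set(c(0, 0), c(1, 1), c(0, 0), c(1, 1))),
               "zero")
})

test_that("IVW is sign- and scale-equivariant", {
  h <- make_hset(10, beta_true = 0.3, seed = 8, het_sd = 0.02)
  base <- mr_ivw(h, "random")
  neg <- h; neg$Gamma <- -neg$Gamma
  fn <- mr_ivw(neg, "random")
  expect_equal(fn$estimate$beta, -base$estimate$beta, tolerance = 1e-12)
  expect_equal(fn$estimate$se, base$estimate$se, tolerance = 1e-12)
  expect_equal(fn$heterogeneity$Q, base$heterogeneity$Q, tolerance = 1e-10)
  for (c_scale in c(0.5, 2, 10)) {
    sc <- h; sc$gamma <- sc$gamma * c_scale; sc$se_gamma <- sc$se_gamma * c_scale
    expect_equal(mr_ivw(sc, "random")$estimate$beta,
                 base$estimate$beta / c_scale, tolerance = 1e-12)
  }
})

test_that("Egger recovers an exact line and matches the lm oracle", {
  g <- c(0.1, 0.2, 0.35, 0.5, 0.8)
  h <- harmonized_set(g, rep(0.01, 5), 0.3 + 0.5 * g, rep(0.02, 5))
  fit <- mr_egger(h)
  expect_equal(fit$intercept, 0.3, tolerance = 1e-12)
  expect_equal(fit$slope$beta, 0.5, tolerance = 1e-12)
  expect_equal(fit$heterogeneity$Q, 0, tolerance = 1e-16)
  expect_error(mr_egger(h[1:2, ]), "insufficient instruments")

  for (s in 1:20) {
    h <- make_hset(10, beta_true = 0.3, seed = 100 + s, het_sd = 0.05)
    # oriented data for the oracle, as the estimator defines
    sgn <- ifelse(h$gamma < 0, -1, 1)
    g <- sgn * h$gamma; G <- sgn * h$Gamma; w <- 1 / h$se_Gamma^2
    cf <- wls_oracle(g, G, w, intercept = TRUE)
    fit <- mr_egger(h)
    expect_equal(fit$intercept, cf[1], tolerance = 1e-10)
    expect_equal(fit$slope$beta, cf[2], tolerance = 1e-10)
    # SEs equal lm's model-based SEs when the dispersion exceeds 1
    lmfit <- summary(lm(G ~ g, weights = w))
    disp <- sqrt(fit$heterogeneity$Q / fit$heterogeneity$df)
    if (disp > 1) {
      expect_equal(fit$intercept_se, lmfit$coefficients[1, 2], tolerance = 1e-8)
      expect_equal(fit$slope$se, lmfit$coefficients[2, 2], tolerance = 1e-8)
    }
  }
})

test_that("Egger slope is consistent with IVW under zero intercept", {
  set.seed(20)
  reps <- 100
  diffs <- replicate(reps, {
    h <- make_hset(30, beta_true = 0.3, seed = sample.int(1e6, 1), het_sd = 0.02)
    mr_egger(h)$slope$beta - mr_ivw(h)$estimate$beta
  })
  expect_lt(abs(mean(diffs)), 2 * sd(diffs) / sqrt(reps) + 0.01)
})

test_that("Cochran's Q matches an explicit loop and handles exact fits", {
  g <- c(0.1, 0.3, 0.6)
  h <- harmonized_set(g, rep(0.01, 3), 0.4 * g, rep(0.02, 3))
  q <- cochran_q(h, 0.4, "ivw")
  expect_equal(q$Q, 0, tolerance = 1e-20)
  expect_equal(q$pval, 1)
  h2 <- make_hset(9, beta_true = 0.2, seed = 4, het_sd = 0.05)
  for (model in c("ivw", "egger")) {
    beta <- 0.25; intercept <- if (model == "egger") 0.02 else 0
    q2 <- cochran_q(h2, beta, model, intercept)
    sgn <- if (model == "egger") ifelse(h2$gamma < 0, -1, 1) else rep(1, 9)
    Q_loop <- sum((sgn * h2$Gamma - intercept - beta * sgn * h2$gamma)^2 / h2$se_Gamma^2)
    expect_equal(q2$Q, Q_loop, tolerance = 1e-10)
    expect_equal(q2$df, 9L - if (model == "ivw") 1L else 2L)
    expect_equal(q2$pval, pchisq(q2$Q, q2$df, lower.tail = FALSE))
  }
  expect_error(cochran_q(h, 0.4, "egger")$df, NA) # df = 1 fine at J = 3
  expect_error(cochran_q(h[1, , drop = FALSE], 0.4, "ivw"), "degrees of freedom")
})

test_that("leave-one-out matches IVW rerun on explicit subsets", {
  h <- make_hset(8, beta_true = 0.3, seed = 6, het_sd = 0.03)
  loo <- leave_one_out(h, "fixed")
  expect_equal(nrow(loo), 8L)
  for (j in seq_len(8)) {
    ref <- mr_ivw(h[-j, , drop = FALSE], "fixed")$estimate
    expect_equal(loo$beta[j], ref$beta, tolerance = 1e-12)
    expect_equal(loo$se[j], ref$se, tolerance = 1e-12)
  }
  # homogeneous data: every LOO estimate equals the full one
  g <- c(0.2, 0.4, 0.6, 0.8)
  hh <- harmonized_set(g, rep(0.01, 4), 0.3 * g, rep(0.02, 4))
  full <- mr_ivw(hh, "fixed")$estimate$beta
  expect_equal(leave_one_out(hh, "fixed")$beta, rep(full, 4), tolerance = 1e-12)
})

test_that("results table has one row per method with CI consistency", {
  h <- make_hset(10, beta_true = 0.3, seed = 12, het_sd = 0.02)
  tab <- mr_results_table(h)
  expect_identical(tab$method, c("ivw_fixed", "ivw_random", "egger_slope"))
  expect_true(all(tab$ci_low <= tab$beta & tab$beta <= tab$ci_high))
  expect_equal(tab$ci_high - tab$beta, qnorm(0.975) * tab$se, tolerance = 1e-12)
})
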