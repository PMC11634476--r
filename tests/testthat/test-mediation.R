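# Delta-method mediation arithmetic, two-step composition, and the
# candidate screen.

# SEs back-derived from published-style 95% CIs (half-width / z).
se_from_ci <- function(half_width) half_width / (2 * qnorm(0.975))

test_that("product-of-coefficients proportion and delta-method CI match a symbolic oracle", {
  b1 <- -0.207; s1 <- 0.164 / 3.9199
  b2 <- 0.274;  s2 <- 0.223 / 3.9199
  bt <- -0.290
  m <- mediation_effect(mr_estimate("xm", b1, s1, 16),
                        mr_estimate("my", b2, s2, 20),
                        mr_estimate("tot", bt, 0.109 / 1.959964, 16))
  expect_equal(m$indirect, b1 * b2, tolerance = 1e-12)
  expect_equal(m$proportion * bt, m$indirect, tolerance = 1e-12)
  # symbolic delta method for f(b1, b2) = b1 b2 / T with T fixed:
  # grad = (b2/T, b1/T); var = (b2/T)^2 s1^2 + (b1/T)^2 s2^2
  se_sym <- sqrt((b2 / bt)^2 * s1^2 + (b1 / bt)^2 * s2^2)
  expect_equal(m$proportion_se, se_sym, tolerance = 1e-10)
  expect_equal(m$proportion_ci_low, b1 * b2 / bt - qnorm(0.975) * se_sym,
               tolerance = 1e-10)
  expect_equal(m$proportion_ci_high, b1 * b2 / bt + qnorm(0.975) * se_sym,
               tolerance = 1e-10)
})

test_that("null first stage gives zero indirect effect and proportion", {
  m <- mediation_effect(mr_estimate("xm", 0, 0.05, 5),
                        mr_estimate("my", 0.4, 0.05, 5),
                        mr_estimate("tot", -0.3, 0.05, 5))
  expect_equal(m$indirect, 0)
  expect_equal(m$proportion, 0)
  expect_error(mediation_effect(mr_estimate("xm", 0.1, 0.05, 5),
                                mr_estimate("my", 0.4, 0.05, 5),
                                mr_estimate("tot", 0, 0.05, 5)),
               "undefined proportion")
  expect_warning(mediation_effect(mr_estimate("xm", 0.5, 0.01, 5),
                                  mr_estimate("my", 0.9, 0.01, 5),
                                  mr_estimate("tot", 0.3, 0.01, 5)),
                 "outside")
})

test_that("proportion is invariant to rescaling the mediator units", {
  b1 <- 0.21; s1 <- 0.04; b2 <- -0.35; s2 <- 0.06; bt <- -0.15
  base <- suppressWarnings(
    mediation_effect(mr_estimate("xm", b1, s1, 5),
                     mr_estimate("my", b2, s2, 5),
                     mr_estimate("tot", bt, 0.03, 5)))
  for (c_scale in c(0.1, 3, 25)) {
    sc <- suppressWarnings(
      mediation_effect(mr_estimate("xm", b1 * c_scale, s1 * c_scale, 5),
                       mr_estimate("my", b2 / c_scale, s2 / c_scale, 5),
                       mr_estimate("tot", bt, 0.03, 5)))
    expect_equal(sc$indirect, base$indirect, tolerance = 1e-10)
    expect_equal(sc$proportion, base$proportion, tolerance = 1e-10)
    expect_equal(sc$proportion_se, base$proportion_se, tolerance = 1e-10)
  }
})

test_that("propagated denominator mode widens the SE", {
  m_f <- mediation_effect(mr_estimate("xm", -0.2, 0.04, 5),
                          mr_estimate("my", 0.3, 0.05, 5),
                          mr_estimate("tot", -0.3, 0.06, 5),
                          denominator_mode = "fixed")
  m_p <- mediation_effect(mr_estimate("xm", -0.2, 0.04, 5),
                          mr_estimate("my", 0.3, 0.05, 5),
                          mr_estimate("tot", -0.3, 0.06, 5),
                          denominator_mode = "propagated")
  expect_gt(m_p$proportion_se, m_f$proportion_se)
  expect_equal(m_p$proportion, m_f$proportion)
})

test_that("two-step stages equal manual IVW runs on each harmonized pair", {
  sim <- simulate_chain(sim_config(seed = 9))
  exp_ids <- sim$truth$snps$variant_id[sim$truth$snps$role == "exposure_iv"]
  med_ids <- sim$truth$snps$variant_id[sim$truth$snps$role == "mediator_iv"]
  m <- two_step_mediation(sim$exposure, sim$mediator, sim$outcome,
                          exp_ids, med_ids)
  h_xm <- harmonize_pair(sim$exposure[sim$exposure$variant_id %in% exp_ids, ],
                         sim$mediator)
  h_my <- harmonize_pair(sim$mediator[sim$mediator$variant_id %in% med_ids, ],
                         sim$outcome)
  h_tot <- harmonize_pair(sim$exposure[sim$exposure$variant_id %in% exp_ids, ],
                          sim$outcome)
  expect_equal(m$beta_xm$beta, mr_ivw(h_xm)$estimate$beta, tolerance = 1e-12)
  expect_equal(m$beta_my$beta, mr_ivw(h_my)$estimate$beta, tolerance = 1e-12)
  expect_equal(m$beta_total$beta, mr_ivw(h_tot)$estimate$beta, tolerance = 1e-12)
  expect_equal(m$indirect, m$beta_xm$beta * m$beta_my$beta, tolerance = 1e-14)
  # overlapping instruments are dropped from the mediator stage
  expect_message(
    m2 <- two_step_mediation(sim$exposure, sim$mediator, sim$outcome,
                             exp_ids, c(exp_ids[1:2], med_ids)),
    "overlap")
  expect_equal(m2$beta_my$beta, m$beta_my$beta, tolerance = 1e-12)
})

test_that("a null exposure->mediator path yields a near-zero indirect effect", {
  set.seed(123)
  indirects <- replicate(60, {
    cfg <- sim_config(alpha = 0, seed = sample.int(1e6, 1))
    sim <- simulate_chain(cfg)
    exp_ids <- sim$truth$snps$variant_id[sim$truth$snps$role == "exposure_iv"]
    med_ids <- sim$truth$snps$variant_id[sim$truth$snps$role == "mediator_iv"]
    suppressWarnings(two_step_mediation(sim$exposure, sim$mediator, sim$outcome,
                                        exp_ids, med_ids)$indirect)
  })
  expect_lt(abs(mean(indirects)), 3 * sd(indirects) / sqrt(60))
})

test_that("single-candidate screen reduces to two-step mediation", {
  sim <- simulate_chain(sim_config(seed = 15))
  exp_ids <- sim$truth$snps$variant_id[sim$truth$snps$role == "exposure_iv"]
  med_ids <- sim$truth$snps$variant_id[sim$truth$snps$role == "mediator_iv"]
  st <- screen_mediators(sim$exposure, sim$outcome,
                         list(med = list(sumstats = sim$mediator,
                                         instruments = med_ids)),
                         exposure_instruments = exp_ids)
  ref <- two_step_mediation(sim$exposure, sim$mediator, sim$outcome,
                            exp_ids, med_ids)
  expect_equal(nrow(st), 1L)
  expect_true(st$qualifies)
  expect_equal(st$proportion, ref$proportion, tolerance = 1e-12)
  expect_equal(st$indirect, ref$indirect, tolerance = 1e-12)
})

test_that("screen recovers true mediators and rejects null candidates", {
  ss <- make_screen_sim(n_true = 4, n_null = 8, seed = 52)
  st <- suppressWarnings(
    screen_mediators(ss$exposure, ss$outcome, ss$candidates,
                     exposure_instruments = ss$exp_ids,
                     cfg = screen_config(alpha_screen = 0.05)))
  hits <- st$mediator[st$qualifies]
  expect_gte(sum(hits %in% ss$true_labels), 3)
  expect_lte(sum(hits %in% ss$null_labels), 2)
  # recovered proportions for true mediators sit near the design value
  props <- st$proportion[st$qualifies & st$mediator %in% ss$true_labels]
  expect_lt(abs(mean(props) - ss$true_proportion), 0.1)
  expect_error(screen_mediators(ss$exposure, ss$outcome, list(),
                                exposure_instruments = ss$exp_ids),
               "no candidate")
})

test_that("all-null candidates with Bonferroni adjustment rarely qualify", {
  n_qual <- 0
  for (r in 1:5) {
    ss <- make_screen_sim(n_true = 0, n_null = 6, seed = 660 + r)
    st <- suppressWarnings(
      screen_mediators(ss$exposure, ss$outcome, ss$candidates,
                       exposure_instruments = ss$exp_ids,
                       cfg = screen_config(multiplicity = "bonferroni")))
    n_qual <- n_qual + sum(st$qualifies)
  }
  expect_lte(n_qual, 1)
})

test_that("screen table round-trips through its delimited export", {
  sim <- simulate_chain(sim_config(seed = 21))
  exp_ids <- sim$truth$snps$variant_id[sim$truth$snps$role == "exposure_iv"]
  med_ids <- sim$truth$snps$variant_id[sim$truth$snps$role == "mediator_iv"]
  st <- screen_mediators(sim$exposure, sim$outcome,
                         list(m = list(sumstats = sim$mediator, instruments = med_ids)),
                         exposure_instruments = exp_ids)
  path <- tempfile()
  write_screen_table(st, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(back$proportion, st$proportion, tolerance = 1e-6)
  volcano <- read.table(paste0(path, ".volcano"), header = TRUE, sep = "\t")
  expect_equal(volcano$neg_log10_p, -log10(st$p_my), tolerance = 1e-6)
  unlink(c(path, paste0(path, ".volcano")))
})
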