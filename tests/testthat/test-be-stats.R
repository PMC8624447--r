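test_that("CV-sigma conversions reproduce the regulatory anchor points", {
  expect_equal(round(cv2sigma(0.30), 3), 0.294)
  expect_equal(cv2sigma(0), 0)
  expect_equal(cv2sigma(0.50), 0.47238, tolerance = 1e-5)
  # exact inverse over a grid
  cvs <- seq(0, 1.2, by = 0.05)
  expect_equal(sigma2cv(cv2sigma(cvs)), cvs, tolerance = 1e-12)
  expect_error(cv2sigma(-0.1), ">= 0")
})

test_that("EMA expanded limits scale with SWR, cap at CV 50% and stay log-symmetric", {
  cap <- ema_expanded_limits(cv2sigma(0.50))
  expect_equal(unname(round(cap, 2)), c(69.84, 143.19))
  # beyond the cap the limits do not widen further
  expect_equal(ema_expanded_limits(0.60), cap)
  # at the scaling threshold the limits are exp(+/- 0.760 * 0.294)
  at_thr <- ema_expanded_limits(0.294)
  expect_equal(unname(at_thr[["upper"]]), 100 * exp(0.760 * 0.294))
  expect_equal(unname(at_thr[["lower"]]), 100 * exp(-0.760 * 0.294))
  # log symmetry lower * upper = 100^2 across the whole range
  for (s in seq(0.294, 0.8, by = 0.05)) {
    lim <- ema_expanded_limits(s)
    expect_equal(unname(lim[["lower"]] * lim[["upper"]]), 1e4,
                 tolerance = 1e-9)
  }
})

test_that("SWR estimation matches the least-squares oracle and hand-derived toys", {
  # balanced toy: two reference values per subject differing by exactly +/- d;
  # with period effects balanced out, SS = n d^2 / 2 on n - 2 df
  d <- 0.3
  toy <- balanced_ref_2x4(d, n_per_seq = 4)
  est <- estimate_swr(toy, be_design("2x4"))
  ora <- lsq_swr_oracle(toy)
  expect_equal(est$swr, ora$swr, tolerance = 1e-10)
  expect_equal(est$df, ora$df)
  n <- 8
  expect_equal(est$swr, d * sqrt(n / (2 * (n - 2))), tolerance = 1e-10)

  # zero within-subject noise: swr collapses to numerical zero
  m0 <- validation_pk_model(wsv_f = 0)
  ds0 <- simulate_trial_dataset(m0, "2x4", 12, seed = 31,
                                include_error = FALSE)
  expect_lt(estimate_swr(ds0, be_design("2x4"))$swr, 1e-10)

  # the 2x2 design must refuse
  expect_error(estimate_swr(ds0, be_design("2x2")), "not estimable")
})

test_that("GMR and CI from the fixed-effects model match the normal-equations oracle", {
  # exact ratio, zero noise: GMR is the ratio and the CI has zero width
  cr <- constant_ratio_2x2(6, ratio = 1.10)
  g <- suppressWarnings(glm_gmr_ci(cr, "cmax"))  # zero-residual fit warns
  expect_equal(g$gmr, 110, tolerance = 1e-10)
  expect_equal(g$ci_upper - g$ci_lower, 0, tolerance = 1e-6)

  # noisy toys against the hand-built QR oracle
  for (seed in c(7, 8, 9)) {
    nd <- noisy_2x2(6, seed = seed)
    for (ep in c("cmax", "auc")) {
      g1 <- glm_gmr_ci(nd, ep)
      g2 <- lsq_gmr_oracle(nd, ep)
      expect_equal(g1$gmr, g2$gmr, tolerance = 1e-10)
      expect_equal(g1$ci_lower, g2$ci_lower, tolerance = 1e-10)
      expect_equal(g1$ci_upper, g2$ci_upper, tolerance = 1e-10)
      expect_equal(g1$df, g2$df)
    }
  }

  # simulation with no noise at GMR 1 recovers exactly 100%
  ds <- simulate_trial_dataset(validation_pk_model(wsv_f = 0), "2x2", 8,
                               seed = 41, include_error = FALSE)
  expect_equal(suppressWarnings(glm_gmr_ci(ds, "cmax"))$gmr, 100,
               tolerance = 1e-8)

  # all subjects in one sequence is a degenerate design
  one_seq <- constant_ratio_2x2(4)
  one_seq$sequence <- "TR"
  expect_error(glm_gmr_ci(one_seq, "cmax"), "degenerate")
})

test_that("TOST containment is equivalent to two one-sided t-tests at alpha 0.05", {
  for (seed in c(13, 14, 15, 16)) {
    nd <- noisy_2x2(8, seed = seed, sd = 0.25)
    g <- glm_gmr_ci(nd, "cmax")
    ci_pass <- g$ci_lower >= 80 && g$ci_upper <= 125
    est <- log(g$gmr / 100)
    tcrit <- qt(0.95, g$df)
    t_lower <- (est - log(0.80)) / g$se
    t_upper <- (log(1.25) - est) / g$se
    expect_identical(ci_pass, t_lower > tcrit && t_upper > tcrit)
  }
})

test_that("the EMA decision composes scaling, cap, GMR constraint and AUC rule", {
  # scaled pass: CI inside the expanded limits and GMR inside 80-125
  r1 <- hvdbe:::ema_cmax_rule(swr = 0.40, gmr = 118, ci_lower = 95,
                              ci_upper = 131)
  expect_equal(r1$method, "scaled")
  expect_equal(unname(r1$limits[["upper"]]), 100 * exp(0.76 * 0.40))
  expect_true(r1$pass)

  # same CI but GMR point estimate outside 80-125: fails despite wide limits
  r2 <- hvdbe:::ema_cmax_rule(swr = 0.40, gmr = 126, ci_lower = 95,
                              ci_upper = 131)
  expect_false(r2$pass)

  # SWR below the threshold: conventional limits even for a "known" HVD
  r3 <- hvdbe:::ema_cmax_rule(swr = 0.20, gmr = 118, ci_lower = 95,
                              ci_upper = 131)
  expect_equal(r3$method, "unscaled")
  expect_equal(unname(r3$limits), c(80, 125))
  expect_false(r3$pass)

  # missing swr (2x2) is always unscaled
  r4 <- hvdbe:::ema_cmax_rule(swr = NA, gmr = 105, ci_lower = 92,
                              ci_upper = 119)
  expect_equal(r4$method, "unscaled")
  expect_true(r4$pass)

  # full decision on a simulated highly variable 2x4 trial: AUC always
  # judged against 80-125 and overall = AND of the endpoints
  m <- validation_pk_model(wsv_f = 0.45)
  ds <- simulate_trial_dataset(m, "2x4", 36, seed = 51,
                               include_error = FALSE)
  dec <- ema_decision(ds, be_design("2x4"))
  tb <- dec$table
  expect_equal(tb$endpoint, c("cmax", "auc"))
  expect_equal(tb$method[2], "unscaled")
  expect_equal(tb$acc_lower[2], 80)
  expect_equal(dec$pass, all(tb$pass))
  # in a 2x2 trial no swr is attached and both endpoints are unscaled
  ds2 <- simulate_trial_dataset(m, "2x2", 24, seed = 52,
                                include_error = FALSE)
  dec2 <- ema_decision(ds2, be_design("2x2"))
  expect_true(all(dec2$table$method == "unscaled"))
  expect_true(is.na(dec2$table$swr[1]))
})

test_that("the EMA subject-inclusion rule keeps subjects with both products", {
  d <- constant_ratio_2x2(6)
  d <- d[!(d$subject == 2 & d$treatment == "R"), ]  # subject 2 loses its R
  f <- ema_filter(d)
  expect_false(2 %in% f$subject)
  expect_equal(sort(unique(f$subject)), c(1, 3, 4, 5, 6))
})
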