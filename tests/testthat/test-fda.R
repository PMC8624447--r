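test_that("per-subject contrasts follow the full- and partial-replicate definitions", {
  toy <- balanced_ref_2x4(0.3, n_per_seq = 2)
  con <- fda_contrasts(toy, be_design("2x4"), "cmax")
  expect_equal(nrow(con$ilat), 4)
  expect_equal(nrow(con$dlat), 4)
  for (id in unique(toy$subject)) {
    d <- toy[toy$subject == id, ]
    d <- d[order(d$period), ]
    lt <- log(d$cmax[d$treatment == "T"])
    lr <- log(d$cmax[d$treatment == "R"])
    expect_equal(con$ilat$ilat[con$ilat$subject == id],
                 mean(lt) - mean(lr))
    expect_equal(con$dlat$dlat[con$dlat$subject == id], lr[1] - lr[2])
  }

  # partial replicate RRT: ilat = logT - mean(logR), dlat chronological
  rrt <- data.frame(subject = 1, sequence = "RRT", period = 1:3,
                    treatment = c("R", "R", "T"),
                    cmax = exp(c(6.0, 6.4, 6.3)), auc = exp(c(7, 7.2, 7.1)))
  rrt$log_cmax <- log(rrt$cmax); rrt$log_auc <- log(rrt$auc)
  con3 <- fda_contrasts(rrt, be_design("3x3"), "cmax")
  expect_equal(con3$ilat$ilat, 6.3 - (6.0 + 6.4) / 2)
  expect_equal(con3$dlat$dlat, 6.0 - 6.4)

  # missing second reference: dlat missing, ilat still available
  rrt2 <- rrt[-2, ]
  con4 <- fda_contrasts(rrt2, be_design("3x3"), "cmax")
  expect_equal(nrow(con4$dlat), 0)
  expect_equal(con4$ilat$ilat, 6.3 - 6.0)

  expect_error(fda_contrasts(rrt, be_design("2x2"), "cmax"),
               "replicated-reference")
})

test_that("the Howe-type upper bound matches a brute-force oracle and its anchors", {
  # theta reproduced from (log 1.25 / 0.25)^2
  b <- fda_rsabe_upper_bound(0.1, 0.05, 10, 0.16, 10)
  expect_equal(b$theta, 0.7966887, tolerance = 1e-6)

  # degenerate no-difference case: criterion trivially met
  b0 <- fda_rsabe_upper_bound(0, 1e-12, 10, 0.16, 10)
  expect_lt(b0$upper, 0)
  # and the bound reduces to the chi-square-deflated variance term
  expect_equal(b0$upper, -b0$theta * 0.16 * 10 / qchisq(0.95, 10),
               tolerance = 1e-9)

  # printed 6-subject toy series against the independent implementation
  ilat <- c(0.12, -0.05, 0.30, 0.02, -0.18, 0.25)
  iseq <- c("A", "A", "A", "B", "B", "B")
  dlat <- c(0.40, -0.35, 0.52, -0.20, 0.10, -0.48)
  st_i <- hvdbe:::contrast_stats(ilat, iseq)
  st_d <- hvdbe:::contrast_stats(dlat, iseq)
  got <- fda_rsabe_upper_bound(st_i$mean, st_i$se, st_i$df,
                               st_d$s2 / 2, st_d$df)
  ora <- rsabe_oracle(ilat, iseq, dlat, iseq)
  expect_equal(got$upper, ora$upper, tolerance = 1e-10)
  expect_equal(st_i$mean, ora$dbar, tolerance = 1e-12)
  expect_equal(st_i$se, ora$se, tolerance = 1e-12)
  expect_equal(st_d$s2 / 2, ora$s2wr, tolerance = 1e-12)

  expect_error(fda_rsabe_upper_bound(0.1, 0.05, 0, 0.16, 10),
               "degrees of freedom")
})

test_that("the FDA mixed-scaling decision routes endpoints by their own SWR", {
  # highly variable trial: both endpoints go the scaled route
  m <- validation_pk_model(wsv_f = 0.45)
  ds <- simulate_trial_dataset(m, "2x4", 36, seed = 61,
                               include_error = FALSE)
  dec <- fda_decision(ds, be_design("2x4"))
  expect_equal(dec$table$method, c("scaled", "scaled"))
  expect_true(all(dec$table$swr > 0.294))
  expect_equal(dec$pass, all(dec$table$pass))

  # low-variability full replicate: unscaled via the mixed model
  mlo <- pk_model(wsv = c(ka = 0.05, f = 0.15), tv_f_test = 1.0,
                  error_additive = 0, error_proportional = 0,
                  corr_f_tr = 0.9, corr_ka_tr = 0.8)
  dlo <- simulate_trial_dataset(mlo, "2x4", 24, seed = 62,
                                include_error = FALSE)
  declo <- fda_decision(dlo, be_design("2x4"))
  expect_true(all(grepl("^unscaled", declo$table$method)))

  # 2x2 is always the unscaled fixed-effects TOST
  d22 <- simulate_trial_dataset(m, "2x2", 24, seed = 63,
                                include_error = FALSE)
  dec22 <- fda_decision(d22, be_design("2x2"))
  expect_equal(dec22$table$method, c("unscaled", "unscaled"))
  expect_true(all(is.na(dec22$table$swr)))
})

test_that("the five-variance-term mixed model fits replicate data and falls back safely", {
  m <- pk_model(wsv = c(ka = 0.05, f = 0.15),
                error_additive = 0, error_proportional = 0)
  ds <- simulate_trial_dataset(m, "2x4", 24, seed = 71,
                               include_error = FALSE)
  mm <- mixed_gmr_ci(ds, "cmax")
  gg <- glm_gmr_ci(ds, "cmax")
  expect_false(mm$fallback)
  expect_true(is.finite(mm$gmr) && mm$ci_lower < mm$ci_upper)
  # the treatment-effect estimates agree closely for balanced complete data
  expect_equal(mm$gmr, gg$gmr, tolerance = 0.02)

  # zero-variance data cannot support the REML fit: GLM fallback
  zz <- simulate_trial_dataset(validation_pk_model(wsv_f = 0), "2x4", 8,
                               seed = 72, include_error = FALSE)
  mz <- mixed_gmr_ci(zz, "cmax")
  expect_true(is.finite(mz$gmr))
  expect_equal(mz$gmr, 100, tolerance = 1e-6)
})
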