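test_that("micro constants reproduce the typical-value ratios and Vieta identities", {
  mc <- micro_constants(29400, 14600, 1040, 57300)
  expect_equal(mc$k10, 2.0137, tolerance = 1e-4)
  expect_equal(mc$k12, 0.07123, tolerance = 1e-3)
  expect_equal(mc$k21, 0.018150, tolerance = 1e-4)
  expect_lt(mc$lambda1, mc$lambda2)

  # symmetric unit case has closed-form eigenvalues (3 -/+ sqrt(5))/2
  mc1 <- micro_constants(1, 1, 1, 1)
  expect_equal(c(mc1$k10, mc1$k12, mc1$k21), c(1, 1, 1))
  expect_equal(mc1$lambda1, (3 - sqrt(5)) / 2)
  expect_equal(mc1$lambda2, (3 + sqrt(5)) / 2)

  pars <- random_pk_par_sets(50, seed = 11)
  for (i in seq_len(nrow(pars))) {
    mc <- micro_constants(pars$cl[i], pars$vc[i], pars$q[i], pars$vp[i])
    expect_equal(mc$lambda1 + mc$lambda2, mc$k10 + mc$k12 + mc$k21,
                 tolerance = 1e-12)
    expect_equal(mc$lambda1 * mc$lambda2, mc$k10 * mc$k21,
                 tolerance = 1e-12)
    expect_gt(mc$lambda1, 0)
  }
  expect_error(micro_constants(-1, 1, 1, 1), "positive")
})

test_that("closed-form concentration matches ODE integration and its limits", {
  m <- pk_model()
  tt <- default_times()[-1]
  # typical reference parameters against the numerical oracle
  a <- conc_2cpt(tt, 1.31, 1, m$dose_pg, m$tv_cl, m$tv_vc, m$tv_q, m$tv_vp)
  b <- ode_conc_oracle(tt, 1.31, 1, m$dose_pg, m$tv_cl, m$tv_vc, m$tv_q,
                       m$tv_vp)
  expect_lt(max(abs(a / b - 1)), 1e-6)

  # random parameter sets (subset; the full sweep runs in the acceptance suite)
  pars <- random_pk_par_sets(20, seed = 3)
  for (i in seq_len(nrow(pars))) {
    ci <- conc_2cpt(tt, pars$ka[i], pars$f[i], 75e9, pars$cl[i], pars$vc[i],
                    pars$q[i], pars$vp[i])
    oi <- ode_conc_oracle(tt, pars$ka[i], pars$f[i], 75e9, pars$cl[i],
                          pars$vc[i], pars$q[i], pars$vp[i])
    keep <- oi >= 1e-9 * max(oi)   # above the solver tolerance floor
    expect_lt(max(abs(ci[keep] / oi[keep] - 1)), 1e-6)
  }

  # C(0) = 0 and non-negativity
  expect_identical(conc_2cpt(0, 1.31, 1, m$dose_pg, m$tv_cl, m$tv_vc,
                             m$tv_q, m$tv_vp), 0)
  expect_true(all(a >= 0))

  # q -> 0 collapses to the one-compartment Bateman solution
  tq <- c(0.5, 1, 2, 4, 8, 12)
  c2 <- conc_2cpt(tq, 1.31, 1, m$dose_pg, m$tv_cl, m$tv_vc, 1e-9, m$tv_vp)
  c1 <- bateman_conc(tq, 1.31, 1, m$dose_pg, m$tv_cl, m$tv_vc)
  expect_lt(max(abs(c2 / c1 - 1)), 1e-4)

  # mass balance: dense-grid AUC equals F*D/CL
  tg <- seq(0, 400, by = 0.05)
  cd <- conc_2cpt(tg, 1.31, 1, m$dose_pg, m$tv_cl, m$tv_vc, m$tv_q, m$tv_vp)
  auc <- sum(diff(tg) * (cd[-length(cd)] + cd[-1]) / 2)
  expect_equal(auc, m$dose_pg / (m$tv_cl * 1000), tolerance = 0.005)

  # removable singularity at ka == lambda is perturbed, not an error
  mc <- micro_constants(m$tv_cl, m$tv_vc, m$tv_q, m$tv_vp)
  expect_message(
    cs <- conc_2cpt(1, mc$lambda2, 1, m$dose_pg, m$tv_cl, m$tv_vc, m$tv_q,
                    m$tv_vp),
    "perturbed")
  expect_true(is.finite(cs) && cs > 0)
})

test_that("model constructor enforces the documented invariants", {
  expect_error(pk_model(tv_f_test = 1.6), "1.5")
  expect_error(pk_model(tv_f_test = 0), "1.5")
  expect_error(pk_model(corr_f_tr = 1.2), "\\[-1, 1\\]")
  expect_error(pk_model(bsv = c(cl = -0.1, vc = 1, q = 1, vp = 1, ka = 1,
                                f = 1)), ">= 0")
  expect_error(pk_model(dose_mg = 0), "dose")
  bad_corr <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3)
  bad4 <- diag(4); bad4[1, 2] <- bad4[2, 1] <- 0.99
  bad4[1, 3] <- bad4[3, 1] <- 0.99; bad4[2, 3] <- bad4[3, 2] <- -0.99
  expect_error(pk_model(corr_disposition = bad4), "positive semi-definite")
})

test_that("sampled parameters have the configured log-scale moments", {
  des <- be_design("2x4")
  m <- pk_model(bsv = c(cl = 0.91, vc = 1.17, q = 1.33, vp = 1.20,
                        ka = 0.42, f = 0.7),
                wsv = c(ka = 0, f = 0.294), corr_f_tr = 1.0)
  p <- sample_subject_params(m, 20000, des, seed = 101)
  # first reference occasion per subject
  pr <- p[p$treatment == "R", ]
  pr <- pr[order(pr$subject, pr$period), ]
  pr <- pr[!duplicated(pr$subject), ]
  expect_equal(sd(log(pr$f)), sqrt(0.7^2 + 0.294^2), tolerance = 0.01)

  # occasion-to-occasion difference of reference log F has SD wsv*sqrt(2)
  pr2 <- p[p$treatment == "R", ]
  pr2 <- pr2[order(pr2$subject, pr2$period), ]
  first <- pr2[!duplicated(pr2$subject), ]
  second <- pr2[duplicated(pr2$subject), ]
  dd <- log(first$f) - log(second$f)
  expect_equal(sd(dd), 0.294 * sqrt(2), tolerance = 0.02 * 0.294 * sqrt(2))

  # disposition parameters are identical across a subject's occasions
  expect_true(all(tapply(p$cl, p$subject, function(x) diff(range(x))) == 0))

  # configured disposition correlation is recovered
  ps <- p[!duplicated(p$subject), ]
  expect_equal(cor(log(ps$cl), log(ps$vc)), 0.5, tolerance = 0.03)
  expect_lt(abs(cor(log(ps$cl), log(ps$q))), 0.03)
})

test_that("degenerate variability collapses parameters onto typical values", {
  des <- be_design("2x2")
  m0 <- pk_model(bsv = c(cl = 0, vc = 0, q = 0, vp = 0, ka = 0, f = 0),
                 wsv = c(ka = 0, f = 0), tv_f_test = 1.1)
  p <- sample_subject_params(m0, 6, des, seed = 5)
  expect_equal(p$cl, rep(29400, nrow(p)))
  expect_equal(p$f[p$treatment == "T"],
               rep(1.1, sum(p$treatment == "T")))
  expect_equal(p$ka[p$treatment == "R"],
               rep(1.31, sum(p$treatment == "R")))

  # perfect T-R correlation with no occasion noise: log F difference constant
  m1 <- pk_model(corr_f_tr = 1, wsv = c(ka = 0, f = 0), tv_f_test = 1.1)
  p1 <- sample_subject_params(m1, 50, be_design("2x2"), seed = 6)
  dif <- tapply(seq_len(nrow(p1)), p1$subject, function(ix) {
    r <- p1[ix, ]
    log(r$f[r$treatment == "T"]) - log(r$f[r$treatment == "R"])
  })
  expect_equal(as.numeric(unlist(dif)), rep(log(1.1), 50), tolerance = 1e-12)
})

test_that("residual error model adds the configured variance and floors at zero", {
  m <- pk_model()  # additive 20, proportional 0.15
  x <- rep(1000, 1e5)
  obs <- apply_residual_error(x, m, seed = 9)
  expect_equal(sd(obs), sqrt(150^2 + 20^2), tolerance = 0.01)
  expect_true(all(obs >= 0))

  # no-error arm is the identity
  expect_identical(apply_residual_error(x, m, include_error = FALSE), x)

  # at zero prediction the observation is a floored additive draw
  z <- apply_residual_error(rep(0, 2e4), m, seed = 10)
  expect_true(all(z >= 0))
  expect_gt(mean(z == 0), 0.45)         # half the draws are negative
  expect_equal(mean(z), 20 / sqrt(2 * pi), tolerance = 0.05)

  # determinism under a fixed seed
  expect_identical(apply_residual_error(x, m, seed = 9), obs)
})
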