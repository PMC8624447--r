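# Independent oracles and small fixture builders shared across the suite.
# Everything here is deliberately coded along a different route than the
# package implementation it checks.

# ---- ODE oracle: two-compartment oral model integrated numerically --------
# depot -> central <-> peripheral, first-order absorption; F scales the
# absorbed amount. Returns pg/mL on `times`.
ode_conc_oracle <- function(times, ka, f, dose_pg, cl, vc, q, vp) {
  k10 <- cl / vc; k12 <- q / vc; k21 <- q / vp
  rhs <- function(t, y, p) {
    list(c(-ka * y[1],
           ka * y[1] - (k10 + k12) * y[2] + k21 * y[3],
           k12 * y[2] - k21 * y[3]))
  }
  y0 <- c(depot = f * dose_pg, central = 0, peripheral = 0)
  out <- deSolve::lsoda(y0, c(0, times[times > 0]), rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  conc <- out[, "central"] / (vc * 1000)
  if (times[1] == 0) conc else conc[-1]
}

# one-compartment first-order-absorption closed form (Bateman)
bateman_conc <- function(t, ka, f, dose_pg, cl, vc) {
  k10 <- cl / vc
  ka * f * dose_pg / (vc * 1000 * (ka - k10)) * (exp(-k10 * t) - exp(-ka * t))
}

# ---- least-squares oracle for the crossover GLM ---------------------------
# Builds the design matrix by hand (treatment, sequence, period, subject
# dummies) and solves the normal equations by QR; returns the treatment
# contrast, its SE and the residual df.
lsq_gmr_oracle <- function(dataset, endpoint, conf = 0.90) {
  y <- log(dataset[[endpoint]])
  trt <- as.integer(dataset$treatment == "T")
  X <- cbind(1, trt)
  for (s in unique(dataset$sequence)[-1])
    X <- cbind(X, as.integer(dataset$sequence == s))
  for (p in sort(unique(dataset$period))[-1])
    X <- cbind(X, as.integer(dataset$period == p))
  for (id in unique(dataset$subject)[-1])
    X <- cbind(X, as.integer(dataset$subject == id))
  qx <- qr(X)
  beta <- qr.coef(qx, y)
  fitted <- X[, !is.na(beta), drop = FALSE] %*% beta[!is.na(beta)]
  rss <- sum((y - fitted)^2)
  df <- length(y) - qx$rank
  s2 <- rss / df
  XtXinv <- chol2inv(qr.R(qx)[seq_len(qx$rank), seq_len(qx$rank)])
  # column 2 of X is the treatment indicator and is never pivoted out here
  keep <- qx$pivot[seq_len(qx$rank)]
  pos <- match(2L, keep)
  se <- sqrt(s2 * XtXinv[pos, pos])
  est <- unname(beta[2])
  tq <- qt(1 - (1 - conf) / 2, df)
  list(gmr = 100 * exp(est), se = se, df = df,
       ci_lower = 100 * exp(est - tq * se),
       ci_upper = 100 * exp(est + tq * se),
       sigma_w = sqrt(s2))
}

# residual-SD oracle for the within-reference model (sequence + period +
# subject on the reference records), same hand-built-matrix route
lsq_swr_oracle <- function(dataset, endpoint = "cmax") {
  ref <- dataset[dataset$treatment == "R", , drop = FALSE]
  y <- log(ref[[endpoint]])
  X <- matrix(1, nrow(ref), 1)
  for (s in unique(ref$sequence)[-1])
    X <- cbind(X, as.integer(ref$sequence == s))
  for (p in sort(unique(ref$period))[-1])
    X <- cbind(X, as.integer(ref$period == p))
  for (id in unique(ref$subject)[-1])
    X <- cbind(X, as.integer(ref$subject == id))
  qx <- qr(X)
  fitted <- qr.fitted(qx, y)
  df <- length(y) - qx$rank
  list(swr = sqrt(sum((y - fitted)^2) / df), df = df)
}

# ---- brute-force RSABE bound oracle ---------------------------------------
# From raw ilat/dlat series: sequence means via lm dummies, unweighted mean
# of sequence means, Howe-type combination written out step by step.
rsabe_oracle <- function(ilat, iseq, dlat, dseq) {
  fit_i <- lm(ilat ~ 0 + factor(iseq))
  coefs <- coef(fit_i)
  dbar <- mean(coefs)
  vc <- vcov(fit_i)
  se <- sqrt(sum(diag(vc)) / length(coefs)^2)
  df_i <- df.residual(fit_i)

  fit_d <- lm(dlat ~ 0 + factor(dseq))
  s2d <- sum(residuals(fit_d)^2) / df.residual(fit_d)
  s2wr <- s2d / 2
  df_d <- df.residual(fit_d)

  theta <- (log(1.25) / 0.25)^2
  x <- dbar^2
  boundx <- (abs(dbar) + qt(0.95, df_i) * se)^2
  y <- -theta * s2wr
  boundy <- y * df_d / qchisq(0.95, df_d)
  list(upper = x + y + sqrt((boundx - x)^2 + (boundy - y)^2),
       dbar = dbar, se = se, df_i = df_i, s2wr = s2wr, df_d = df_d)
}

# ---- fixture builders ------------------------------------------------------

# deterministic endpoint dataset: every subject's log T - log R difference is
# exactly log(ratio); subject baselines vary
constant_ratio_2x2 <- function(n = 4, ratio = 1.1) {
  base <- seq(6, 7, length.out = n)
  seqs <- rep(c("TR", "RT"), length.out = n)
  rows <- lapply(seq_len(n), function(i) {
    if (seqs[i] == "TR") {
      data.frame(subject = i, sequence = "TR", period = 1:2,
                 treatment = c("T", "R"),
                 cmax = exp(c(base[i] + log(ratio), base[i])),
                 auc = exp(c(base[i] + log(ratio), base[i])))
    } else {
      data.frame(subject = i, sequence = "RT", period = 1:2,
                 treatment = c("R", "T"),
                 cmax = exp(c(base[i], base[i] + log(ratio))),
                 auc = exp(c(base[i], base[i] + log(ratio))))
    }
  })
  d <- do.call(rbind, rows)
  d$log_cmax <- log(d$cmax); d$log_auc <- log(d$auc)
  d
}

# noisy 2x2 endpoint table with known seed, for oracle comparisons
noisy_2x2 <- function(n = 4, seed = 7, sd = 0.2) {
  set.seed(seed)
  d <- constant_ratio_2x2(n, ratio = 1.05)
  d$cmax <- d$cmax * exp(rnorm(nrow(d), 0, sd))
  d$auc <- d$auc * exp(rnorm(nrow(d), 0, sd))
  d$log_cmax <- log(d$cmax); d$log_auc <- log(d$auc)
  d
}

# balanced 2x4-style reference table where each subject's two reference
# log values differ by exactly +/- d (signs balanced within sequence)
balanced_ref_2x4 <- function(d = 0.3, n_per_seq = 4) {
  rows <- list()
  id <- 0
  for (sq in c("TRTR", "RTRT")) {
    r_periods <- if (sq == "TRTR") c(2L, 4L) else c(1L, 3L)
    t_periods <- setdiff(1:4, r_periods)
    for (i in seq_len(n_per_seq)) {
      id <- id + 1
      sign <- if (i %% 2 == 0) 1 else -1
      base <- 6 + 0.1 * id
      rows[[id]] <- data.frame(
        subject = id, sequence = sq,
        period = c(t_periods, r_periods),
        treatment = c("T", "T", "R", "R"),
        cmax = exp(c(base, base,
                     base + sign * d / 2, base - sign * d / 2)),
        auc = exp(c(base, base,
                    base + sign * d / 2, base - sign * d / 2)))
    }
  }
  out <- do.call(rbind, rows)
  out$log_cmax <- log(out$cmax); out$log_auc <- log(out$auc)
  out[order(out$subject, out$period), ]
}

trapz_int <- function(x, y)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

random_pk_par_sets <- function(n, seed) {
  set.seed(seed)
  data.frame(
    cl = exp(runif(n, log(1e3), log(5e4))),
    vc = exp(runif(n, log(1e3), log(5e4))),
    q = exp(runif(n, log(1e2), log(1e4))),
    vp = exp(runif(n, log(1e3), log(1e5))),
    ka = exp(runif(n, log(0.3), log(4))),
    f = runif(n, 0.5, 1.2)
  )
}
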