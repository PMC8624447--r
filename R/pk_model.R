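#' Population pharmacokinetic model for bioequivalence simulation
#'
#' Defines a two-compartment, first-order-absorption population PK model with
#' lognormal between-subject (BSV) and within-subject/occasion (WSV) random
#' effects, treatment-specific absorption rate (Ka) and bioavailability (F),
#' and a combined additive + proportional residual-error model. The defaults
#' are the clopidogrel-like parameter set used throughout the package:
#' typical disposition values CL = 29400 L/h, Vc = 14600 L, Q = 1040 L/h,
#' Vp = 57300 L, Ka(test/ref) = 1.34/1.31 1/h, with BSV SDs
#' (0.91, 1.17, 1.33, 1.20, 0.42, 0.7) for (CL, Vc, Q, Vp, Ka, F) on the log
#' scale, occasion-level WSV for Ka (0.1) and F (0.294), test-reference
#' correlations of 0.9 (F) and 0.8 (Ka), and residual error 20 pg/mL additive
#' plus 15% proportional.
#'
#' The ratio `tv_f_test / tv_f_ref` is the true geometric mean ratio (GMR) of
#' exposure between test and reference, and the occasion-level SD of log F
#' (`wsv["f"]`) is the main dial for within-subject variability: because the
#' model is linear in F, the within-subject SD of log Cmax and log AUC equals
#' `wsv["f"]` when all other within-subject sources are off.
#'
#' @param tv_cl,tv_vc,tv_q,tv_vp Typical clearance (L/h), central volume (L),
#'   inter-compartmental clearance (L/h) and peripheral volume (L).
#' @param tv_ka_test,tv_ka_ref Typical first-order absorption rate constants
#'   (1/h) for the test and reference formulations.
#' @param tv_f_test,tv_f_ref Typical bioavailability fractions; their ratio is
#'   the true GMR. Must lie in (0, 1.5].
#' @param bsv Named numeric vector of between-subject SDs (log scale) for
#'   `cl`, `vc`, `q`, `vp`, `ka`, `f`.
#' @param wsv Named numeric vector of occasion-level within-subject SDs (log
#'   scale) for `ka` and `f`; disposition parameters have no occasion effects.
#' @param corr_f_tr,corr_ka_tr Correlation between the subject-level test and
#'   reference random effects of F and Ka.
#' @param corr_cl_vc,corr_q_vp Correlations among the disposition random
#'   effects; all other disposition cross-correlations are zero unless a full
#'   matrix is supplied.
#' @param corr_disposition Optional 4x4 correlation matrix for the disposition
#'   effects in order (CL, Vc, Q, Vp); overrides `corr_cl_vc`/`corr_q_vp`.
#' @param error_additive Additive residual SD in pg/mL.
#' @param error_proportional Proportional residual SD (fraction).
#' @param dose_mg Administered dose in mg; stored internally in pg so that
#'   simulated concentrations are in pg/mL.
#' @return An object of class `pk_model`.
#' @examples
#' m <- pk_model()
#' m
#' # a true GMR of 110% with within-subject CV of 30% on bioavailability
#' pk_model(tv_f_test = 1.10, wsv = c(ka = 0.1, f = cv2sigma(0.30)))
#' @seealso [validation_pk_model()] for the zero-error comparison preset,
#'   [sample_subject_params()], [simulate_trial()].
#' @export
pk_model <- function(tv_cl = 29400, tv_vc = 14600, tv_q = 1040, tv_vp = 57300,
                     tv_ka_test = 1.34, tv_ka_ref = 1.31,
                     tv_f_test = 1.0, tv_f_ref = 1.0,
                     bsv = c(cl = 0.91, vc = 1.17, q = 1.33, vp = 1.20,
                             ka = 0.42, f = 0.7),
                     wsv = c(ka = 0.1, f = 0.294),
                     corr_f_tr = 0.9, corr_ka_tr = 0.8,
                     corr_cl_vc = 0.5, corr_q_vp = 0.5,
                     corr_disposition = NULL,
                     error_additive = 20, error_proportional = 0.15,
                     dose_mg = 75) {
  bsv <- as_named(bsv, c("cl", "vc", "q", "vp", "ka", "f"), "bsv")
  wsv <- as_named(wsv, c("ka", "f"), "wsv")
  for (v in c(tv_cl, tv_vc, tv_q, tv_vp, tv_ka_test, tv_ka_ref))
    if (!is.finite(v) || v <= 0)
      stop_invalid("typical PK values must be strictly positive")
  if (any(!is.finite(c(bsv, wsv))) || any(c(bsv, wsv) < 0))
    stop_invalid("all random-effect SDs must be finite and >= 0")
  for (f in c(tv_f_test, tv_f_ref))
    if (!is.finite(f) || f <= 0 || f > 1.5)
      stop_invalid("bioavailability typical values must lie in (0, 1.5]")
  for (r in c(corr_f_tr, corr_ka_tr, corr_cl_vc, corr_q_vp))
    if (!is.finite(r) || abs(r) > 1)
      stop_invalid("correlations must lie in [-1, 1]")
  if (!is.finite(error_additive) || error_additive < 0 ||
      !is.finite(error_proportional) || error_proportional < 0)
    stop_invalid("residual error SDs must be >= 0")
  if (!is.finite(dose_mg) || dose_mg <= 0)
    stop_invalid("dose must be > 0")

  if (is.null(corr_disposition)) {
    corr_disposition <- diag(4)
    corr_disposition[1, 2] <- corr_disposition[2, 1] <- corr_cl_vc
    corr_disposition[3, 4] <- corr_disposition[4, 3] <- corr_q_vp
  } else {
    corr_disposition <- as.matrix(corr_disposition)
    if (!identical(dim(corr_disposition), c(4L, 4L)) ||
        any(abs(corr_disposition) > 1) ||
        any(abs(corr_disposition - t(corr_disposition)) > 1e-12) ||
        any(abs(diag(corr_disposition) - 1) > 1e-12))
      stop_invalid("corr_disposition must be a symmetric 4x4 correlation ",
                   "matrix for (CL, Vc, Q, Vp)")
  }
  dimnames(corr_disposition) <- list(c("cl", "vc", "q", "vp"),
                                     c("cl", "vc", "q", "vp"))
  check_psd(corr_disposition, "disposition")
  check_psd(matrix(c(1, corr_f_tr, corr_f_tr, 1), 2), "F test-reference")
  check_psd(matrix(c(1, corr_ka_tr, corr_ka_tr, 1), 2), "Ka test-reference")

  structure(list(
    tv_cl = tv_cl, tv_vc = tv_vc, tv_q = tv_q, tv_vp = tv_vp,
    tv_ka_test = tv_ka_test, tv_ka_ref = tv_ka_ref,
    tv_f_test = tv_f_test, tv_f_ref = tv_f_ref,
    bsv = bsv, wsv = wsv,
    corr_f_tr = corr_f_tr, corr_ka_tr = corr_ka_tr,
    corr_disposition = corr_disposition,
    error_additive = error_additive,
    error_proportional = error_proportional,
    dose_mg = dose_mg,
    dose_pg = dose_mg * 1e9
  ), class = "pk_model")
}

as_named <- function(x, nms, what) {
  x <- unlist(x)
  if (is.null(names(x)) && length(x) == length(nms)) names(x) <- nms
  if (!all(nms %in% names(x)))
    stop_invalid(what, " must be named with: ", paste(nms, collapse = ", "))
  x[nms]
}

check_psd <- function(corr, block) {
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop_invalid("correlation matrix for the ", block,
                 " block is not positive semi-definite")
  invisible(TRUE)
}

#' @export
print.pk_model <- function(x, ...) {
  cat("Two-compartment oral population PK model\n")
  cat(sprintf("  CL %.4g L/h, Vc %.4g L, Q %.4g L/h, Vp %.4g L; dose %g mg\n",
              x$tv_cl, x$tv_vc, x$tv_q, x$tv_vp, x$dose_mg))
  cat(sprintf("  Ka test/ref: %.3g/%.3g 1/h;  F test/ref: %.3g/%.3g (true GMR %.1f%%)\n",
              x$tv_ka_test, x$tv_ka_ref, x$tv_f_test, x$tv_f_ref,
              100 * x$tv_f_test / x$tv_f_ref))
  cat(sprintf("  BSV (log SD): %s\n",
              paste(sprintf("%s=%.3g", names(x$bsv), x$bsv), collapse = ", ")))
  cat(sprintf("  WSV (log SD): ka=%.3g, f=%.3g (within-subject CV of F: %.1f%%)\n",
              x$wsv["ka"], x$wsv["f"], 100 * sigma2cv(x$wsv[["f"]])))
  cat(sprintf("  corr T-R: F %.2g, Ka %.2g;  residual error: %.3g pg/mL + %.3g prop.\n",
              x$corr_f_tr, x$corr_ka_tr, x$error_additive, x$error_proportional))
  invisible(x)
}

#' Validation parameter set matching LMM-based power benchmarks
#'
#' Returns the model variant used for cross-checking the simulator against
#' linear-mixed-model-based power results from the literature: identical PK
#' parameters for test and reference within a subject (test-reference
#' correlations of 1.0), occasion-level variability confined to
#' bioavailability, and no residual concentration error. Under this
#' configuration the within-reference CV of Cmax and AUC equals
#' `sigma2cv(wsv_f)` exactly (0.30 at the default `wsv_f = 0.294`).
#'
#' Because the comparison conditions require the PK parameters of test and
#' reference to coincide within a subject, the absorption rate typical value
#' is shared (reference value for both products), so the true GMR of Cmax
#' and AUC is exactly `tv_f_test`.
#'
#' @param tv_f_test Typical test bioavailability (true GMR, reference = 1).
#' @param wsv_f Occasion-level SD of log F; 0.294 corresponds to a
#'   within-subject CV of 30%.
#' @param ... Further arguments passed to [pk_model()].
#' @return A `pk_model`.
#' @export
validation_pk_model <- function(tv_f_test = 1.0, wsv_f = 0.294, ...) {
  pk_model(tv_f_test = tv_f_test,
           tv_ka_test = 1.31, tv_ka_ref = 1.31,
           wsv = c(ka = 0, f = wsv_f),
           corr_f_tr = 1.0, corr_ka_tr = 1.0,
           error_additive = 0, error_proportional = 0, ...)
}

#' Micro rate constants and disposition eigenvalues
#'
#' Converts the macro parameters of a two-compartment model to the micro rate
#' constants k10 = CL/Vc, k12 = Q/Vc, k21 = Q/Vp and the two disposition
#' eigenvalues, the roots of s^2 - (k10+k12+k21) s + k10 k21 = 0, with
#' `lambda1 <= lambda2` (minus root first).
#'
#' @param cl,vc,q,vp Clearances (L/h) and volumes (L), all > 0.
#' @return A list of class `micro_constants` with elements `k10`, `k12`,
#'   `k21`, `lambda1`, `lambda2`.
#' @examples
#' micro_constants(29400, 14600, 1040, 57300)
#' @export
micro_constants <- function(cl, vc, q, vp) {
  if (any(!is.finite(c(cl, vc, q, vp))) || any(c(cl, vc, q, vp) <= 0))
    stop_invalid("micro_constants: all inputs must be strictly positive")
  k10 <- cl / vc
  k12 <- q / vc
  k21 <- q / vp
  s <- k10 + k12 + k21
  # discriminant is (k10+k12+k21)^2 - 4 k10 k21 >= (k10-k21)^2 >= 0
  disc <- s^2 - 4 * k10 * k21
  root <- sqrt(max(disc, 0))
  structure(list(k10 = k10, k12 = k12, k21 = k21,
                 lambda1 = (s - root) / 2, lambda2 = (s + root) / 2),
            class = "micro_constants")
}

#' @export
print.micro_constants <- function(x, ...) {
  cat(sprintf("k10 = %.6g, k12 = %.6g, k21 = %.6g (1/h)\n", x$k10, x$k12, x$k21))
  cat(sprintf("lambda1 = %.6g, lambda2 = %.6g (1/h)\n", x$lambda1, x$lambda2))
  invisible(x)
}

#' Closed-form concentration of the two-compartment oral model
#'
#' Evaluates the three-exponential solution of the two-compartment model with
#' first-order absorption,
#' \deqn{C(t) = \frac{K_a F D}{V_c}\left[
#'   \frac{(k_{21}-\lambda_1)e^{-\lambda_1 t}}{(\lambda_2-\lambda_1)(K_a-\lambda_1)} +
#'   \frac{(k_{21}-\lambda_2)e^{-\lambda_2 t}}{(K_a-\lambda_2)(\lambda_1-\lambda_2)} +
#'   \frac{(k_{21}-K_a)e^{-K_a t}}{(\lambda_1-K_a)(\lambda_2-K_a)}\right].}
#' Volumes are taken in litres and the dose in pg, so concentrations come out
#' in pg/mL. When `ka` falls within relative tolerance 1e-9 of a disposition
#' eigenvalue (a removable singularity) it is perturbed by 1e-6 relative and a
#' message is emitted.
#'
#' All arguments are vectorised and recycled to a common length.
#'
#' @param t Time since dosing in hours, >= 0.
#' @param ka Absorption rate constant (1/h).
#' @param f Bioavailability fraction.
#' @param dose Dose in pg.
#' @param cl,vc,q,vp Individual disposition parameters (L/h, L).
#' @return Concentration in pg/mL (non-negative; exactly 0 at t = 0).
#' @examples
#' conc_2cpt(c(0, 1, 2, 6), ka = 1.31, f = 1, dose = 75e9,
#'           cl = 29400, vc = 14600, q = 1040, vp = 57300)
#' @export
conc_2cpt <- function(t, ka, f, dose, cl, vc, q, vp) {
  if (any(t < 0)) stop_invalid("conc_2cpt: t must be >= 0")
  n <- max(lengths(list(t, ka, f, dose, cl, vc, q, vp)))
  t <- rep_len(t, n); ka <- rep_len(ka, n); f <- rep_len(f, n)
  dose <- rep_len(dose, n); cl <- rep_len(cl, n); vc <- rep_len(vc, n)
  q <- rep_len(q, n); vp <- rep_len(vp, n)

  k10 <- cl / vc
  k12 <- q / vc
  k21 <- q / vp
  s <- k10 + k12 + k21
  root <- sqrt(pmax(s^2 - 4 * k10 * k21, 0))
  l1 <- (s - root) / 2
  l2 <- (s + root) / 2

  near <- (abs(ka - l1) < 1e-9 * pmax(l1, .Machine$double.xmin)) |
          (abs(ka - l2) < 1e-9 * pmax(l2, .Machine$double.xmin))
  if (any(near)) {
    message("conc_2cpt: ka within tolerance of a disposition eigenvalue for ",
            sum(near), " evaluation(s); perturbed by 1e-6 relative")
    ka[near] <- ka[near] * (1 + 1e-6)
  }

  vc_ml <- vc * 1000  # L -> mL so dose in pg gives pg/mL
  cc <- (ka * f * dose / vc_ml) * (
    (k21 - l1) * exp(-l1 * t) / ((l2 - l1) * (ka - l1)) +
    (k21 - l2) * exp(-l2 * t) / ((ka - l2) * (l1 - l2)) +
    (k21 - ka) * exp(-ka * t) / ((l1 - ka) * (l2 - ka)))
  # the three terms cancel analytically at t = 0; force the exact zero and
  # clamp any floating-point residue elsewhere
  cc[t == 0] <- 0
  pmax(cc, 0)
}

#' Default blood-sampling schedule
#'
#' Dense around the expected time of maximal concentration (Ka near 1.3 1/h
#' puts Tmax close to 1 h) and extending to 24 h for the AUC tail.
#'
#' @return Numeric vector of sampling times in hours, starting at 0.
#' @export
default_times <- function() {
  c(0, 0.25, 0.5, 0.75, 1, 1.25, 1.5, 2, 2.5, 3, 4, 6, 8, 12, 24)
}

#' Sample individual and occasion-level PK parameters
#'
#' Draws, for each subject, one joint lognormal realisation of the disposition
#' parameters (CL, Vc, Q, Vp; correlated via the model's disposition
#' correlation matrix) shared across all periods, a bivariate (test,
#' reference) subject-level effect for F and for Ka with the configured
#' test-reference correlations, and an independent occasion-level effect for F
#' and Ka at every administration. Each parameter is
#' `typical_value(treatment) * exp(eta + kappa)`, so all values are strictly
#' positive and the mean of the log individual effects is 0.
#'
#' @param model A [pk_model()].
#' @param n_subjects Number of subjects.
#' @param design A [be_design()]; determines periods and treatments.
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @param sequences Optional character vector of per-subject sequence labels;
#'   defaults to a balanced assignment drawn inside this call.
#' @return A data.frame with one row per subject x period: columns `subject`,
#'   `sequence`, `period`, `treatment` ("T"/"R"), and the individual `cl`,
#'   `vc`, `q`, `vp`, `ka`, `f`.
#' @export
sample_subject_params <- function(model, n_subjects, design, seed = NULL,
                                  sequences = NULL) {
  stopifnot(inherits(model, "pk_model"), inherits(design, "be_design"))
  if (n_subjects < 1) stop_invalid("n_subjects must be >= 1")
  with_rng_seed(seed, {
    if (is.null(sequences))
      sequences <- assign_sequences(n_subjects, design)
    stopifnot(length(sequences) == n_subjects)
    P <- design$n_periods
    n <- n_subjects

    sd_disp <- model$bsv[c("cl", "vc", "q", "vp")]
    sigma_disp <- diag(sd_disp) %*% model$corr_disposition %*% diag(sd_disp)
    eta_disp <- MASS::mvrnorm(n, mu = rep(0, 4), Sigma = sigma_disp)
    eta_f  <- bivariate_tr(n, model$bsv[["f"]],  model$corr_f_tr)
    eta_ka <- bivariate_tr(n, model$bsv[["ka"]], model$corr_ka_tr)
    kap_f  <- matrix(stats::rnorm(n * P, 0, model$wsv[["f"]]),  n, P)
    kap_ka <- matrix(stats::rnorm(n * P, 0, model$wsv[["ka"]]), n, P)

    seq_mat <- do.call(rbind, strsplit(sequences, ""))
    subj <- rep(seq_len(n), each = P)
    per <- rep(seq_len(P), times = n)
    trt <- as.vector(t(seq_mat))
    is_t <- trt == "T"
    col_tr <- ifelse(is_t, 1L, 2L)

    data.frame(
      subject = subj,
      sequence = rep(sequences, each = P),
      period = per,
      treatment = trt,
      cl = model$tv_cl * exp(eta_disp[subj, 1]),
      vc = model$tv_vc * exp(eta_disp[subj, 2]),
      q  = model$tv_q  * exp(eta_disp[subj, 3]),
      vp = model$tv_vp * exp(eta_disp[subj, 4]),
      ka = ifelse(is_t, model$tv_ka_test, model$tv_ka_ref) *
        exp(eta_ka[cbind(subj, col_tr)] + kap_ka[cbind(subj, per)]),
      f  = ifelse(is_t, model$tv_f_test, model$tv_f_ref) *
        exp(eta_f[cbind(subj, col_tr)] + kap_f[cbind(subj, per)]),
      stringsAsFactors = FALSE
    )
  })
}

# bivariate normal (test, ref) subject effects with common SD and correlation
bivariate_tr <- function(n, sd, corr) {
  sigma <- sd^2 * matrix(c(1, corr, corr, 1), 2)
  MASS::mvrnorm(n, mu = c(0, 0), Sigma = sigma)
}

#' Apply the residual concentration-error model
#'
#' Observed concentrations are `C_pred * (1 + eps_p) + eps_a` with independent
#' `eps_p ~ N(0, error_proportional^2)` and `eps_a ~ N(0, error_additive^2)`
#' per sample; negative results are floored at 0 and retained (no LLOQ rule).
#' With `include_error = FALSE` (the error-exclusion sensitivity arm) the
#' predictions are returned unchanged.
#'
#' @param conc Numeric vector or matrix of predicted concentrations (pg/mL).
#' @param model A [pk_model()] supplying the two error SDs.
#' @param seed Optional integer seed.
#' @param include_error Apply the error model? Default `TRUE`.
#' @return Observed concentrations, same shape as `conc`, all >= 0.
#' @export
apply_residual_error <- function(conc, model, seed = NULL,
                                 include_error = TRUE) {
  stopifnot(inherits(model, "pk_model"))
  if (!include_error) return(conc)
  with_rng_seed(seed, {
    n <- length(conc)
    obs <- conc * (1 + stats::rnorm(n, 0, model$error_proportional)) +
      stats::rnorm(n, 0, model$error_additive)
    out <- pmax(obs, 0)
    attributes(out) <- attributes(conc)
    out
  })
}
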