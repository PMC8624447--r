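#' Convert a within-subject CV to a log-scale SD, and back
#'
#' For lognormal endpoints the within-subject coefficient of variation CV and
#' the log-scale SD sigma are linked by `sigma = sqrt(log(1 + CV^2))`. The
#' regulatory highly-variable-drug threshold CV = 30% corresponds to
#' sigma = 0.294 (3 decimals), and the EMA scaling cap CV = 50% to
#' sigma = 0.47238.
#'
#' @param cv Within-subject CV as a fraction (0.30 for 30%), >= 0.
#' @param sigma Log-scale SD, >= 0.
#' @return The converted value.
#' @examples
#' cv2sigma(0.30)   # 0.2936
#' sigma2cv(0.294)  # 0.3004
#' @export
cv2sigma <- function(cv) {
  if (any(!is.finite(cv)) || any(cv < 0)) stop_invalid("cv must be >= 0")
  sqrt(log(1 + cv^2))
}

#' @rdname cv2sigma
#' @export
sigma2cv <- function(sigma) {
  if (any(!is.finite(sigma)) || any(sigma < 0))
    stop_invalid("sigma must be >= 0")
  sqrt(exp(sigma^2) - 1)
}

# log-scale endpoint column for a trial dataset
log_endpoint <- function(dataset, endpoint = c("cmax", "auc")) {
  endpoint <- match.arg(endpoint)
  col <- paste0("log_", endpoint)
  if (!col %in% names(dataset))
    dataset[[col]] <- log(dataset[[endpoint]])
  dataset[[col]]
}

#' Within-reference SD from the replicated reference administrations
#'
#' Fits the fixed-effects linear model of the log-transformed reference
#' endpoint on sequence, period and subject-within-sequence (all fixed
#' effects, least squares) using only the reference administrations, and
#' returns the root residual mean square as the estimated within-reference
#' SD (SWR) together with its residual degrees of freedom. Requires a design
#' in which the reference is administered at least twice per subject; SWR is
#' not estimable in a 2x2 design.
#'
#' @param dataset Trial dataset (long endpoint table).
#' @param design A [be_design()]; must have `replicated_reference = TRUE`.
#' @param endpoint `"cmax"` or `"auc"`.
#' @return List with `swr` and `df` (residual degrees of freedom).
#' @export
estimate_swr <- function(dataset, design, endpoint = c("cmax", "auc")) {
  stopifnot(inherits(design, "be_design"))
  if (!design$replicated_reference)
    stop_invalid("SWR is not estimable in the ", design$name,
                 " design: the reference is not replicated")
  endpoint <- match.arg(endpoint)
  ref <- dataset[dataset$treatment == "R", , drop = FALSE]
  logy <- log_endpoint(ref, endpoint)
  d <- data.frame(logy = logy,
                  sequence = factor(ref$sequence),
                  period = factor(ref$period),
                  subject = factor(ref$subject))
  fit <- stats::lm(logy ~ sequence + period + subject, data = d)
  df <- stats::df.residual(fit)
  if (df < 1)
    stop_invalid("no residual degrees of freedom to estimate SWR")
  list(swr = sqrt(sum(stats::residuals(fit)^2) / df), df = df)
}

#' EMA expanded acceptance limits for highly variable drugs
#'
#' Widens the bioequivalence acceptance range according to the estimated
#' within-reference SD: the limits are `100 * exp(-k * SWR)` and
#' `100 * exp(+k * SWR)` with the regulatory constant k = 0.760, capped at
#' the range corresponding to a within-subject CV of 50%, i.e.
#' [69.84%, 143.19%]. The limits are log-symmetric (lower * upper = 100^2).
#' Callers apply these only when SWR >= 0.294; below that the conventional
#' 80-125% range holds.
#'
#' @param swr Estimated within-reference log-scale SD.
#' @return Numeric vector `c(lower, upper)` in percent (unrounded; report
#'   with 2 decimals).
#' @examples
#' ema_expanded_limits(cv2sigma(0.50))  # capped: 69.84 143.19
#' @export
ema_expanded_limits <- function(swr) {
  if (!is.finite(swr) || swr < 0) stop_invalid("swr must be >= 0")
  k <- 0.760
  sigma_cap <- cv2sigma(0.50)
  upper <- 100 * exp(k * min(swr, sigma_cap))
  c(lower = 1e4 / upper, upper = upper)
}

#' Geometric mean ratio and 90% CI from the fixed-effects crossover model
#'
#' Fits the log-transformed endpoint on treatment, sequence, period and
#' subject-within-sequence as fixed effects (ordinary least squares) and
#' returns the back-transformed treatment contrast (test minus reference)
#' with its two-sided 90% confidence interval from the t distribution at the
#' residual degrees of freedom.
#'
#' @param dataset Trial dataset.
#' @param endpoint `"cmax"` or `"auc"`.
#' @param conf Two-sided confidence level (0.90 for bioequivalence).
#' @return List with `gmr`, `ci_lower`, `ci_upper` (percent), `se`, `df` and
#'   `sigma_w` (root residual mean square, the within-subject SD of the model).
#' @export
glm_gmr_ci <- function(dataset, endpoint = c("cmax", "auc"), conf = 0.90) {
  endpoint <- match.arg(endpoint)
  logy <- log_endpoint(dataset, endpoint)
  d <- data.frame(logy = logy,
                  treatment = factor(dataset$treatment, levels = c("R", "T")),
                  sequence = factor(dataset$sequence),
                  period = factor(dataset$period),
                  subject = factor(dataset$subject))
  if (nlevels(d$sequence) < 2)
    stop_invalid("degenerate design: all subjects in one sequence")
  fit <- stats::lm(logy ~ treatment + sequence + period + subject, data = d)
  cf <- stats::coef(summary(fit))
  if (!"treatmentT" %in% rownames(cf))
    stop_invalid("treatment contrast not estimable from this dataset")
  est <- cf["treatmentT", "Estimate"]
  se <- cf["treatmentT", "Std. Error"]
  df <- stats::df.residual(fit)
  if (df < 1 || !is.finite(se))
    stop_invalid("insufficient residual degrees of freedom for the ",
                 "treatment contrast")
  tq <- stats::qt(1 - (1 - conf) / 2, df)
  list(gmr = 100 * exp(est),
       ci_lower = 100 * exp(est - tq * se),
       ci_upper = 100 * exp(est + tq * se),
       se = se, df = df, sigma_w = summary(fit)$sigma)
}

#' GMR and 90% CI from the FDA five-variance-term mixed model
#'
#' REML fit of the log endpoint on treatment, sequence and period (fixed)
#' with subject-level random effects that differ between test and reference
#' (between-subject variance for each product plus their covariance) and
#' treatment-specific residual variances (within-subject variance for each
#' product) - five variance terms in total. Used for the unscaled branch of
#' the FDA analysis of full-replicate (2x4) designs, where it typically
#' yields a larger standard error for the treatment difference than the
#' fixed-effects model. On convergence failure the fixed-effects
#' [glm_gmr_ci()] result is returned with `fallback = TRUE`.
#'
#' @inheritParams glm_gmr_ci
#' @return As [glm_gmr_ci()], plus `fallback` (logical).
#' @export
mixed_gmr_ci <- function(dataset, endpoint = c("cmax", "auc"), conf = 0.90) {
  endpoint <- match.arg(endpoint)
  logy <- log_endpoint(dataset, endpoint)
  d <- data.frame(logy = logy,
                  treatment = factor(dataset$treatment, levels = c("R", "T")),
                  sequence = factor(dataset$sequence),
                  period = factor(dataset$period),
                  subject = factor(dataset$subject))
  res <- tryCatch({
    fit <- nlme::lme(logy ~ treatment + sequence + period, data = d,
                     random = ~ 0 + treatment | subject,
                     weights = nlme::varIdent(form = ~ 1 | treatment),
                     method = "REML",
                     control = nlme::lmeControl(opt = "optim",
                                                maxIter = 200,
                                                msMaxIter = 200,
                                                returnObject = FALSE))
    tt <- summary(fit)$tTable
    est <- tt["treatmentT", "Value"]
    se <- tt["treatmentT", "Std.Error"]
    df <- tt["treatmentT", "DF"]
    tq <- stats::qt(1 - (1 - conf) / 2, df)
    list(gmr = 100 * exp(est),
         ci_lower = 100 * exp(est - tq * se),
         ci_upper = 100 * exp(est + tq * se),
         se = se, df = df, sigma_w = fit$sigma, fallback = FALSE)
  }, error = function(e) NULL)
  if (is.null(res)) {
    res <- glm_gmr_ci(dataset, endpoint, conf)
    res$fallback <- TRUE
  }
  res
}

# conventional unscaled acceptance range, percent
abe_limits <- function() c(lower = 80, upper = 125)

ci_within <- function(ci_lower, ci_upper, limits) {
  ci_lower >= limits[["lower"]] && ci_upper <= limits[["upper"]]
}

# assemble one guideline x endpoint result row
guideline_row <- function(guideline, endpoint, method, swr, gmr, ci_lower,
                          ci_upper, limits, pass, note = "") {
  data.frame(guideline = guideline, endpoint = endpoint, method = method,
             swr = swr, gmr = gmr, ci_lower = ci_lower, ci_upper = ci_upper,
             acc_lower = limits[["lower"]], acc_upper = limits[["upper"]],
             pass = pass, note = note, stringsAsFactors = FALSE)
}

new_be_decision <- function(guideline, rows) {
  structure(list(guideline = guideline, table = rows,
                 pass = all(rows$pass)),
            class = "be_decision")
}

#' @export
print.be_decision <- function(x, digits = 2, ...) {
  cat(sprintf("%s bioequivalence decision: %s\n", x$guideline,
              if (x$pass) "PASS" else "FAIL"))
  tb <- x$table
  for (i in seq_len(nrow(tb))) {
    cat(sprintf("  %-4s %-8s GMR %6.2f%%  90%% CI [%6.2f, %6.2f]  limits [%6.2f, %6.2f]%s  %s\n",
                tb$endpoint[i], paste0("(", tb$method[i], ")"), tb$gmr[i],
                tb$ci_lower[i], tb$ci_upper[i], tb$acc_lower[i],
                tb$acc_upper[i],
                ifelse(is.na(tb$swr[i]), "",
                       sprintf("  SWR %.3f", tb$swr[i])),
                ifelse(tb$pass[i], "pass", "fail")))
  }
  invisible(x)
}

#' EMA missing-data inclusion rule
#'
#' Retains the subjects that provide at least one test and at least one
#' reference endpoint value; only these contribute to the EMA analysis.
#'
#' @param dataset Trial dataset.
#' @return The filtered dataset.
#' @export
ema_filter <- function(dataset) {
  has_t <- tapply(dataset$treatment == "T", dataset$subject, any)
  has_r <- tapply(dataset$treatment == "R", dataset$subject, any)
  keep_ids <- names(has_t)[has_t & has_r[names(has_t)]]
  dataset[as.character(dataset$subject) %in% keep_ids, , drop = FALSE]
}

# pure EMA rule composition for one Cmax result; exported building block so
# the acceptance logic is testable without simulating
ema_cmax_rule <- function(swr, gmr, ci_lower, ci_upper) {
  if (!is.na(swr) && swr >= 0.294) {
    limits <- ema_expanded_limits(swr)
    pass <- ci_within(ci_lower, ci_upper, limits) && gmr >= 80 && gmr <= 125
    list(method = "scaled", limits = limits, pass = pass)
  } else {
    limits <- abe_limits()
    list(method = "unscaled", limits = limits,
         pass = ci_within(ci_lower, ci_upper, limits))
  }
}

#' Bioequivalence decision under the EMA procedure
#'
#' Applies the EMA average-bioequivalence-with-expanded-limits procedure:
#' all designs are analysed with the fixed-effects model ([glm_gmr_ci()]);
#' in replicate designs the within-reference SD of Cmax is estimated from
#' the reference administrations, and if SWR >= 0.294 the Cmax acceptance
#' range is widened via [ema_expanded_limits()] with the additional
#' constraint that the GMR point estimate lie within 80-125%. Scaling is
#' never applied to AUC, whose 90% CI must fall within 80-125% regardless of
#' variability, and never in the 2x2 design (SWR not estimable). Overall
#' bioequivalence requires both endpoints to pass. Subjects lacking either a
#' test or a reference value are excluded first ([ema_filter()]).
#'
#' @param dataset Trial dataset.
#' @param design A [be_design()].
#' @return A `be_decision` object.
#' @export
ema_decision <- function(dataset, design) {
  stopifnot(inherits(design, "be_design"))
  dataset <- ema_filter(dataset)
  res_cmax <- glm_gmr_ci(dataset, "cmax")
  res_auc <- glm_gmr_ci(dataset, "auc")
  swr <- if (design$replicated_reference)
    estimate_swr(dataset, design, "cmax")$swr else NA_real_
  rule <- ema_cmax_rule(swr, res_cmax$gmr, res_cmax$ci_lower,
                        res_cmax$ci_upper)
  rows <- rbind(
    guideline_row("EMA", "cmax", rule$method, swr, res_cmax$gmr,
                  res_cmax$ci_lower, res_cmax$ci_upper, rule$limits,
                  rule$pass),
    guideline_row("EMA", "auc", "unscaled", NA_real_, res_auc$gmr,
                  res_auc$ci_lower, res_auc$ci_upper, abe_limits(),
                  ci_within(res_auc$ci_lower, res_auc$ci_upper, abe_limits()))
  )
  new_be_decision("EMA", rows)
}
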