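#' Noncompartmental reduction of one concentration profile
#'
#' Computes the two bioequivalence endpoints from a sampled profile: Cmax is
#' the maximum observed concentration and AUC is the linear-trapezoid area
#' from 0 to the last sampling time (AUC0-t; no extrapolation to infinity).
#' Natural logs of both are attached.
#'
#' @param times Sampling times (h), starting at 0, strictly increasing,
#'   length >= 3.
#' @param conc Observed concentrations (pg/mL), same length as `times`.
#' @return A one-row data.frame with `cmax`, `auc`, `log_cmax`, `log_auc` and
#'   `valid` (FALSE when the profile has no positive concentration, in which
#'   case the endpoint values are `NA` and the row should be excluded
#'   upstream).
#' @examples
#' compute_outcomes(c(0, 1, 2), c(0, 10, 0))   # cmax 10, auc 10
#' @export
compute_outcomes <- function(times, conc) {
  if (length(times) < 3) stop_invalid("need at least 3 time points")
  if (length(conc) != length(times))
    stop_invalid("times and conc must have equal length")
  if (is.unsorted(times, strictly = TRUE))
    stop_invalid("times must be strictly increasing")
  cmax <- max(conc)
  if (!is.finite(cmax) || cmax <= 0)
    return(data.frame(cmax = NA_real_, auc = NA_real_, log_cmax = NA_real_,
                      log_auc = NA_real_, valid = FALSE))
  auc <- trapz(times, conc)
  data.frame(cmax = cmax, auc = auc,
             log_cmax = log(cmax), log_auc = log(auc), valid = TRUE)
}

#' Endpoint dataset of a simulated trial
#'
#' Applies the noncompartmental reduction to every administration record of a
#' simulated trial, yielding the long subject x period x treatment endpoint
#' table (the interchange format for the decision procedures and the post-hoc
#' analysis). Records whose profile never rises above zero are flagged
#' invalid and dropped with a warning.
#'
#' @param sim A [simulate_trial()] result.
#' @return data.frame with columns `subject`, `sequence`, `period`,
#'   `treatment`, `cmax`, `auc`, `log_cmax`, `log_auc`.
#' @export
trial_outcomes <- function(sim) {
  stopifnot(inherits(sim, "trial_sim"))
  cmax <- apply(sim$conc, 1, max)
  auc <- as.vector(sim$conc %*% trapz_weights(sim$times))
  out <- data.frame(
    subject = sim$params$subject,
    sequence = sim$params$sequence,
    period = sim$params$period,
    treatment = sim$params$treatment,
    cmax = cmax, auc = auc,
    log_cmax = log(cmax), log_auc = log(auc),
    stringsAsFactors = FALSE
  )
  bad <- !is.finite(out$log_cmax) | !is.finite(out$log_auc) | cmax <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with no positive concentration excluded")
    out <- out[!bad, , drop = FALSE]
  }
  out
}
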