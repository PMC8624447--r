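#' Simulate concentration-time profiles for one crossover trial
#'
#' Runs the per-replicate simulation pipeline up to the concentration stage:
#' subjects are assigned to sequences, individual and occasion-level PK
#' parameters are drawn, the closed-form two-compartment concentration is
#' evaluated on the sampling grid for every administration, and the residual
#' error model is applied (unless `include_error = FALSE`, the
#' error-exclusion sensitivity arm).
#'
#' @param model A [pk_model()].
#' @param design A [be_design()] or design name.
#' @param n_subjects Number of subjects enrolled.
#' @param seed Optional integer seed; the whole trial is reproducible from it.
#' @param include_error Apply the residual concentration error model?
#' @param times Sampling times in hours (must start at 0); see
#'   [default_times()].
#' @return Object of class `trial_sim`: list with `params` (the data.frame
#'   from [sample_subject_params()]), `times`, and `conc`, a matrix of
#'   observed concentrations with one row per administration record (aligned
#'   with `params`) and one column per sampling time.
#' @seealso [trial_outcomes()] to reduce to Cmax/AUC, [profiles_long()] for a
#'   tidy export.
#' @export
simulate_trial <- function(model, design, n_subjects, seed = NULL,
                           include_error = TRUE, times = default_times()) {
  if (is.character(design)) design <- be_design(design)
  stopifnot(inherits(model, "pk_model"))
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE))
    stop_invalid("times must start at 0 and be strictly increasing")
  with_rng_seed(seed, {
    params <- sample_subject_params(model, n_subjects, design)
    nt <- length(times)
    nr <- nrow(params)
    tt <- rep(times, each = nr)
    cc <- conc_2cpt(tt,
                    ka = params$ka, f = params$f, dose = model$dose_pg,
                    cl = params$cl, vc = params$vc, q = params$q,
                    vp = params$vp)
    conc <- matrix(cc, nrow = nr, ncol = nt)
    conc <- apply_residual_error(conc, model, include_error = include_error)
    colnames(conc) <- paste0("t", times)
    structure(list(params = params, times = times, conc = conc,
                   design = design, model = model),
              class = "trial_sim")
  })
}

#' @export
print.trial_sim <- function(x, ...) {
  cat(sprintf("Simulated %s trial: %d subjects, %d administration records, %d sampling times\n",
              x$design$name, length(unique(x$params$subject)), nrow(x$conc),
              length(x$times)))
  invisible(x)
}

#' Export simulated profiles as a long table
#'
#' @param sim A [simulate_trial()] result.
#' @return data.frame with columns `subject`, `sequence`, `period`,
#'   `treatment`, `time_h`, `conc_pg_ml`.
#' @export
profiles_long <- function(sim) {
  stopifnot(inherits(sim, "trial_sim"))
  nr <- nrow(sim$conc)
  nt <- length(sim$times)
  idx <- rep(seq_len(nr), times = nt)
  data.frame(
    subject = sim$params$subject[idx],
    sequence = sim$params$sequence[idx],
    period = sim$params$period[idx],
    treatment = sim$params$treatment[idx],
    time_h = rep(sim$times, each = nr),
    conc_pg_ml = as.vector(sim$conc),
    stringsAsFactors = FALSE
  )
}

#' Simulate a trial and reduce it to a BE endpoint dataset
#'
#' Convenience wrapper running simulate -> NCA -> dropout, producing the long
#' endpoint table consumed by the decision procedures.
#'
#' @inheritParams simulate_trial
#' @param dropout `NULL` for no dropout, or a [dropout_schedule()] matched to
#'   the design's periods.
#' @return A trial dataset: see [trial_outcomes()].
#' @export
simulate_trial_dataset <- function(model, design, n_subjects, seed = NULL,
                                   include_error = TRUE, dropout = NULL,
                                   times = default_times()) {
  if (is.character(design)) design <- be_design(design)
  with_rng_seed(seed, {
    sim <- simulate_trial(model, design, n_subjects,
                          include_error = include_error, times = times)
    dataset <- trial_outcomes(sim)
    if (!is.null(dropout)) dataset <- apply_dropout(dataset, dropout)
    dataset
  })
}
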