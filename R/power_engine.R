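#' Monte-Carlo power scenario
#'
#' Bundles everything one power study needs: the population PK model, the
#' crossover design, the subject-number grid, the true-GMR grid (typical test
#' bioavailability values against a reference of 1), the grid of
#' occasion-level bioavailability SDs (the within-subject variability
#' conditions), the replicate count, the dropout schedule, the residual-error
#' switch, the guideline set and the master seed. Per-replicate seeds are
#' derived deterministically from the master seed, so any single replicate
#' can be reproduced in isolation and a parallel run would equal the
#' sequential one.
#'
#' @param model A [pk_model()] serving as the template; its `tv_f_test` and
#'   `wsv["f"]` are overridden cell-by-cell from the grids.
#' @param design Design name or [be_design()].
#' @param n_grid Integer vector of subject numbers (kept as multiples of the
#'   sequence count so balance holds).
#' @param gmr_grid True GMR values (test bioavailability, reference = 1).
#' @param wsv_f_grid Occasion-level SDs of log F; `NULL` keeps the model's.
#' @param n_replicates Simulated trials per grid cell (1000 emulates a full
#'   study; tests use 200-300).
#' @param seed Master seed.
#' @param include_error Apply residual concentration error?
#' @param dropout `NULL`, `TRUE` (default period-dependent schedule) or a
#'   [dropout_schedule()].
#' @param guidelines Subset of `c("EMA", "FDA")`.
#' @param times Sampling schedule.
#' @return Object of class `be_scenario`.
#' @export
be_scenario <- function(model = pk_model(), design = "2x4",
                        n_grid = c(12, 24, 36, 48),
                        gmr_grid = c(0.9, 1.0, 1.1),
                        wsv_f_grid = NULL,
                        n_replicates = 1000, seed = 1,
                        include_error = TRUE, dropout = NULL,
                        guidelines = c("EMA", "FDA"),
                        times = default_times()) {
  if (is.character(design)) design <- be_design(design)
  stopifnot(inherits(model, "pk_model"), inherits(design, "be_design"))
  if (!length(n_grid) || !length(gmr_grid))
    stop_invalid("n_grid and gmr_grid must be non-empty")
  if (n_replicates < 1) stop_invalid("n_replicates must be >= 1")
  guidelines <- match.arg(guidelines, several.ok = TRUE)
  if (isTRUE(dropout)) dropout <- dropout_schedule(design$n_periods)
  if (!is.null(dropout) && !isFALSE(dropout) &&
      length(dropout) != design$n_periods)
    stop_invalid("dropout schedule does not match the design's periods")
  if (isFALSE(dropout)) dropout <- NULL
  wsv_f_grid <- wsv_f_grid %||% model$wsv[["f"]]
  structure(list(model = model, design = design, n_grid = sort(n_grid),
                 gmr_grid = gmr_grid, wsv_f_grid = wsv_f_grid,
                 n_replicates = n_replicates, seed = seed,
                 include_error = include_error, dropout = dropout,
                 guidelines = guidelines, times = times),
            class = "be_scenario")
}

#' @export
print.be_scenario <- function(x, ...) {
  cat(sprintf("BE power scenario: %s design, n = {%s}, GMR = {%s}, wsv_F = {%s}\n",
              x$design$name, paste(x$n_grid, collapse = ","),
              paste(x$gmr_grid, collapse = ","),
              paste(signif(x$wsv_f_grid, 3), collapse = ",")))
  cat(sprintf("  %d replicates/cell, seed %d, residual error %s, dropout %s, guidelines %s\n",
              x$n_replicates, x$seed,
              if (x$include_error) "on" else "off",
              if (is.null(x$dropout)) "none"
              else paste(signif(unclass(x$dropout), 3), collapse = "/"),
              paste(x$guidelines, collapse = "+")))
  invisible(x)
}

# model template with cell-specific GMR and within-subject F variability
cell_model <- function(model, gmr, wsv_f) {
  model$tv_f_test <- gmr * model$tv_f_ref
  model$wsv[["f"]] <- wsv_f
  model
}

#' Run one Monte-Carlo trial replicate and decide bioequivalence
#'
#' Simulates a complete trial (parameters, profiles, residual error, NCA,
#' dropout) and evaluates it under the requested guidelines. Decision-stage
#' errors (insufficient degrees of freedom, inestimable contrasts after
#' dropout, degenerate fits) are caught and recorded as bioequivalence
#' failures with a reason code - an unanalyzable trial is a failed trial,
#' never an aborted batch.
#'
#' @param model A [pk_model()] (already carrying the cell's GMR and wsv).
#' @param design A [be_design()].
#' @param n_subjects Subjects enrolled.
#' @param seed Replicate seed (deterministic decisions given the seed).
#' @param include_error,dropout,times As in [be_scenario()].
#' @param guidelines Subset of `c("EMA", "FDA")`.
#' @return Named list per guideline: `list(pass, reason, decision)` where
#'   `decision` is the `be_decision` (or `NULL` on a recorded failure).
#' @export
run_replicate <- function(model, design, n_subjects, seed = NULL,
                          include_error = TRUE, dropout = NULL,
                          guidelines = c("EMA", "FDA"),
                          times = default_times()) {
  guidelines <- match.arg(guidelines, several.ok = TRUE)
  dataset <- simulate_trial_dataset(model, design, n_subjects, seed = seed,
                                    include_error = include_error,
                                    dropout = dropout, times = times)
  out <- list()
  for (g in guidelines) {
    out[[g]] <- tryCatch({
      dec <- if (g == "EMA") ema_decision(dataset, design)
             else fda_decision(dataset, design)
      list(pass = dec$pass, reason = NA_character_, decision = dec)
    }, error = function(e) {
      list(pass = FALSE, reason = conditionMessage(e), decision = NULL)
    })
  }
  out
}

#' Estimate the power surface of a scenario
#'
#' For every (wsv_F, GMR, n) grid cell, runs `n_replicates` independent trial
#' simulations and estimates power as the fraction passing bioequivalence
#' under each guideline, with an exact (Clopper-Pearson) 95% Monte-Carlo
#' confidence interval. The abscissa for design comparison is the total
#' number of observations `N = n_subjects * n_periods`.
#'
#' @param scenario A [be_scenario()].
#' @param progress Print a line per grid cell?
#' @return A `power_curve` data.frame: one row per design x guideline x
#'   wsv_F x GMR x n cell with columns `design`, `guideline`, `gmr`,
#'   `wsv_f`, `cv_wr` (the within-subject CV implied by `wsv_f`),
#'   `n_subjects`, `N`, `power`, `mc_lower`, `mc_upper`, `n_pass`,
#'   `n_replicates`, `n_error` (replicates failed for analysis reasons).
#' @export
estimate_power <- function(scenario, progress = FALSE) {
  stopifnot(inherits(scenario, "be_scenario"))
  grid <- expand.grid(wsv_f = scenario$wsv_f_grid, gmr = scenario$gmr_grid,
                      n_subjects = scenario$n_grid,
                      KEEP.OUT.ATTRS = FALSE)
  R <- scenario$n_replicates
  seeds <- matrix(derive_seeds(scenario$seed, nrow(grid) * R),
                  nrow = nrow(grid))
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    m <- cell_model(scenario$model, grid$gmr[i], grid$wsv_f[i])
    pass <- matrix(NA, R, length(scenario$guidelines),
                   dimnames = list(NULL, scenario$guidelines))
    err <- stats::setNames(integer(length(scenario$guidelines)),
                           scenario$guidelines)
    for (r in seq_len(R)) {
      rep_out <- run_replicate(m, scenario$design, grid$n_subjects[i],
                               seed = seeds[i, r],
                               include_error = scenario$include_error,
                               dropout = scenario$dropout,
                               guidelines = scenario$guidelines,
                               times = scenario$times)
      for (g in scenario$guidelines) {
        pass[r, g] <- rep_out[[g]]$pass
        if (!is.na(rep_out[[g]]$reason)) err[g] <- err[g] + 1L
      }
    }
    for (g in scenario$guidelines) {
      k <- sum(pass[, g])
      ci <- stats::binom.test(k, R)$conf.int
      rows[[length(rows) + 1L]] <- data.frame(
        design = scenario$design$name, guideline = g,
        gmr = grid$gmr[i], wsv_f = grid$wsv_f[i],
        cv_wr = sigma2cv(grid$wsv_f[i]),
        n_subjects = grid$n_subjects[i],
        N = grid$n_subjects[i] * scenario$design$n_periods,
        power = k / R, mc_lower = ci[1], mc_upper = ci[2],
        n_pass = k, n_replicates = R, n_error = err[[g]],
        stringsAsFactors = FALSE)
    }
    if (progress)
      cat(sprintf("cell %d/%d done (n=%d, gmr=%.2f, wsv=%.3f)\n",
                  i, nrow(grid), grid$n_subjects[i], grid$gmr[i],
                  grid$wsv_f[i]))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("power_curve", "data.frame")
  out
}

#' Validation scenario tracking the LMM-based literature conditions
#'
#' Returns a scenario built on [validation_pk_model()]: test and reference PK
#' identical within subject (test-reference correlations 1), within-subject
#' variability confined to bioavailability (Ka occasion SD 0, F occasion SD
#' 0.294 so the within-reference CV is exactly 0.30) and no residual
#' concentration error. Under these conditions the simulated power curves
#' track published LMM-based sample-size results for highly variable drugs.
#'
#' @param design Design name or [be_design()].
#' @param n_grid,gmr_grid,n_replicates,seed Passed to [be_scenario()].
#' @param wsv_f Occasion-level SD of log F (0.294, CV 30%).
#' @param ... Further arguments to [be_scenario()].
#' @return A `be_scenario`.
#' @export
validation_preset <- function(design = "2x4", n_grid = c(12, 24, 36, 48),
                              gmr_grid = c(0.9, 1.0, 1.1),
                              n_replicates = 1000, seed = 1,
                              wsv_f = 0.294, ...) {
  be_scenario(model = validation_pk_model(wsv_f = wsv_f),
              design = design, n_grid = n_grid, gmr_grid = gmr_grid,
              wsv_f_grid = wsv_f, n_replicates = n_replicates, seed = seed,
              include_error = FALSE, ...)
}
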