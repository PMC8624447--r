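#' Subsample a three-period replicate dataset into a virtual 2x2 trial
#'
#' From a dataset in which every subject has one test and two reference
#' administrations, keeps the test record and one uniformly chosen reference
#' record per subject. The synthesized two-period trial is relabelled so the
#' fixed-effects model has a coherent design matrix: the sequence is derived
#' from the chronological order of the two retained records ("TR" or "RT")
#' and the period covariate is re-indexed 1..2. Optionally a random subject
#' subsample is taken first (for matching a smaller total-observation
#' target). Subjects lacking the required records are excluded with a
#' warning.
#'
#' @param dataset Trial dataset from a 3-period replicate study.
#' @param n_subjects Optional number of subjects to retain (sampled without
#'   replacement) before the period subsampling; `NULL` keeps all.
#' @param seed Optional integer seed.
#' @return A trial dataset labelled as a 2x2 design.
#' @export
subsample_2x2 <- function(dataset, n_subjects = NULL, seed = NULL) {
  with_rng_seed(seed, {
    ids <- unique(dataset$subject)
    if (!is.null(n_subjects)) {
      if (n_subjects > length(ids))
        stop_invalid("n_subjects exceeds the available ", length(ids),
                     " subjects")
      ids <- sample(ids, n_subjects)
    }
    rows <- list()
    dropped <- 0L
    for (id in ids) {
      d <- dataset[dataset$subject == id, , drop = FALSE]
      d <- d[order(d$period), , drop = FALSE]
      t_rows <- which(d$treatment == "T")
      r_rows <- which(d$treatment == "R")
      if (length(t_rows) != 1 || length(r_rows) != 2) {
        dropped <- dropped + 1L
        next
      }
      keep <- d[c(t_rows, sample(r_rows, 1)), , drop = FALSE]
      keep <- keep[order(keep$period), , drop = FALSE]
      keep$sequence <- paste(keep$treatment, collapse = "")
      keep$period <- seq_len(2)
      rows[[length(rows) + 1L]] <- keep
    }
    if (dropped > 0)
      warning(dropped, " subject(s) without a complete T + 2R record set ",
              "excluded from the 2x2 subsample")
    do.call(rbind, rows)
  })
}

#' Subsample subjects of a three-period dataset to a target observation count
#'
#' Retains `round(target_N / 3)` uniformly sampled subjects with all three
#' periods, so the reduced trial has approximately the requested total
#' number of observations N.
#'
#' @param dataset Trial dataset from a 3-period study.
#' @param target_N Target total number of observations.
#' @param seed Optional integer seed.
#' @return The reduced trial dataset.
#' @export
subsample_3x3 <- function(dataset, target_N, seed = NULL) {
  ids <- unique(dataset$subject)
  n_keep <- round(target_N / 3)
  if (n_keep < 1 || n_keep > length(ids))
    stop_invalid("target_N = ", target_N, " is infeasible for ",
                 length(ids), " subjects")
  with_rng_seed(seed, {
    keep <- sample(ids, n_keep)
    dataset[dataset$subject %in% keep, , drop = FALSE]
  })
}

#' Post-hoc subsampling power analysis of an observed replicate dataset
#'
#' Repeatedly draws virtual trials from an existing three-period replicate
#' dataset - 2x2 trials by sampling one of the two reference periods per
#' subject, or reduced 3x3 trials by sampling subjects to a target N - and
#' reports the fraction of subsamples passing bioequivalence under each
#' guideline (the post-hoc power), together with the mean estimated
#' within-subject CV and GMR per endpoint across iterations. For 2x2
#' subsamples the reported CV is the within-total CV (from the residual SD
#' of the fixed-effects model, which pools both products); for 3x3
#' subsamples it is the within-reference CV (from the guideline's own SWR
#' estimate).
#'
#' @param dataset Trial dataset from a 3-period replicate study (every
#'   subject one test, two reference records).
#' @param design `"2x2"` or `"3x3"`: the virtual design to subsample.
#' @param n_subjects For `design = "2x2"`: optional subject subsample size.
#' @param target_N For `design = "3x3"`: target total observations; `NULL`
#'   keeps all subjects.
#' @param iterations Number of subsamples (1000 emulates a full analysis).
#' @param seed Master seed; iteration seeds are derived from it.
#' @param guidelines Subset of `c("EMA", "FDA")`.
#' @return Object of class `posthoc_power`: list with `power` (named vector
#'   per guideline), `summary` (data.frame of mean within-CV % and mean
#'   GMR % per guideline x endpoint), `n_subjects`, `N`, `iterations`.
#' @export
posthoc_power <- function(dataset, design = c("2x2", "3x3"),
                          n_subjects = NULL, target_N = NULL,
                          iterations = 1000, seed = 1,
                          guidelines = c("EMA", "FDA")) {
  design <- match.arg(design)
  guidelines <- match.arg(guidelines, several.ok = TRUE)
  seeds <- derive_seeds(seed, iterations)
  des <- be_design(design)
  pass <- matrix(FALSE, iterations, length(guidelines),
                 dimnames = list(NULL, guidelines))
  cv_acc <- gmr_acc <- array(
    NA_real_, dim = c(iterations, length(guidelines), 2),
    dimnames = list(NULL, guidelines, c("cmax", "auc")))
  n_used <- NA_integer_
  for (it in seq_len(iterations)) {
    sub <- if (design == "2x2")
      subsample_2x2(dataset, n_subjects = n_subjects, seed = seeds[it])
    else if (is.null(target_N)) dataset
    else subsample_3x3(dataset, target_N, seed = seeds[it])
    n_used <- length(unique(sub$subject))
    for (g in guidelines) {
      res <- tryCatch(
        if (g == "EMA") ema_decision(sub, des) else fda_decision(sub, des),
        error = function(e) NULL)
      if (is.null(res)) next
      pass[it, g] <- res$pass
      for (ep in c("cmax", "auc")) {
        row <- res$table[res$table$endpoint == ep, ]
        gmr_acc[it, g, ep] <- row$gmr
        cv_acc[it, g, ep] <- if (design == "3x3") {
          swr <- if (g == "EMA")
            estimate_swr(ema_filter(sub), des, ep)$swr
          else row$swr
          100 * sigma2cv(swr)
        } else {
          100 * sigma2cv(glm_gmr_ci(sub, ep)$sigma_w)
        }
      }
    }
  }
  summary_df <- do.call(rbind, lapply(guidelines, function(g) {
    do.call(rbind, lapply(c("cmax", "auc"), function(ep) {
      data.frame(guideline = g, endpoint = ep,
                 mean_within_cv = mean(cv_acc[, g, ep], na.rm = TRUE),
                 cv_kind = if (design == "2x2") "within-total"
                           else "within-reference",
                 mean_gmr = mean(gmr_acc[, g, ep], na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(
    design = design,
    power = colMeans(pass),
    summary = summary_df,
    n_subjects = n_used,
    N = n_used * des$n_periods,
    iterations = iterations
  ), class = "posthoc_power")
}

#' @export
print.posthoc_power <- function(x, ...) {
  cat(sprintf("Post-hoc subsampling power (%s design, n = %d, N = %d, %d iterations)\n",
              x$design, x$n_subjects, x$N, x$iterations))
  for (g in names(x$power))
    cat(sprintf("  %s: power %.1f%%\n", g, 100 * x$power[[g]]))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
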