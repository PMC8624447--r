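#' Crossover design layouts for bioequivalence trials
#'
#' Builds the treatment-by-period layout of the three supported crossover
#' designs: the conventional two-period design ("2x2", sequences TR/RT), the
#' three-period partial replicate in which the reference is given twice
#' ("3x3", sequences RRT/RTR/TRR) and the four-period full replicate
#' ("2x4", sequences TRTR/RTRT). The replicate designs administer the
#' reference at least twice per subject, which is what makes the
#' within-reference SD (SWR) estimable and reference-scaling available; the
#' 2x2 design supports only the unscaled analysis.
#'
#' @param name One of `"2x2"`, `"3x3"`, `"2x4"`.
#' @return An object of class `be_design` with elements `name`, `sequences`
#'   (character vector of treatment strings), `n_periods`,
#'   `replicated_reference` (reference given at least twice in every
#'   sequence) and `full_replicate` (both products given twice).
#' @examples
#' be_design("3x3")
#' @export
be_design <- function(name = c("2x2", "3x3", "2x4")) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% c("2x2", "3x3", "2x4"))
    stop_invalid("unknown design '", paste(name, collapse = ","),
                 "'; valid designs are: 2x2, 3x3, 2x4")
  sequences <- switch(name,
    "2x2" = c("TR", "RT"),
    "3x3" = c("RRT", "RTR", "TRR"),
    "2x4" = c("TRTR", "RTRT"))
  new_be_design(name, sequences)
}

# construct a design from explicit sequences (also used for synthesized
# post-hoc 2x2 subsamples)
new_be_design <- function(name, sequences) {
  n_periods <- unique(nchar(sequences))
  if (length(n_periods) != 1)
    stop_invalid("all sequences must span the same number of periods")
  letters_ok <- all(strsplit(paste(sequences, collapse = ""), "")[[1]] %in%
                      c("T", "R"))
  if (!letters_ok) stop_invalid("sequences may contain only 'T' and 'R'")
  r_counts <- vapply(strsplit(sequences, ""), function(s) sum(s == "R"), 1L)
  t_counts <- vapply(strsplit(sequences, ""), function(s) sum(s == "T"), 1L)
  structure(list(
    name = name,
    sequences = sequences,
    n_periods = n_periods,
    replicated_reference = all(r_counts >= 2),
    full_replicate = all(r_counts >= 2) && all(t_counts >= 2)
  ), class = "be_design")
}

#' @export
print.be_design <- function(x, ...) {
  cat(sprintf("%s crossover design: sequences %s (%d periods)%s\n",
              x$name, paste(x$sequences, collapse = "/"), x$n_periods,
              if (x$full_replicate) ", full replicate"
              else if (x$replicated_reference) ", replicated reference"
              else ""))
  invisible(x)
}

#' Balanced random assignment of subjects to sequences
#'
#' Block-balanced randomisation: sequence counts differ by at most one, with
#' the surplus subjects (when `n_subjects` is not a multiple of the number of
#' sequences) allocated to randomly chosen sequences.
#'
#' @param n_subjects Number of subjects (at least the number of sequences).
#' @param design A [be_design()].
#' @param seed Optional integer seed.
#' @return Character vector of length `n_subjects` with the sequence label of
#'   each subject, in randomised order.
#' @export
assign_sequences <- function(n_subjects, design, seed = NULL) {
  stopifnot(inherits(design, "be_design"))
  k <- length(design$sequences)
  if (n_subjects < k)
    stop_invalid("need at least ", k, " subjects for the ", design$name,
                 " design")
  with_rng_seed(seed, {
    base <- rep(design$sequences, n_subjects %/% k)
    extra <- sample(design$sequences, n_subjects %% k)
    sample(c(base, extra))
  })
}

#' Period-dependent dropout schedule
#'
#' Cumulative probabilities, by period, that a subject has withdrawn before
#' that period. The default emulates dropout growing with study duration:
#' 3% by the second period, 4% by the third and 6% by the fourth, truncated
#' to the design's period count (so nothing is lost in period 1).
#'
#' @param n_periods Number of periods of the target design (2, 3 or 4).
#' @param rates Dropout rates for periods 2..4.
#' @param cumulative Are `rates` cumulative probabilities of having withdrawn
#'   by each period (default), or per-period increments to be accumulated?
#' @return Object of class `dropout_schedule`: numeric vector of length
#'   `n_periods`, non-decreasing, in [0, 1).
#' @export
dropout_schedule <- function(n_periods, rates = c(0.03, 0.04, 0.06),
                             cumulative = TRUE) {
  stopifnot(n_periods >= 1)
  if (!cumulative) rates <- cumsum(rates)
  sched <- c(0, rates)[seq_len(n_periods)]
  if (any(sched < 0) || any(sched >= 1) || is.unsorted(sched))
    stop_invalid("dropout schedule must be non-decreasing and in [0, 1)")
  structure(sched, class = "dropout_schedule")
}

#' Apply monotone completely-at-random dropout to a trial dataset
#'
#' Each subject is independently assigned a (possibly never-reached) dropout
#' period from the cumulative schedule; all of that subject's records from
#' that period onward are removed and earlier periods are retained, giving a
#' monotone missing-completely-at-random pattern. The marginal probability
#' that a subject is missing period p equals `schedule[p]`.
#'
#' @param dataset A trial dataset (long data.frame with `subject` and
#'   `period` columns, e.g. from [trial_outcomes()]).
#' @param schedule A [dropout_schedule()] with one entry per period.
#' @param seed Optional integer seed.
#' @return The dataset with dropped records removed.
#' @export
apply_dropout <- function(dataset, schedule, seed = NULL) {
  stopifnot(all(c("subject", "period") %in% names(dataset)))
  n_periods <- max(dataset$period)
  if (length(schedule) != n_periods)
    stop_invalid("dropout schedule length (", length(schedule),
                 ") must equal the number of periods (", n_periods, ")")
  subjects <- unique(dataset$subject)
  with_rng_seed(seed, {
    u <- stats::runif(length(subjects))
    # earliest period by which the subject has withdrawn; Inf = completer
    drop_period <- vapply(u, function(ui) {
      hit <- which(ui < schedule)
      if (length(hit)) min(hit) else Inf
    }, numeric(1))
    keep <- dataset$period < drop_period[match(dataset$subject, subjects)]
    dataset[keep, , drop = FALSE]
  })
}
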