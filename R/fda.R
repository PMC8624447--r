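#' Per-subject FDA response variables (ilat and dlat)
#'
#' Builds the two log-scale contrast series the FDA reference-scaled analysis
#' works with: for each subject, `ilat` is the mean of the log test values
#' minus the mean of the log reference values, and `dlat` is the difference
#' between the first and second reference administration (chronological
#' order within subject). A subject contributes no value for a contrast when
#' a needed record is missing: `ilat` requires at least one test and one
#' reference record, `dlat` requires both reference administrations.
#'
#' @param dataset Trial dataset.
#' @param design A [be_design()] with replicated reference.
#' @param endpoint `"cmax"` or `"auc"`.
#' @return List with data.frames `ilat` (`subject`, `sequence`, `ilat`) and
#'   `dlat` (`subject`, `sequence`, `dlat`).
#' @export
fda_contrasts <- function(dataset, design, endpoint = c("cmax", "auc")) {
  stopifnot(inherits(design, "be_design"))
  if (!design$replicated_reference)
    stop_invalid("the FDA scaled contrasts require a replicated-reference ",
                 "design; the ", design$name, " design is not")
  endpoint <- match.arg(endpoint)
  dataset <- dataset[order(dataset$subject, dataset$period), , drop = FALSE]
  logy <- log_endpoint(dataset, endpoint)
  sp <- split(seq_len(nrow(dataset)), dataset$subject)
  ilat <- dlat <- list()
  for (ids in sp) {
    trt <- dataset$treatment[ids]
    y <- logy[ids]
    subj <- dataset$subject[ids[1]]
    sq <- dataset$sequence[ids[1]]
    if (any(trt == "T") && any(trt == "R"))
      ilat[[length(ilat) + 1L]] <-
        data.frame(subject = subj, sequence = sq,
                   ilat = mean(y[trt == "T"]) - mean(y[trt == "R"]))
    if (sum(trt == "R") >= 2) {
      r <- y[trt == "R"]
      dlat[[length(dlat) + 1L]] <-
        data.frame(subject = subj, sequence = sq, dlat = r[1] - r[2])
    }
  }
  list(ilat = do.call(rbind, ilat) %||%
         data.frame(subject = integer(), sequence = character(),
                    ilat = numeric()),
       dlat = do.call(rbind, dlat) %||%
         data.frame(subject = integer(), sequence = character(),
                    dlat = numeric()))
}

# sequence-adjusted summary of a per-subject contrast series: unweighted mean
# of per-sequence means, its standard error from the sequence-stratified
# residual variance, and the residual df
contrast_stats <- function(values, sequence) {
  sequence <- factor(sequence)
  sequence <- droplevels(sequence)
  n_s <- tabulate(sequence)
  S <- nlevels(sequence)
  n <- length(values)
  df <- n - S
  if (df < 1 || any(n_s < 1))
    stop_invalid("insufficient degrees of freedom for the scaled analysis")
  means <- tapply(values, sequence, mean)
  mbar <- mean(means)
  ss <- sum((values - means[sequence])^2)
  s2 <- ss / df
  se <- sqrt(s2 * sum(1 / n_s) / S^2)
  list(mean = mbar, se = se, s2 = s2, df = df, n = n)
}

#' Upper 95% confidence bound for the FDA scaled-ABE criterion
#'
#' The FDA criterion is `(muT - muR)^2 - theta * sigmaWR^2 <= 0` with
#' `theta = (log(1.25) / sigmaW0)^2` and `sigmaW0 = 0.25`. Its one-sided 95%
#' upper confidence bound is computed by the Howe-type combination: with
#' point estimates `x = dbar^2` and `y = -theta * s2wr`,
#' `boundx = (|dbar| + t(0.95, df_i) * se)^2`,
#' `boundy = y * df_d / chisq(0.95, df_d)`, and
#' `upper = x + y + sqrt((boundx - x)^2 + (boundy - y)^2)`.
#' The scaled test passes when `upper <= 0` (together with the 80-125% GMR
#' point-estimate constraint, applied by [fda_decision()]).
#'
#' @param dbar Sequence-adjusted mean of the per-subject test-reference
#'   contrasts (`ilat`), i.e. the estimate of `muT - muR`.
#' @param se Standard error of `dbar`.
#' @param df_i Degrees of freedom for `dbar` (contrast count minus number of
#'   sequences).
#' @param s2wr Estimated within-reference variance, `var(dlat | sequence)/2`.
#' @param df_d Degrees of freedom of `s2wr`.
#' @return List with `upper` (the bound), `x`, `y`, `boundx`, `boundy` and
#'   `theta`.
#' @export
fda_rsabe_upper_bound <- function(dbar, se, df_i, s2wr, df_d) {
  if (df_i < 1 || df_d < 1)
    stop_invalid("insufficient degrees of freedom for the RSABE bound")
  theta <- (log(1.25) / 0.25)^2
  x <- dbar^2
  boundx <- (abs(dbar) + stats::qt(0.95, df_i) * se)^2
  y <- -theta * s2wr
  boundy <- y * df_d / stats::qchisq(0.95, df_d)
  upper <- x + y + sqrt((boundx - x)^2 + (boundy - y)^2)
  list(upper = upper, x = x, y = y, boundx = boundx, boundy = boundy,
       theta = theta)
}

# FDA analysis of one endpoint; returns a guideline_row
fda_endpoint <- function(dataset, design, endpoint) {
  if (design$replicated_reference) {
    con <- fda_contrasts(dataset, design, endpoint)
    ist <- contrast_stats(con$ilat$ilat, con$ilat$sequence)
    dst <- contrast_stats(con$dlat$dlat, con$dlat$sequence)
    s2wr <- dst$s2 / 2
    swr <- sqrt(s2wr)
    if (swr >= 0.294) {
      bnd <- fda_rsabe_upper_bound(ist$mean, ist$se, ist$df, s2wr, dst$df)
      gmr <- 100 * exp(ist$mean)
      pass <- bnd$upper <= 0 && gmr >= 80 && gmr <= 125
      return(guideline_row("FDA", endpoint, "scaled", swr, gmr,
                           NA_real_, NA_real_,
                           c(lower = NA_real_, upper = NA_real_), pass,
                           note = sprintf("rsabe_upper=%.6g", bnd$upper)))
    }
    # unscaled branch: mixed model for the full replicate, GLM otherwise
    res <- if (design$full_replicate) mixed_gmr_ci(dataset, endpoint)
           else glm_gmr_ci(dataset, endpoint)
    method <- if (design$full_replicate) {
      if (isTRUE(res$fallback)) "unscaled-glm-fallback" else "unscaled-mixed"
    } else "unscaled"
    return(guideline_row("FDA", endpoint, method, swr, res$gmr,
                         res$ci_lower, res$ci_upper, abe_limits(),
                         ci_within(res$ci_lower, res$ci_upper, abe_limits())))
  }
  res <- glm_gmr_ci(dataset, endpoint)
  guideline_row("FDA", endpoint, "unscaled", NA_real_, res$gmr,
                res$ci_lower, res$ci_upper, abe_limits(),
                ci_within(res$ci_lower, res$ci_upper, abe_limits()))
}

#' Bioequivalence decision under the FDA mixed-scaling procedure
#'
#' Implements the FDA "mixed scaling" approach for each endpoint (Cmax and
#' AUC, each with its own within-reference SD): in replicate designs the
#' within-reference variance is estimated from the sequence-adjusted
#' reference-reference contrasts (`s2wr = var(dlat)/2`); when
#' `swr >= 0.294` the reference-scaled criterion applies (Howe-type 95%
#' upper bound <= 0 plus the 80-125% GMR constraint), and below 0.294 the
#' unscaled TOST applies - via the five-variance-term mixed model for the
#' full-replicate 2x4 design and the fixed-effects model for the 3x3. The
#' 2x2 design is always analysed by the unscaled fixed-effects TOST. Overall
#' bioequivalence requires both endpoints to pass.
#'
#' @param dataset Trial dataset.
#' @param design A [be_design()].
#' @return A `be_decision` object.
#' @export
fda_decision <- function(dataset, design) {
  stopifnot(inherits(design, "be_design"))
  rows <- rbind(fda_endpoint(dataset, design, "cmax"),
                fda_endpoint(dataset, design, "auc"))
  new_be_decision("FDA", rows)
}
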