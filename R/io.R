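#' Load a simulation scenario from a YAML or JSON config file
#'
#' Reads a structured config whose keys mirror the [pk_model()] and
#' [be_scenario()] fields. Unknown keys, out-of-range values and malformed
#' blocks are collected and reported together in a single error. Missing
#' keys fall back to the package defaults (the clopidogrel-like parameter
#' set, 2x4 design, 1000 replicates).
#'
#' Recognised top-level keys: `model` (a mapping of [pk_model()] arguments),
#' `design`, `n_grid`, `gmr_grid`, `wsv_f_grid`, `n_replicates`, `seed`,
#' `include_error`, `dropout` (false, true or a list of cumulative rates),
#' `guidelines`, `times`.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A validated [be_scenario()].
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()

  known <- c("model", "design", "n_grid", "gmr_grid", "wsv_f_grid",
             "n_replicates", "seed", "include_error", "dropout",
             "guidelines", "times")
  problems <- character()
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    problems <- c(problems, paste0("unknown key(s): ",
                                   paste(unknown, collapse = ", ")))
  model_args <- cfg$model %||% list()
  if (!is.null(model_args$corr_disposition))
    model_args$corr_disposition <-
      matrix(unlist(model_args$corr_disposition), 4, 4, byrow = TRUE)
  if (!is.null(model_args$bsv)) model_args$bsv <- unlist(model_args$bsv)
  if (!is.null(model_args$wsv)) model_args$wsv <- unlist(model_args$wsv)
  model <- tryCatch(do.call(pk_model, model_args),
                    error = function(e)
                      { problems <<- c(problems,
                                       paste0("model: ",
                                              conditionMessage(e))); NULL })
  design <- tryCatch(be_design(cfg$design %||% "2x4"),
                     error = function(e)
                       { problems <<- c(problems, conditionMessage(e)); NULL })
  dropout <- cfg$dropout %||% NULL
  if (is.list(dropout) || (is.numeric(dropout) && length(dropout) > 1))
    dropout <- tryCatch(
      structure(unlist(dropout), class = "dropout_schedule"),
      error = function(e)
        { problems <<- c(problems, conditionMessage(e)); NULL })
  if (length(problems))
    stop_invalid("invalid scenario config:\n  - ",
                 paste(problems, collapse = "\n  - "))
  be_scenario(model = model, design = design,
              n_grid = cfg$n_grid %||% c(12, 24, 36, 48),
              gmr_grid = cfg$gmr_grid %||% c(0.9, 1.0, 1.1),
              wsv_f_grid = cfg$wsv_f_grid,
              n_replicates = cfg$n_replicates %||% 1000,
              seed = cfg$seed %||% 1,
              include_error = cfg$include_error %||% TRUE,
              dropout = dropout,
              guidelines = unlist(cfg$guidelines) %||% c("EMA", "FDA"),
              times = unlist(cfg$times) %||% default_times())
}

#' Save a scenario back to YAML
#'
#' Writes a canonical YAML representation that [load_scenario()] reads back
#' into an identical scenario (round-trip stable).
#'
#' @param scenario A [be_scenario()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "be_scenario"))
  m <- scenario$model
  cfg <- list(
    model = list(
      tv_cl = m$tv_cl, tv_vc = m$tv_vc, tv_q = m$tv_q, tv_vp = m$tv_vp,
      tv_ka_test = m$tv_ka_test, tv_ka_ref = m$tv_ka_ref,
      tv_f_test = m$tv_f_test, tv_f_ref = m$tv_f_ref,
      bsv = as.list(m$bsv), wsv = as.list(m$wsv),
      corr_f_tr = m$corr_f_tr, corr_ka_tr = m$corr_ka_tr,
      corr_disposition = apply(m$corr_disposition, 1, as.list,
                               simplify = FALSE),
      error_additive = m$error_additive,
      error_proportional = m$error_proportional,
      dose_mg = m$dose_mg),
    design = scenario$design$name,
    n_grid = scenario$n_grid,
    gmr_grid = scenario$gmr_grid,
    wsv_f_grid = scenario$wsv_f_grid,
    n_replicates = scenario$n_replicates,
    seed = scenario$seed,
    include_error = scenario$include_error,
    dropout = if (is.null(scenario$dropout)) FALSE
              else as.numeric(scenario$dropout),
    guidelines = scenario$guidelines,
    times = scenario$times)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write power-curve or decision results as tidy CSV (plus plots)
#'
#' Writes a `power_curve` to `power_curve.csv` in `dir` with a stable column
#' order, and optionally one power-versus-N plot file per guideline. The
#' plots regenerate from the CSV alone.
#'
#' @param curve A `power_curve` from [estimate_power()] (or any data.frame).
#' @param dir Output directory (created if absent).
#' @param plots Also write `power_<guideline>.png` files?
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(curve, dir, plots = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, "power_curve.csv")
  utils::write.csv(as.data.frame(curve), csv, row.names = FALSE)
  files <- csv
  if (plots && nrow(curve)) {
    for (g in unique(curve$guideline)) {
      f <- file.path(dir, paste0("power_", g, ".png"))
      grDevices::png(f, width = 900, height = 600)
      print(plot_power_curve(curve[curve$guideline == g, , drop = FALSE]))
      grDevices::dev.off()
      files <- c(files, f)
    }
  }
  invisible(files)
}

#' Read a trial dataset from a long CSV
#'
#' The interchange format: columns `subject`, `sequence`, `period`,
#' `treatment` and at least one of `cmax`/`auc` (log columns are recomputed
#' if absent). This is also the entry point for real replicate-design data
#' fed to the post-hoc analysis.
#'
#' @param path CSV path.
#' @return A trial dataset data.frame.
#' @export
read_trial_dataset <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "sequence", "period", "treatment")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop_invalid("dataset is missing column(s): ",
                 paste(missing_cols, collapse = ", "))
  if (!any(c("cmax", "auc") %in% names(d)))
    stop_invalid("dataset must contain a 'cmax' and/or 'auc' column")
  for (ep in intersect(c("cmax", "auc"), names(d))) {
    lg <- paste0("log_", ep)
    if (!lg %in% names(d)) d[[lg]] <- log(d[[ep]])
  }
  d
}

#' Run manifest for bit-for-bit reproducibility
#'
#' Captures what a rerun needs: the MD5 hash of the canonical YAML form of
#' the scenario, the master seed, the seed-derivation rule for replicates,
#' the package version and a timestamp.
#'
#' @param scenario A [be_scenario()].
#' @return Object of class `run_manifest`.
#' @export
run_manifest <- function(scenario) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_scenario(scenario, tmp)
  structure(list(
    config_hash = unname(tools::md5sum(tmp)),
    seed = scenario$seed,
    seed_rule = paste("replicate seeds: sample.int(2^31 - 2,",
                      "cells * replicates) under set.seed(master);",
                      "matrix filled by grid cell"),
    package_version = as.character(utils::packageVersion("hvdbe")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  ), class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("hvdbe run manifest\n")
  cat("  config md5:", x$config_hash, "\n")
  cat("  master seed:", x$seed, "\n")
  cat("  seed rule:", x$seed_rule, "\n")
  cat("  package:", x$package_version, " at ", x$timestamp, "\n")
  invisible(x)
}

#' Plot power versus total number of observations
#'
#' One line per design (if several are present), power on the y axis and the
#' total number of observations N = subjects x periods on the x axis,
#' faceted by guideline and GMR, with Monte-Carlo confidence ribbons.
#'
#' @param curve A `power_curve` data.frame.
#' @return A ggplot object.
#' @export
plot_power_curve <- function(curve) {
  stopifnot(all(c("N", "power", "design", "guideline", "gmr") %in%
                  names(curve)))
  ggplot2::ggplot(curve, ggplot2::aes(x = N, y = power,
                                      colour = design)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mc_lower,
                                      ymax = mc_upper,
                                      fill = design),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::facet_grid(guideline ~ gmr,
                        labeller = ggplot2::label_both) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Total number of observations (N)",
                  y = "Power (BE success rate)",
                  colour = "Design", fill = "Design") +
    ggplot2::theme_bw()
}

#' @export
plot.power_curve <- function(x, ...) plot_power_curve(x)
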