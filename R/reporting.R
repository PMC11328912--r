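#' @title Solvatochromism and dynamics correlation reports
#'
#' @description
#' Computed-versus-experimental regressions of the three vibrational
#' observables (central frequency, correlation time, fluctuation amplitude)
#' across solvent systems, cross-observable correlations (e.g. frequency vs
#' correlation time, whose near-zero Pearson r demonstrates the two
#' observables are independent), and report assembly. Point exclusions (a
#' solvent whose force field misbehaves; an experimental value contested in
#' the literature) are always explicit flags echoed into the result, never
#' silent drops.
#'
#' @name reporting
NULL

#' Ordinary least-squares regression with explicit exclusions
#'
#' Fits `y = intercept + slope * x` on the non-excluded points and reports the
#' signed Pearson r and r^2 (identical to OLS R^2 for simple regression).
#'
#' @param x,y numeric vectors of equal length.
#' @param exclude optional integer indices or logical mask of points to
#'   exclude; echoed in the result.
#' @param labels optional point labels used in the `excluded` echo.
#' @return an object of class `"vib_regression"`: `slope`, `intercept`,
#'   `pearson_r`, `r_squared`, `n_points`, `excluded`.
#' @export
linear_regression <- function(x, y, exclude = NULL, labels = NULL) {
  if (length(x) != length(y))
    vib_stop("x and y must have equal length", "vib_invalid_regression")
  keep <- rep(TRUE, length(x))
  if (!is.null(exclude)) {
    if (is.logical(exclude)) keep <- !exclude
    else keep[exclude] <- FALSE
  }
  xs <- x[keep]; ys <- y[keep]
  if (length(xs) < 2)
    vib_stop("need at least 2 non-excluded points", "vib_invalid_regression")
  if (any(!is.finite(xs)) || any(!is.finite(ys)))
    vib_stop("x and y must be finite on the non-excluded set",
             "vib_invalid_regression")
  if (stats::var(xs) == 0)
    vib_stop("degenerate regression: all x values identical",
             "vib_degenerate_regression")
  if (stats::var(ys) == 0)
    vib_stop("degenerate regression: all y values identical (Pearson r undefined)",
             "vib_degenerate_regression")
  fit <- stats::lm(ys ~ xs)
  r <- stats::cor(xs, ys)
  excluded <- if (is.null(labels)) which(!keep) - 1L else labels[!keep]
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    pearson_r = r, r_squared = r^2,
    n_points = length(xs), excluded = excluded),
    class = "vib_regression")
}

#' @export
print.vib_regression <- function(x, ...) {
  cat(sprintf(
    "<vib_regression: y = %.4g + %.4g x, r = %.4f, r^2 = %.4f, n = %d%s>\n",
    x$intercept, x$slope, x$pearson_r, x$r_squared, x$n_points,
    if (length(x$excluded)) paste0(", excluded: ",
                                   paste(x$excluded, collapse = ", "))
    else ""))
  invisible(x)
}

#' Cross-observable correlation over solvent records
#'
#' Correlates one observable against another across solvent systems (e.g.
#' computed central frequency vs computed correlation time). Because the
#' pairing convention for such independence checks is a reporting choice, any
#' pair of record columns can be requested.
#'
#' @param records data frame of solvent records (one row per system).
#' @param observable_x,observable_y column names.
#' @param exclude optional exclusions as in [linear_regression()].
#' @return a `vib_regression` (the signed `pearson_r` is the quantity of
#'   interest for independence checks).
#' @export
observable_correlation <- function(records, observable_x, observable_y,
                                   exclude = NULL) {
  for (col in c(observable_x, observable_y))
    if (!col %in% names(records))
      vib_stop(sprintf("records have no column '%s'", col),
               "vib_invalid_regression")
  x <- records[[observable_x]]
  y <- records[[observable_y]]
  ok <- is.finite(x) & is.finite(y)
  keep_labels <- if (!is.null(records$system)) records$system
                 else as.character(seq_len(nrow(records)) - 1L)
  excl <- !ok
  if (!is.null(exclude)) {
    if (is.logical(exclude)) excl <- excl | exclude
    else excl[exclude] <- TRUE
  }
  if (sum(!excl) < 2)
    vib_stop("both observables must be populated for at least 2 records",
             "vib_invalid_regression")
  linear_regression(x, y, exclude = excl, labels = keep_labels)
}

#' Reference solvent observables for the NMA amide I benchmark
#'
#' Central frequencies (cm^-1), FFCF correlation times (ps) and fluctuation
#' amplitudes (cm^-1) of the amide I mode of N-methylacetamide in seven
#' solvent systems: computed by the cluster-frequency pipeline and measured by
#' FTIR/2DIR. `delta_exp_ir_cm1` is the amplitude extracted from the IR/2DIR
#' spectra by the approximate lineshape analysis. Exclusion flags mark the
#' points left out of the published regressions: toluene in the frequency fit
#' (force-field deficiency) and the D2O amplitude (a conflicting literature
#' value of 9 cm^-1).
#'
#' @return a data frame, one row per solvent system.
#' @export
solvent_observables <- function() {
  path <- system.file("extdata", "nma_amide_I_observables.csv",
                      package = "vibsolv")
  if (!nzchar(path))
    vib_stop("packaged observables table not found", "vib_io_error")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Assemble a results report
#'
#' Emits a Table-style records CSV, a JSON record of all regressions with
#' their exclusions, and a run-provenance block (package version, seeds,
#' cutoffs, conventions — whatever the caller supplies).
#'
#' @param records data frame of solvent records.
#' @param regressions named list of `vib_regression` objects (may be empty).
#' @param provenance named list of run provenance entries.
#' @param outdir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
build_report <- function(records, regressions = list(),
                         provenance = list(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  records_path <- file.path(outdir, "records.csv")
  utils::write.csv(records, records_path, row.names = FALSE, na = "")
  reg_path <- file.path(outdir, "regressions.json")
  reg_list <- lapply(regressions, function(r)
    list(slope = r$slope, intercept = r$intercept, pearson_r = r$pearson_r,
         r_squared = r$r_squared, n_points = r$n_points,
         excluded = as.character(r$excluded)))
  jsonlite::write_json(reg_list, reg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  prov_path <- file.path(outdir, "provenance.json")
  prov <- c(list(package = "vibsolv",
                 version = as.character(utils::packageVersion("vibsolv")),
                 timestamp = format(Sys.time(), tz = "UTC")),
            provenance)
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(records = records_path, regressions = reg_path,
                 provenance = prov_path))
}
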