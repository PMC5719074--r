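# Plain-text interchange: CSV for kinetic datasets, with a key-value
# provenance sidecar recording the generating truth and seed.

provenance_lines <- function(x) {
  flat <- function(v) {
    if (inherits(v, "two_state_params")) v <- unclass(v)
    if (is.list(v)) v <- unlist(v)
    paste(format(v, digits = 15, trim = TRUE), collapse = " ")
  }
  attrs <- attributes(x)
  keep <- intersect(names(attrs),
                    c("mechanism", "truth", "noise_cv", "noise_sd", "seed",
                      "wavelength_nm", "porph_conc", "enzyme_conc"))
  unlist(lapply(keep, function(nm) {
    v <- attrs[[nm]]
    if (nm == "truth" && is.list(v)) {
      vv <- unlist(if (inherits(v, "two_state_params")) unclass(v) else v)
      vv <- vv[!vapply(vv, is.null, logical(1))]
      paste0("truth.", names(vv), " = ",
             vapply(vv, flat, character(1)))
    } else {
      paste0(nm, " = ", flat(v))
    }
  }))
}

#' Write a kinetic dataset as CSV with a provenance sidecar
#'
#' Writes the tabular part of a generated dataset as a headed CSV and a
#' `<path>.provenance.txt` key-value sidecar recording the generating
#' mechanism/parameters, noise level and seed.
#'
#' @param x A `michaelis_dataset`, `dose_response`, `progress_curve` or
#'   `kobs_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(x, path) {
  df <- if (inherits(x, "kobs_series")) x$points else as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE)
  prov <- if (inherits(x, "kobs_series")) {
    c(paste0("truth.", names(unlist(unclass(x$truth))), " = ",
             unlist(unclass(x$truth))),
      paste0("seed = ", x$seed))
  } else provenance_lines(x)
  writeLines(prov, paste0(path, ".provenance.txt"))
  invisible(path)
}

#' Read kinetic CSV files
#'
#' Readers for the plain CSV layouts used across the package: rate grids
#' (`S,I,v`), dose-response tables (`I,activity`), stopped-flow traces
#' (`t,A`) and observed-rate series (`x,k_obs[,se]`).  Column presence is
#' validated; no unit conversion is applied.
#'
#' @param path CSV path.
#' @return A data frame with the validated columns.
#' @name read_kinetic
NULL

read_checked <- function(path, cols) {
  df <- utils::read.csv(path)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("'", path, "' lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname read_kinetic
#' @export
read_rate_grid_csv <- function(path) read_checked(path, c("S", "I", "v"))

#' @rdname read_kinetic
#' @export
read_dose_response_csv <- function(path) read_checked(path, c("I", "activity"))

#' @rdname read_kinetic
#' @export
read_trace_csv <- function(path) read_checked(path, c("t", "A"))

#' @rdname read_kinetic
#' @export
read_kobs_csv <- function(path) read_checked(path, c("x", "k_obs"))
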