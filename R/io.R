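# Readers/writers for RT-DC style event tables and the end-to-end pipeline
# runner. Tables are CSV/TSV with the de-facto feature names (area_um,
# deform, porosity); experiment metadata travels in "#% key: value" header
# lines so a file is self-describing. The binary RT-DC HDF5 container is not
# supported in this build (no HDF5 bindings available to R here); requesting
# it points the user at the CSV path.

#' Assemble an event dataset
#'
#' @param events data.frame with at least `area_um` and `deform`.
#' @param setup a [channel_setup()] or `NULL` (required before estimation).
#' @param provenance free-form character describing the source.
#' @return list of class `guv_dataset`.
#' @export
guv_dataset <- function(events, setup = NULL, provenance = "in-memory") {
  check_events(events)
  if (any(events$area_um < 1 | events$area_um > 1e4, na.rm = TRUE))
    guv_warn("areas outside 1..1e4 um^2 found; check that area_um is in square micrometres")
  structure(list(events = events, setup = setup, provenance = provenance),
            class = "guv_dataset")
}

#' @export
print.guv_dataset <- function(x, ...) {
  cat(sprintf("GUV event dataset: %d events (%s)\n", nrow(x$events),
              x$provenance))
  if (!is.null(x$setup)) print(x$setup)
  invisible(x)
}

setup_to_meta <- function(setup) {
  if (is.null(setup)) return(character(0))
  c(sprintf("channel_um: %.10g", setup$L * 1e6),
    sprintf("flow_ul_s: %.10g", setup$Q * 1e9),
    sprintf("viscosity_mpa_s: %.10g", setup$eta * 1e3),
    sprintf("pixel_um: %.10g", setup$px * 1e6))
}

meta_to_setup <- function(meta) {
  need <- c("channel_um", "flow_ul_s", "viscosity_mpa_s")
  if (!all(need %in% names(meta))) return(NULL)
  channel_setup(channel_um = as.numeric(meta[["channel_um"]]),
                flow_ul_s = as.numeric(meta[["flow_ul_s"]]),
                viscosity_mpa_s = as.numeric(meta[["viscosity_mpa_s"]]),
                pixel_um = if ("pixel_um" %in% names(meta))
                  as.numeric(meta[["pixel_um"]]) else 0.34)
}

#' Read an RT-DC style event table
#'
#' CSV/TSV with header columns `area_um` and `deform` (others, e.g.
#' `porosity`, are carried along). Metadata lines of the form
#' `#% key: value` written by [write_events()] are parsed back into a
#' [channel_setup()]. The RT-DC HDF5 dialect is not readable in this build;
#' export the events group to CSV instead.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"`, or `"tsv"`.
#' @return a [guv_dataset()].
#' @export
read_events <- function(path, format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path))
    guv_stop("guvmech_io_error", "no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (format == "auto") {
    if (ext %in% c("rtdc", "h5", "hdf5"))
      guv_stop("guvmech_io_error",
               paste("the RT-DC HDF5 dialect is not supported in this build;",
                     "export the events group (area_um, deform[, porosity]) to CSV"))
    format <- if (ext %in% c("tsv", "tab")) "tsv" else "csv"
  }
  sep <- if (format == "tsv") "\t" else ","
  lines <- readLines(path, n = 100L)
  meta_lines <- grep("^#% ", lines, value = TRUE)
  meta <- character(0)
  if (length(meta_lines)) {
    kv <- strsplit(sub("^#% ", "", meta_lines), ": ", fixed = TRUE)
    meta <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  }
  ev <- utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  for (col in c("area_um", "deform"))
    if (!col %in% names(ev))
      guv_stop("guvmech_schema_error", "event table lacks required column '%s'",
               col)
  if (nrow(ev) == 0) {
    # empty tables come back with logical columns; coerce to numeric
    ev[] <- lapply(ev, as.numeric)
  } else if (!all(vapply(ev[c("area_um", "deform")], is.numeric, logical(1)))) {
    guv_stop("guvmech_schema_error", "area_um and deform must be numeric")
  }
  guv_dataset(ev, setup = meta_to_setup(meta), provenance = path)
}

#' Write an event table
#'
#' CSV/TSV with the dataset's metadata embedded as `#% key: value` header
#' lines; [read_events()] round-trips features and setup.
#'
#' @param dataset a [guv_dataset()].
#' @param path output path.
#' @param format `"csv"` (default) or `"tsv"`.
#' @return the path, invisibly.
#' @export
write_events <- function(dataset, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "guv_dataset"))
  sep <- if (format == "tsv") "\t" else ","
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#% ", setup_to_meta(dataset$setup)), con)
  writeLines(sprintf("#%% provenance: %s", dataset$provenance), con)
  utils::write.table(dataset$events, con, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' @param method `"combined"` (default), `"collective"` or `"direct"`.
#' @param gates a [gate_config()].
#' @param calibration a [guv_calibration()].
#' @param n_components mixture components for the combined method.
#' @param seed integer seed for stochastic stages.
#' @param pixel_correction a [pixel_correction()] coefficient set applied
#'   when the table carries an `area_px` column, or `NULL` to skip.
#' @return list of class `guv_runconfig`.
#' @export
run_config <- function(method = c("combined", "collective", "direct"),
                       gates = gate_config(),
                       calibration = default_calibration(),
                       n_components = 2, seed = 1,
                       pixel_correction = NULL) {
  method <- match.arg(method)
  if (method == "combined" && n_components < 2)
    guv_stop("guvmech_config_error",
             "combined method needs n_components >= 2")
  structure(list(method = method, gates = gates, calibration = calibration,
                 n_components = n_components, seed = as.integer(seed),
                 pixel_correction = pixel_correction),
            class = "guv_runconfig")
}

#' Run the extraction pipeline on a dataset
#'
#' Applies, in order: pixelation correction (when configured and an
#' `area_px` column is present), quality gates, and the configured estimator.
#' The report records the gate accounting, the estimate(s), mixture
#' parameters where applicable, calibration provenance and the seed, so a
#' run can be reproduced from its report alone.
#'
#' @param dataset a [guv_dataset()] with a non-`NULL` setup.
#' @param config a [run_config()].
#' @return list of class `guv_report`.
#' @export
run_extract <- function(dataset, config = run_config()) {
  stopifnot(inherits(dataset, "guv_dataset"), inherits(config, "guv_runconfig"))
  if (is.null(dataset$setup))
    guv_stop("guvmech_config_error",
             "dataset has no channel setup; attach one with guv_dataset()")
  ev <- dataset$events
  if (!is.null(config$pixel_correction) && "area_px" %in% names(ev))
    ev$deform <- pixelation_correct(ev$deform, ev$area_px,
                                    config$pixel_correction)
  gated <- apply_gates(ev, config$gates)
  message(sprintf("gates: %d kept / %d area / %d deform / %d porosity",
                  gated$counts["kept"], gated$counts["area_range"],
                  gated$counts["deform_max"], gated$counts["porosity"]))
  if (nrow(gated$kept) == 0)
    guv_stop("guvmech_empty_error", "no events left after gating")
  setup <- dataset$setup
  calib <- config$calibration
  res <- switch(config$method,
    direct = {
      K <- direct_K(gated$kept, setup, calib)
      model <- fit_lnK_mixture(K, n_components = config$n_components,
                               seed = config$seed)
      list(K_per_event = as.numeric(K), mixture = unclass_mixture(model),
           K = direct_aggregate(model), method = "direct-aggregate")
    },
    collective = {
      est <- collective_K(gated$kept, setup, calib)
      list(K = est$K, method = "collective", slope_per_um2 = est$slope,
           r_squared = est$r_squared, n_used = est$n_used)
    },
    combined = {
      cmb <- combined_K(gated$kept, setup, calib,
                        n_components = config$n_components,
                        seed = config$seed)
      list(K = vapply(cmb$estimates, `[[`, numeric(1), "K"),
           method = "combined", class_sizes = cmb$class_sizes,
           n_outliers = cmb$n_outliers,
           mixture = unclass_mixture(cmb$mixture))
    })
  structure(list(provenance = dataset$provenance,
                 n_input = nrow(dataset$events),
                 gate_counts = as.list(gated$counts),
                 method = config$method,
                 seed = config$seed,
                 calibration_provenance = calib$provenance,
                 result = res),
            class = "guv_report")
}

unclass_mixture <- function(m)
  list(weights = m$weights, means_lnK = m$means, sds_lnK = m$sds,
       K_components = exp(m$means), loglik = m$loglik, seed = m$seed)

#' @export
print.guv_report <- function(x, ...) {
  cat(sprintf("guvmech report (%s, %d events in)\n", x$method, x$n_input))
  cat("  gates kept:", x$gate_counts$kept, "\n")
  cat("  K [N/m]:", paste(signif(unlist(x$result["K"]), 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a report as JSON
#'
#' @param report a `guv_report` (or any list).
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
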