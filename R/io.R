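#' Read a movie from multi-page TIFF or HDF5
#'
#' TIFF files carry no rate metadata, so a sidecar YAML (`<path>.yaml`) with at
#' least `rate_hz` is required; `channel` and `saturation_level` are read from
#' it when present. HDF5 files store one 3-D dataset `frames` with attributes
#' `rate_hz`, `channel` and `saturation_level`. Rate metadata is mandatory in
#' both formats and is never guessed.
#'
#' @param path File path.
#' @param format `"tiff"` or `"hdf5"`; default inferred from the extension.
#' @return A [movie], time-major.
#' @export
load_movie <- function(path, format = c("auto", "tiff", "hdf5")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5" else "tiff"
  }
  if (format == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(dim(pages[[1]])) != 2L) stop("shape not 3-D: expected one 2-D grid per page")
    side <- paste0(path, ".yaml")
    if (!file.exists(side))
      stop("missing rate metadata: sidecar YAML required for TIFF movies (", side, ")")
    meta <- yaml::read_yaml(side)
    if (is.null(meta$rate_hz)) stop("missing rate metadata: `rate_hz` absent from sidecar")
    frames <- aperm(simplify2array(pages), c(3, 1, 2))
    movie(frames, rate = meta$rate_hz,
          channel = if (is.null(meta$channel)) "green" else meta$channel,
          saturation_level = if (is.null(meta$saturation_level)) 65535
                             else meta$saturation_level)
  } else {
    on.exit(rhdf5::h5closeAll(), add = TRUE)
    frames <- rhdf5::h5read(path, "frames")
    if (length(dim(frames)) != 3L) stop("shape not 3-D")
    at <- rhdf5::h5readAttributes(path, "frames")
    if (is.null(at$rate_hz)) stop("missing rate metadata: `rate_hz` attribute absent")
    movie(frames, rate = as.numeric(at$rate_hz),
          channel = if (is.null(at$channel)) "green" else as.character(at$channel),
          saturation_level = if (is.null(at$saturation_level)) 65535
                             else as.numeric(at$saturation_level))
  }
}

#' Write a movie to multi-page TIFF or HDF5
#'
#' TIFF output is 16-bit with a sidecar YAML holding the metadata; intensities
#' are rounded to integers on disk. HDF5 stores the floating-point array as-is.
#'
#' @param x A [movie].
#' @param path Output path.
#' @param format `"tiff"` or `"hdf5"`; default inferred from the extension.
#' @return `path`, invisibly.
#' @export
save_movie <- function(x, path, format = c("auto", "tiff", "hdf5")) {
  stopifnot(inherits(x, "movie"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5" else "tiff"
  }
  if (format == "tiff") {
    n <- n_frames(x)
    pages <- lapply(seq_len(n), function(i)
      round(x$frames[i, , , drop = TRUE]) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
    yaml::write_yaml(list(rate_hz = x$rate, channel = x$channel,
                          saturation_level = x$saturation_level),
                     paste0(path, ".yaml"))
  } else {
    if (file.exists(path)) unlink(path)
    on.exit(rhdf5::h5closeAll(), add = TRUE)
    rhdf5::h5createFile(path)
    rhdf5::h5write(x$frames, path, "frames")
    fid <- rhdf5::H5Fopen(path)
    did <- rhdf5::H5Dopen(fid, "frames")
    rhdf5::h5writeAttribute(x$rate, did, "rate_hz")
    rhdf5::h5writeAttribute(x$channel, did, "channel")
    rhdf5::h5writeAttribute(x$saturation_level, did, "saturation_level")
    rhdf5::H5Dclose(did)
    rhdf5::H5Fclose(fid)
  }
  invisible(path)
}

#' Read a trace from CSV
#'
#' Expects the two-column format `time_s,value` with a uniform time grid.
#'
#' @param path CSV file path.
#' @param units,polarity Passed to [trace()].
#' @return A [trace].
#' @export
read_trace_csv <- function(path, units = "au", polarity = "positive_up") {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df)))
    stop("trace CSV must have header `time_s,value`")
  dt <- diff(df$time_s)
  if (length(dt) == 0) stop("trace needs at least 2 samples")
  if (diff(range(dt)) > 1e-6 * mean(dt)) stop("time grid is not uniform")
  trace(df$value, rate = 1 / mean(dt), t0_offset = df$time_s[1],
        units = units, polarity = polarity)
}

#' Write a trace to CSV (`time_s,value`)
#' @param x A [trace].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path) {
  stopifnot(inherits(x, "trace"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

RESULT_SCHEMA_VERSION <- "1.0"

#' Save an analysis result to JSON
#'
#' Writes any of the toolkit's result objects (e.g. an exponential-onset fit, a
#' spike-match result, screening metrics) with a schema version, the object's
#' class, and an optional config echo and seed. Non-finite numeric fields are
#' serialised as explicit nulls and listed under `degenerate_fields` rather
#' than silently dropped; numeric fields round-trip at full precision.
#'
#' @param result A classed list result object.
#' @param path Output JSON path.
#' @param config Optional configuration list echoed into the file.
#' @param seed Optional integer seed echoed into the file.
#' @return `path`, invisibly.
#' @export
save_results <- function(result, path, config = NULL, seed = NULL) {
  if (!is.list(result) || is.null(class(result)))
    stop("result must be one of the toolkit's classed result objects")
  payload <- unclass(result)
  degen <- character(0)
  for (nm in names(payload)) {
    v <- payload[[nm]]
    if (is.numeric(v) && length(v) > 0 && any(!is.finite(v))) degen <- c(degen, nm)
  }
  doc <- list(schema_version = RESULT_SCHEMA_VERSION,
              class = class(result)[1],
              config = config, seed = seed,
              degenerate_fields = degen,
              data = payload)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", null = "null", dataframe = "columns")
  invisible(path)
}

#' Load an analysis result written by [save_results()]
#'
#' @param path JSON path.
#' @return The result object with its class restored; JSON nulls in numeric
#'   fields come back as `NA`.
#' @export
load_results <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- doc$data
  if (!is.null(doc$degenerate_fields) && length(doc$degenerate_fields) > 0) {
    for (nm in doc$degenerate_fields) {
      if (is.null(out[[nm]])) out[[nm]] <- NA_real_
      out[[nm]] <- as.numeric(out[[nm]])
    }
  }
  class(out) <- doc$class
  attr(out, "schema_version") <- doc$schema_version
  attr(out, "seed") <- doc$seed
  out
}

#' Read a run configuration from YAML
#' @param path YAML path with fields matching [run_config()] arguments;
#'   `band_edges` is a list of two-element `[low, high]` arrays (low may be
#'   `null` for a lowpass band).
#' @return A [run_config].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  bands <- if (is.null(y$band_edges)) NULL else
    lapply(y$band_edges, function(b)
      c(if (is.null(b[[1]])) NA_real_ else as.numeric(b[[1]]), as.numeric(b[[2]])))
  run_config(mode = if (is.null(y$mode)) "awake" else y$mode,
             band_edges = bands,
             baseline_window = if (is.null(y$baseline_window)) c(2, 2.5)
                               else as.numeric(y$baseline_window),
             lowpass_cutoff = if (is.null(y$lowpass_cutoff)) 70 else y$lowpass_cutoff,
             seed = if (is.null(y$seed)) 1L else y$seed,
             roi_size = if (is.null(y$roi_size)) 2L else y$roi_size)
}
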