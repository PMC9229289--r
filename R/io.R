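#' Read an ECG signal from a single-column CSV
#'
#' Accepts a headerless single column of voltage samples, or a CSV whose
#' first column is numeric (a header row is skipped automatically).
#'
#' @param path File path.
#' @param fs Sampling rate in Hz (required; CSV files carry no rate).
#' @param record_id Optional label; defaults to the file name.
#' @return An [ecg_signal()].
#' @export
read_ecg_csv <- function(path, fs, record_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(fs) || is.null(fs)) {
    stop("a sampling rate (fs) must be supplied for CSV signals")
  }
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1L]][1L])))
  tab <- utils::read.csv(path, header = has_header)
  ecg_signal(as.numeric(tab[[1L]]), fs, record_id)
}

#' Write an ECG signal to a single-column CSV
#'
#' @param signal An [ecg_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(signal, path) {
  stopifnot(inherits(signal, "ecg_signal"))
  utils::write.table(data.frame(sample = signal$samples), path,
                     sep = ",", row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a WFDB record (header + format-16 signal)
#'
#' Minimal reader for the PhysioNet WFDB format: parses the `.hea` header
#' (record line `name nsig fs nsamp`, one signal specification line per
#' channel) and loads channel 0 from the interleaved 16-bit little-endian
#' `.dat` file, applying `(digital - baseline) / gain`. Only format 16 is
#' supported.
#'
#' @param record Path to the record, with or without the `.hea` extension.
#' @param fs_override Optional sampling rate overriding the header value.
#' @return An [ecg_signal()].
#' @export
read_wfdb <- function(record, fs_override = NULL) {
  hea <- if (grepl("\\.hea$", record)) record else paste0(record, ".hea")
  if (!file.exists(hea)) stop("file not found: ", hea)
  lines <- readLines(hea)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec_fields <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(rec_fields) < 4L) stop("malformed WFDB header: ", hea)
  nsig <- suppressWarnings(as.integer(rec_fields[2L]))
  fs <- suppressWarnings(as.numeric(rec_fields[3L]))
  nsamp <- suppressWarnings(as.integer(rec_fields[4L]))
  if (any(is.na(c(nsig, fs, nsamp)))) stop("malformed WFDB header: ", hea)
  sig_fields <- strsplit(trimws(lines[2L]), "\\s+")[[1L]]
  dat_file <- file.path(dirname(hea), sig_fields[1L])
  fmt <- sig_fields[2L]
  if (fmt != "16") stop("unsupported WFDB signal format: ", fmt)
  gain_spec <- if (length(sig_fields) >= 3L) sig_fields[3L] else "200"
  gain <- as.numeric(sub("[(/].*$", "", gain_spec))
  baseline <- if (grepl("\\(", gain_spec)) {
    as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_spec))
  } else 0
  if (is.na(gain) || gain == 0) gain <- 200
  con <- file(dat_file, "rb")
  on.exit(close(con))
  digital <- readBin(con, "integer", n = nsamp * nsig, size = 2L,
                     signed = TRUE, endian = "little")
  channel0 <- digital[seq(1L, length(digital), by = nsig)]
  ecg_signal((channel0 - baseline) / gain,
             if (is.null(fs_override)) fs else fs_override,
             record_id = rec_fields[1L])
}

#' Write a WFDB record (header + format-16 signal)
#'
#' Quantises the samples to `round(v * gain)` 16-bit integers. Samples that
#' already lie on the `1/gain` grid round-trip exactly through
#' [read_wfdb()].
#'
#' @param signal An [ecg_signal()].
#' @param record Output path without extension.
#' @param gain ADC gain (units per mV).
#' @return `record`, invisibly.
#' @export
write_wfdb <- function(signal, record, gain = 1000) {
  stopifnot(inherits(signal, "ecg_signal"))
  name <- basename(record)
  digital <- as.integer(round(signal$samples * gain))
  if (any(abs(digital) > 32767L)) stop("signal exceeds 16-bit range at this gain")
  writeLines(c(
    sprintf("%s 1 %g %d", name, signal$fs, length(digital)),
    sprintf("%s.dat 16 %g(0)/mV 16 0 0 0 0 ECG", name, gain)
  ), paste0(record, ".hea"))
  con <- file(paste0(record, ".dat"), "wb")
  on.exit(close(con))
  writeBin(digital, con, size = 2L, endian = "little")
  invisible(record)
}

#' Read any supported record format
#'
#' Dispatches on the file: a `.hea` file (or a path for which `path.hea`
#' exists) is read as a WFDB record, anything else as single-column CSV.
#'
#' @param path Record path.
#' @param fs Sampling rate, required for CSV and overriding a WFDB header.
#' @return An [ecg_signal()].
#' @export
read_record <- function(path, fs = NULL) {
  if (grepl("\\.hea$", path) || file.exists(paste0(path, ".hea"))) {
    return(read_wfdb(path, fs_override = fs))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  read_ecg_csv(path, fs)
}

#' Weighted average of per-database metrics
#'
#' `sum(w * v) / sum(w)` reported to 2 decimals, the convention used for
#' pooling per-database percentages with subject counts as weights.
#'
#' @param values Numeric metric per database.
#' @param weights Positive weights (e.g. subject counts), same length.
#' @return Weighted mean rounded to 2 decimals.
#' @examples
#' weighted_average(c(93.24, 89.57, 82.47), c(90, 18, 48))
#' @export
weighted_average <- function(values, weights) {
  if (length(values) != length(weights)) {
    stop("values and weights must have the same length")
  }
  if (any(weights <= 0)) stop("weights must be positive")
  round(sum(values * weights) / sum(weights), 2)
}

#' Write fiducials to JSON
#'
#' Exports one object per cycle with 0-based sample indices (the convention
#' is stated in the file's `index_base` field).
#'
#' @param fiducials A [fiducial_set][assemble_fiducials()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fiducials <- function(fiducials, path) {
  cols <- c("p_on", "p_peak", "p_off", "q", "r", "s", "t_on", "t_peak",
            "t_off")
  cycles <- as.data.frame(fiducials)
  cycles[cols] <- lapply(cycles[cols], function(v) v - 1L)
  payload <- list(
    index_base = 0L,
    mean_rr = attr(fiducials, "mean_rr"),
    r_all = attr(fiducials, "r_all") - 1L,
    excluded = attr(fiducials, "excluded"),
    cycles = cycles
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read fiducials from JSON
#'
#' @param path A file written by [write_fiducials()].
#' @return A `fiducial_set` with 1-based indices.
#' @export
read_fiducials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cycles <- as.data.frame(payload$cycles)
  cols <- c("p_on", "p_peak", "p_off", "q", "r", "s", "t_on", "t_peak",
            "t_off")
  cycles[cols] <- lapply(cycles[cols], function(v) as.integer(v) + 1L)
  structure(cycles,
            mean_rr = payload$mean_rr,
            r_all = as.integer(payload$r_all) + 1L,
            excluded = as.integer(payload$excluded),
            class = c("fiducial_set", "data.frame"))
}

#' Write / read a feature matrix as CSV
#'
#' The CSV header is the 22 feature names plus `label` (and `cycle` when
#' present); values round-trip at full precision.
#'
#' @param features Data frame from [build_dataset()].
#' @param path File path.
#' @return `path` (write) or the data frame (read).
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, check.names = FALSE)
}

#' Serialize / deserialize a PNN model as JSON
#'
#' @param model A fitted [pnn_fit()] model.
#' @param path File path.
#' @return `path` (write) or the reconstructed model (read).
#' @export
write_pnn <- function(model, path) {
  stopifnot(inherits(model, "pnn"))
  payload <- list(
    classes = model$classes,
    delta = model$delta,
    d = model$d,
    standard_gaussian = model$standard_gaussian,
    labels = as.character(model$y),
    exemplars = unname(apply(model$x, 1L, as.numeric, simplify = FALSE)),
    feature_names = colnames(model$x)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pnn
#' @export
read_pnn <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  x <- payload$exemplars
  if (is.list(x)) x <- do.call(rbind, lapply(x, as.numeric))
  x <- as.matrix(x)
  if (!nrow(x)) stop("model file contains no exemplars")
  if (length(payload$feature_names) == ncol(x)) {
    colnames(x) <- payload$feature_names
  }
  labels <- payload$labels
  classes <- payload$classes
  if (is.numeric(classes)) {
    labels <- as.numeric(labels)
    if (all(classes == round(classes))) labels <- as.integer(labels)
  }
  model <- pnn_fit(x, delta = payload$delta, labels = labels,
                   standard_gaussian = isTRUE(payload$standard_gaussian))
  model
}
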