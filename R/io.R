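#' Column dialect for delimited time-series files
#'
#' Trough-software exports vary in separators, decimal marks and column
#' naming; a dialect object maps a file's layout onto the package's record
#' types. The default is comma-separated with a header row and SI-with-mN/m
#' column names, which is also what [write_timeseries()] emits.
#'
#' @param sep Field separator.
#' @param dec Decimal mark.
#' @param header Logical; does the file carry a header row?
#' @param time,pi,area Column names holding time (s), surface pressure
#'   (mN/m) and trough area.
#' @return An object of class `timeseries_dialect`.
#' @examples
#' timeseries_dialect(sep = "\t", time = "t", pi = "pressure")
#' @export
timeseries_dialect <- function(sep = ",", dec = ".", header = TRUE,
                               time = "time_s", pi = "pi_mn_per_m",
                               area = "area") {
  structure(list(sep = sep, dec = dec, header = header,
                 time = time, pi = pi, area = area),
            class = "timeseries_dialect")
}

# parse "# key: value" annotation lines written by write_timeseries
read_annotations <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  ann <- list(); n <- 0L
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || !startsWith(line, "#")) break
    n <- n + 1L
    m <- regmatches(line, regexec("^#\\s*([^:]+):\\s*(.*)$", line))[[1]]
    if (length(m) == 3L) ann[[trimws(m[2])]] <- trimws(m[3])
  }
  list(annotations = ann, n_lines = n)
}

#' Read a surface-pressure time series from a delimited text file
#'
#' Reads a relaxation transient, trough cycle recording or kinetics trace
#' from CSV/TSV, validates it and returns the corresponding typed record.
#' Rows containing non-finite values are rejected; their file line numbers
#' are reported in a warning and attached as attribute `dropped_lines`.
#'
#' Files written by [write_timeseries()] carry annotation lines
#' (`# key: value`) holding `pi0`, `strain`, the area unit and metadata;
#' these are honoured on reading, so a write-read round trip is
#' value-identical. For foreign files the missing scalars (`strain`, `pi0`)
#' must be supplied as arguments.
#'
#' @param path File path.
#' @param kind One of `"relaxation"`, `"trough"`, `"kinetics"`.
#' @param dialect A [timeseries_dialect()].
#' @param strain,pi0,area_unit Scalars forwarded to the record constructor
#'   when the file does not annotate them.
#' @param meta Extra metadata merged over any annotated metadata.
#' @return A [relaxation_transient()], [trough_recording()] or
#'   [kinetics_trace()] according to `kind`.
#' @seealso [write_timeseries()]
#' @export
read_timeseries <- function(path, kind = c("relaxation", "trough", "kinetics"),
                            dialect = timeseries_dialect(),
                            strain = NULL, pi0 = NULL, area_unit = NULL,
                            meta = list()) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  hdr <- read_annotations(path)
  df <- tryCatch(
    utils::read.table(path, sep = dialect$sep, dec = dialect$dec,
                      header = dialect$header, comment.char = "#",
                      stringsAsFactors = FALSE),
    error = function(e) stop_format(sprintf("cannot parse '%s': %s", path, conditionMessage(e))))

  need <- switch(kind,
                 relaxation = c(dialect$time, dialect$pi),
                 trough = c(dialect$time, dialect$area, dialect$pi),
                 kinetics = c(dialect$time, dialect$pi))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_format(sprintf("missing column(s) in '%s': %s", path,
                        paste(missing_cols, collapse = ", ")))
  for (cn in need) {
    if (!is.numeric(df[[cn]])) {
      suppressWarnings(df[[cn]] <- as.numeric(df[[cn]]))
      if (all(is.na(df[[cn]])))
        stop_format(sprintf("column '%s' in '%s' is not numeric", cn, path))
    }
  }

  ok <- Reduce(`&`, lapply(need, function(cn) is.finite(df[[cn]])))
  dropped <- integer(0)
  if (!all(ok)) {
    # file line = annotation lines + header line + data row index
    dropped <- which(!ok) + hdr$n_lines + as.integer(dialect$header)
    warning(sprintf("dropped %d row(s) with non-finite values from '%s' (file lines: %s)",
                    sum(!ok), path, paste(dropped, collapse = ", ")))
    df <- df[ok, , drop = FALSE]
  }

  ann <- hdr$annotations
  num_ann <- function(key, fallback) {
    if (!is.null(fallback)) return(fallback)
    if (!is.null(ann[[key]])) return(as.numeric(ann[[key]]))
    NULL
  }
  ann_meta <- ann[startsWith(names(ann) %||% character(0), "meta_")]
  names(ann_meta) <- sub("^meta_", "", names(ann_meta))
  meta <- utils::modifyList(as.list(ann_meta), as.list(meta))

  out <- switch(kind,
    relaxation = relaxation_transient(
      time = df[[dialect$time]], pi = df[[dialect$pi]],
      strain = num_ann("strain", strain), pi0 = num_ann("pi0_mn_per_m", pi0),
      meta = meta),
    trough = trough_recording(
      time = df[[dialect$time]], area = df[[dialect$area]],
      pi = df[[dialect$pi]],
      area_unit = if (!is.null(area_unit)) area_unit
                  else if (!is.null(ann$area_unit)) ann$area_unit else "cm^2",
      meta = meta),
    kinetics = kinetics_trace(
      time = df[[dialect$time]], pi = df[[dialect$pi]],
      pi0 = num_ann("pi0_mn_per_m", pi0), meta = meta))
  attr(out, "dropped_lines") <- dropped
  out
}

#' Write a time-series record to a delimited text file
#'
#' Emits annotation lines (`# key: value`) carrying the record type, scalar
#' fields (`pi0`, `strain`, area unit) and metadata, followed by a delimited
#' table whose header names the units. Numbers are written at full precision
#' so that [read_timeseries()] recovers a value-identical record.
#'
#' If the record carries synthetic ground truth (see [gen_relaxation()] and
#' friends), a JSON sidecar `<path>.truth.json` is written alongside.
#'
#' @param x A record produced by [relaxation_transient()],
#'   [trough_recording()] or [kinetics_trace()].
#' @param path Output file path.
#' @param dialect A [timeseries_dialect()] controlling separator, decimal
#'   mark and column names.
#' @param sidecar Write the ground-truth sidecar when present? Default yes.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path, dialect = timeseries_dialect(),
                             sidecar = TRUE) {
  lines <- character(0)
  add <- function(k, v) lines <<- c(lines, sprintf("# %s: %s", k, v))
  cols <- list()
  if (inherits(x, "relaxation_transient")) {
    add("type", "relaxation_transient")
    add("pi0_mn_per_m", format_full(x$pi0))
    add("strain", format_full(x$strain))
    cols[[dialect$time]] <- x$time
    cols[[dialect$pi]] <- x$pi
  } else if (inherits(x, "trough_recording")) {
    add("type", "trough_recording")
    add("area_unit", x$area_unit)
    cols[[dialect$time]] <- x$time
    cols[[dialect$area]] <- x$area
    cols[[dialect$pi]] <- x$pi
  } else if (inherits(x, "kinetics_trace")) {
    add("type", "kinetics_trace")
    add("pi0_mn_per_m", format_full(x$pi0))
    cols[[dialect$time]] <- x$time
    cols[[dialect$pi]] <- x$pi
  } else {
    stop_validation("'x' must be a relaxation_transient, trough_recording or kinetics_trace")
  }
  for (k in names(x$meta)) add(paste0("meta_", k), as.character(x$meta[[k]]))

  tab <- vapply(cols, format_full, character(length(cols[[1]])))
  if (!is.matrix(tab)) tab <- matrix(tab, nrow = 1, dimnames = list(NULL, names(cols)))
  if (dialect$dec != ".") tab <- gsub(".", dialect$dec, tab, fixed = TRUE)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(lines, con)
  if (dialect$header) writeLines(paste(names(cols), collapse = dialect$sep), con)
  writeLines(apply(tab, 1, paste, collapse = dialect$sep), con)

  truth <- attr(x, "truth")
  if (sidecar && !is.null(truth)) {
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}
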