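#' Write a sweep to columnar text with a JSON metadata sidecar
#'
#' The data file is tab-separated with columns `time_ms`, `current_pA`,
#' `voltage_mV` at full double precision; metadata (protocol kind, blocker,
#' concentration, holding voltage, sample rate, seed and the mandatory units
#' declaration) goes to `<path>.json`. A write/read round trip is lossless
#' to better than 1e-9.
#'
#' @param sweep A [new_sweep()].
#' @param path Output path for the data file (e.g. `"sweep.tsv"`).
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep"))
  dt <- data.table::data.table(
    time_ms = sweep$time_ms,
    current_pA = sweep$current_pA,
    voltage_mV = sweep$voltage_mV
  )
  data.table::fwrite(dt, path, sep = "\t")
  jsonlite::write_json(
    sweep$meta,
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Read a sweep written by [write_sweep()]
#'
#' Units metadata is mandatory and validated; only the canonical
#' ms / pA / mV units are accepted (converters live at the I/O boundary, and
#' none are needed for files this package writes).
#'
#' @param path Path to the data file; `<path>.json` must exist.
#' @return A [new_sweep()].
#' @export
read_sweep <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing units metadata: sidecar ", side, " not found")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$units) || !all(c("time", "current", "voltage") %in% names(meta$units))) {
    stop("missing units metadata: sidecar must declare time/current/voltage units")
  }
  if (!identical(unname(unlist(meta$units[c("time", "current", "voltage")])),
                 c("ms", "pA", "mV"))) {
    stop("unsupported units: expected ms / pA / mV")
  }
  d <- tryCatch(
    data.table::fread(path, sep = "\t"),
    error = function(e) stop("malformed sweep file ", path, ": ", conditionMessage(e))
  )
  need <- c("time_ms", "current_pA", "voltage_mV")
  if (!all(need %in% names(d))) {
    stop("malformed sweep file ", path, ": expected columns ", paste(need, collapse = ", "))
  }
  bad <- which(!stats::complete.cases(d[, need, with = FALSE]))
  if (length(bad)) stop("malformed row ", bad[1] + 1L, " in ", path)
  units <- meta$units
  meta$units <- NULL
  sw <- new_sweep(d$time_ms, d$current_pA, d$voltage_mV, meta = as.list(meta))
  sw
}
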