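#' Taylorgram container
#'
#' A time-ordered fluorescence trace plus acquisition metadata: the atomic
#' observable of the pipeline. Time must be strictly increasing (uniform
#' spacing is not required) and the trace must hold at least 50 samples.
#'
#' @param time Time in s, strictly increasing, length >= 50.
#' @param signal Fluorescence (arbitrary units), same length as `time`.
#' @param meta Named list of acquisition metadata. Recognized entries:
#'   `indicator_id`, `indicator_conc` (M), `analyte_id`, `analyte_conc`
#'   (M), `dilution_factor` (>= 1), `replicate_index`, `method`.
#' @return Object of class `taylorgram`.
#' @export
taylorgram <- function(time, signal, meta = list()) {
  time <- as.numeric(time); signal <- as.numeric(signal)
  if (length(time) != length(signal))
    stop("time and signal must have the same length")
  if (length(time) < 50)
    stop("a Taylorgram needs at least 50 samples (got ", length(time), ")")
  bad <- which(diff(time) <= 0)
  if (length(bad))
    stop("time must be strictly increasing; first violation at row ",
         bad[1] + 1L)
  if (!is.null(meta$dilution_factor)) {
    meta$dilution_factor <- as.numeric(meta$dilution_factor)
    if (meta$dilution_factor < 1) stop("dilution_factor must be >= 1")
  }
  structure(list(time = time, signal = signal, meta = meta),
            class = "taylorgram")
}

#' @export
print.taylorgram <- function(x, ...) {
  cat(sprintf("Taylorgram: %d samples, t in [%.3g, %.3g] s, peak %.3g at %.3g s\n",
              length(x$time), min(x$time), max(x$time),
              max(x$signal), x$time[which.max(x$signal)]))
  if (length(x$meta)) {
    keep <- intersect(c("indicator_id", "indicator_conc", "analyte_id",
                        "analyte_conc", "dilution_factor", "replicate_index"),
                      names(x$meta))
    for (k in keep) cat(sprintf("  %s: %s\n", k, format(x$meta[[k]])))
  }
  invisible(x)
}

#' @export
plot.taylorgram <- function(x, ...) {
  graphics::plot(x$time, x$signal, type = "l", xlab = "time (s)",
                 ylab = "fluorescence (a.u.)", ...)
  invisible(x)
}

## metadata entries serialized to / parsed from the CSV header
.TG_META_NUMERIC <- c("indicator_conc", "analyte_conc", "dilution_factor",
                      "replicate_index")

#' Read and write Taylorgram CSV files
#'
#' Traces are stored as plain CSV with `#`-prefixed `key: value` metadata
#' header lines followed by the columns `time_s, fluorescence_au`.
#' A write/read round trip is lossless to full double precision.
#'
#' @param trace A [taylorgram()].
#' @param path File path.
#' @return `read_taylorgram_csv` returns a [taylorgram()];
#'   `write_taylorgram_csv` returns `path` invisibly.
#' @export
write_taylorgram_csv <- function(trace, path) {
  stopifnot(inherits(trace, "taylorgram"))
  con <- file(path, "w"); on.exit(close(con))
  m <- trace$meta
  m <- m[!vapply(m, is.null, logical(1))]
  for (k in names(m)) {
    v <- m[[k]]
    if (is.numeric(v)) v <- sprintf("%.17g", v)
    if (is.character(v) || length(v) == 1)
      writeLines(sprintf("# %s: %s", k, v), con)
  }
  writeLines("time_s,fluorescence_au", con)
  writeLines(sprintf("%.17g,%.17g", trace$time, trace$signal), con)
  invisible(path)
}

#' @rdname write_taylorgram_csv
#' @export
read_taylorgram_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- list()
  for (l in lines[hdr]) {
    kv <- sub("^#\\s*", "", l)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- if (key %in% .TG_META_NUMERIC) as.numeric(val) else val
  }
  body <- lines[!hdr]
  if (!length(body) || !grepl("time_s", body[1]) ||
      !grepl("fluorescence_au", body[1]))
    stop("missing required columns time_s, fluorescence_au in ", path)
  dat <- utils::read.csv(textConnection(body), header = TRUE)
  bad <- which(diff(dat$time_s) <= 0)
  if (length(bad))
    stop("time_s not strictly increasing in ", path, " at data row ",
         bad[1] + 1L)
  taylorgram(dat$time_s, dat$fluorescence_au, meta)
}
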