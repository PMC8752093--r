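#' Write an intensity trace to a tab-separated file
#'
#' Header lines are prefixed with `#` and carry `key=value` pairs
#' (`bin_width`, `duration`, plus any metadata); data columns are
#' `bin_index`, `counts_G`, `counts_R`.
#'
#' @param trace An [intensity_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "intensity_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bin_width=%.12g", trace$bin_width), con)
  writeLines(sprintf("# duration=%.12g", trace$duration), con)
  for (key in names(trace$metadata)) {
    writeLines(sprintf("# %s=%s", key, as.character(trace$metadata[[key]])), con)
  }
  writeLines("bin_index\tcounts_G\tcounts_R", con)
  write.table(
    data.frame(
      bin_index = seq_len(trace$n_bins) - 1L,
      counts_G = trace$counts_G, counts_R = trace$counts_R
    ),
    con,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read an intensity trace written by [write_trace()]
#'
#' @param path File path.
#' @return An [intensity_trace()] with metadata recovered from the header.
#' @export
read_trace <- function(path) {
  lines <- readLines(path, n = 200)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^=]+)=(.*)$", h))[[1]]
    if (length(m) == 3) kv[[trimws(m[2])]] <- trimws(m[3])
  }
  if (is.null(kv$bin_width)) stop("trace file lacks a bin_width header")
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  meta <- kv[setdiff(names(kv), c("bin_width", "duration"))]
  intensity_trace(d$counts_G, d$counts_R,
    bin_width = as.numeric(kv$bin_width), metadata = meta
  )
}

#' Write a correlation curve to a tab-separated file
#'
#' @param curve A `correlation_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "correlation_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pair=%s", curve$pair), con)
  writeLines(sprintf("# mean_rate_A=%.12g", curve$mean_rate_A), con)
  writeLines(sprintf("# mean_rate_B=%.12g", curve$mean_rate_B), con)
  writeLines(sprintf("# duration=%.12g", curve$duration), con)
  writeLines(sprintf("# bin_width=%.12g", curve$bin_width), con)
  writeLines("lag_s\tG\tG_err", con)
  write.table(
    data.frame(lag_s = curve$lags, G = curve$G, G_err = curve$G_err),
    con,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read a correlation curve written by [write_curve()]
#'
#' @param path File path.
#' @return A `correlation_curve`.
#' @export
read_curve <- function(path) {
  lines <- readLines(path, n = 50)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^=]+)=(.*)$", h))[[1]]
    if (length(m) == 3) kv[[trimws(m[2])]] <- trimws(m[3])
  }
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  correlation_curve(
    lags = d$lag_s, G = d$G, G_err = d$G_err,
    pair = kv$pair %||% "GG",
    mean_rate_A = as.numeric(kv$mean_rate_A %||% NA),
    mean_rate_B = as.numeric(kv$mean_rate_B %||% NA),
    duration = as.numeric(kv$duration %||% NA),
    bin_width = as.numeric(kv$bin_width %||% min(d$lag_s))
  )
}
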