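#' Multichannel LFP recording container
#'
#' Bundles a time x channel sample matrix with its sampling rate and
#' channel -> region metadata. All downstream stages (staging, PSD, PLV, PAC)
#' operate on this container.
#'
#' @param data numeric matrix, samples in rows, channels in columns (microvolts).
#' @param rate sampling frequency in Hz (> 0).
#' @param channels character vector of channel labels; defaults to the column
#'   names of `data`.
#' @param region named character vector mapping every channel label to a region
#'   (e.g. `"S1"` or `"RFA"`).
#' @param start_time recording start time in seconds.
#' @return an object of class `lfp_recording` with elements `data`, `rate`,
#'   `channels`, `region`, `start_time`.
#' @export
lfp_recording <- function(data, rate, channels = colnames(data), region,
                          start_time = 0) {
  data <- as.matrix(data)
  if (is.null(channels)) {
    channels <- paste0("ch", seq_len(ncol(data)))
  }
  stopifnot(length(channels) == ncol(data))
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("rate must be a single positive number")
  }
  missing_reg <- setdiff(channels, names(region))
  if (length(missing_reg) > 0) {
    stop("channels without a region: ", paste(missing_reg, collapse = ", "))
  }
  colnames(data) <- channels
  structure(
    list(data = data, rate = rate, channels = channels,
         region = region[channels], start_time = start_time),
    class = "lfp_recording"
  )
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$data), nrow(x$data), x$rate, nrow(x$data) / x$rate))
  cat("regions:", paste(sprintf("%s=%d", names(table(x$region)),
                                table(x$region)), collapse = ", "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `lfp_recording`
#' @return duration in seconds
#' @export
rec_duration <- function(rec) nrow(rec$data) / rec$rate

#' Write a recording to a binary container with JSON sidecar
#'
#' Samples are stored channel-interleaved as little-endian doubles in
#' `<path>.bin`; metadata (`rate`, `channels`, `region_of`, `units`,
#' `n_samples`, `start_time`) goes to `<path>.json`.
#'
#' @param rec an `lfp_recording`
#' @param path file path without extension
#' @return `path`, invisibly
#' @export
write_recording <- function(rec, path) {
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(t(rec$data)), con, size = 8, endian = "little")
  meta <- list(rate = rec$rate, channels = rec$channels,
               region_of = as.list(rec$region), units = "uV",
               n_samples = nrow(rec$data), start_time = rec$start_time)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#' @param path file path without extension
#' @return an `lfp_recording`
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  nch <- length(meta$channels)
  raw <- readBin(con, "double", n = meta$n_samples * nch, size = 8,
                 endian = "little")
  data <- t(matrix(raw, nrow = nch))
  region <- unlist(meta$region_of)
  lfp_recording(data, meta$rate, channels = meta$channels, region = region,
                start_time = meta$start_time %||% 0)
}
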