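#' Write a recording to the binary matrix format
#'
#' Stores the channel x sample matrix as little-endian float32 (channel-major,
#' i.e. sample blocks of n_channels values) in `<path>.bin` with a JSON
#' sidecar `<path>.json` holding fs, channel labels, start time, units and
#' dimensions.
#'
#' @param rec a `recording`.
#' @param path output path stem (without extension).
#' @return the path stem, invisibly.
#' @export
write_recording <- function(rec, path) {
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 4L, endian = "little")
  meta <- list(fs = rec$fs, n_channels = nrow(rec$data),
               n_samples = ncol(rec$data), channel_labels = rec$channel_labels,
               start_time = rec$start_time, units = "uV",
               dtype = "float32", order = "channel-major")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path path stem (without extension).
#' @return a `recording`.
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = meta$n_channels * meta$n_samples,
               size = 4L, endian = "little")
  recording(matrix(x, nrow = meta$n_channels), fs = meta$fs,
            channel_labels = meta$channel_labels,
            start_time = meta$start_time)
}

#' Write an event schedule as TSV
#'
#' @param schedule an `event_schedule` (or compatible data.frame).
#' @param path output file path.
#' @export
write_events_tsv <- function(schedule, path) {
  df <- as.data.frame(schedule)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an event schedule TSV
#'
#' @param path file path.
#' @param total_duration optional recording duration to re-attach.
#' @return an `event_schedule` data.frame.
#' @export
read_events_tsv <- function(path, total_duration = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!is.null(total_duration)) attr(df, "total_duration") <- total_duration
  class(df) <- c("event_schedule", "data.frame")
  df
}

#' Write simulation ground truth as JSON
#'
#' @param ground_truth ground-truth list from [synthesize_participant()].
#' @param path output file path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a feature set as TSV (one row per sample)
#'
#' @param fs a `feature_set`.
#' @param path output file path.
#' @export
write_features_tsv <- function(fs, path) {
  df <- as.data.frame(fs$X)
  names(df) <- fs$feature_names
  df$label <- fs$y
  df$category <- fs$condition$category
  df$timepoint_s <- fs$condition$timepoint
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
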