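#' Read and write tab-separated feature tables
#'
#' Tables have a `subject_id` column, a `group` (or `class`) column, then
#' numeric feature/region columns. Column names are preserved verbatim.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(tab)) stop("table lacks a subject_id column")
  tab
}

#' @rdname read_feature_table
#' @param x table to write.
#' @export
write_feature_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write hypnograms as TSV
#'
#' Columns: `epoch`, `zt_hours`, `state`. The epoch duration is recovered from
#' the zeitgeber-time spacing on read.
#'
#' @param path file path.
#' @return a [hypnogram()].
#' @export
read_hypnogram <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  epoch_s <- round(diff(tab$zt_hours[1:2]) * 3600, 6)
  hypnogram(tab$state, epoch_s = epoch_s, start_zt = tab$zt_hours[1])
}

#' @rdname read_hypnogram
#' @param hyp hypnogram to write.
#' @export
write_hypnogram <- function(hyp, path) {
  utils::write.table(as.data.frame(hyp), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write EEG/EMG recordings
#'
#' Stored as a TSV of samples (`eeg`, `emg`) beside a JSON header carrying
#' the sampling rate and start time, at `<prefix>.tsv` / `<prefix>.json`.
#'
#' @param prefix path prefix (without extension).
#' @return an `eeg_recording`.
#' @export
read_eeg_recording <- function(prefix) {
  hdr <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  tab <- utils::read.delim(paste0(prefix, ".tsv"))
  structure(list(eeg = tab$eeg, emg = tab$emg, fs = hdr$fs,
                 start_zt = hdr$start_zt), class = "eeg_recording")
}

#' @rdname read_eeg_recording
#' @param rec recording to write.
#' @export
write_eeg_recording <- function(rec, prefix) {
  jsonlite::write_json(list(fs = rec$fs, start_zt = rec$start_zt,
                            channels = c("eeg", "emg")),
                       paste0(prefix, ".json"), auto_unbox = TRUE)
  utils::write.table(data.frame(eeg = rec$eeg, emg = rec$emg),
                     paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(prefix)
}

#' Write a thresholded network
#'
#' Edge list as TSV (`region_a`, `region_b`, `r`, `p`); optionally also
#' GraphML for graph tools.
#'
#' @param net a `corr_network` from [joined_network()].
#' @param path TSV output path.
#' @param graphml_path optional GraphML output path.
#' @export
write_corr_network <- function(net, path, graphml_path = NULL) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = data.frame(name = net$nodes))
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(path)
}

#' Write synthetic ground truth as JSON
#'
#' @param truth the `truth` element of a generator result.
#' @param path output path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
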