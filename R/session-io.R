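# Session container: R serialization for the numeric payload plus a
# human-readable YAML sidecar for protocol, parameters and ground truth.

#' Write a session to disk
#'
#' Serializes the full session (data, events, layout, ground truth) to
#' an RDS container and writes a YAML sidecar next to it with the
#' protocol, model parameters and ground-truth labels, so the session's
#' provenance can be inspected without loading the data. The round trip
#' through [read_session()] preserves the numeric data bit-exactly.
#'
#' @param session A `photic_session` (or any `meg_recording`).
#' @param path Output path; `.rds` is appended when missing. The
#'   sidecar replaces the extension with `.yaml`.
#' @return Invisibly, the container path.
#' @export
write_session <- function(session, path) {
  if (!grepl("\\.rds$", path)) path <- paste0(path, ".rds")
  saveRDS(session, path)
  sidecar <- sub("\\.rds$", ".yaml", path)
  meta <- if (inherits(session, "photic_session")) {
    list(
      container = basename(path),
      protocol = unclass(session$protocol),
      params = Filter(Negate(is.function), unclass(session$params)),
      ground_truth = lapply(split(session$ground_truth,
                                  seq_len(nrow(session$ground_truth))),
                            as.list),
      n_channels = nrow(session$layout),
      blocks = names(session$blocks)
    )
  } else {
    list(container = basename(path), class = class(session)[1])
  }
  yaml::write_yaml(meta, sidecar)
  invisible(path)
}

#' Read a session from disk
#'
#' @param path Path written by [write_session()].
#' @return The deserialized session object.
#' @export
read_session <- function(path) {
  if (!grepl("\\.rds$", path)) path <- paste0(path, ".rds")
  readRDS(path)
}
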