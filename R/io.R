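# Pose-CSV + JSON-manifest dataset format.
#
# One CSV per recording with header frame,<seg>_w,<seg>_x,<seg>_y,<seg>_z,...
# (36 quaternion columns after the frame index), plus a manifest:
#   {"recordings": [{"id", "file", "subject", "label", "frame_rate"}, ...],
#    "segments": [9 names]}

#' Write a dataset as pose-CSVs plus a JSON manifest
#'
#' @param dataset A `cav_dataset`.
#' @param path Directory to write into (created if needed).
#' @param manifest_name File name of the manifest (default "manifest.json").
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, path, manifest_name = "manifest.json") {
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop(sprintf("cannot create output directory '%s'", path), call. = FALSE)
  segments <- if (length(dataset$recordings))
    dataset$recordings[[1L]]$segments else cav_segments()
  entries <- vector("list", length(dataset$recordings))
  for (i in seq_along(dataset$recordings)) {
    rec <- dataset$recordings[[i]]
    file <- paste0(rec$recording_id, ".csv")
    # %.17g so canonical data round-trips bit-exactly
    vals <- matrix(sprintf("%.17g", rec$frames), nrow(rec$frames))
    lines <- c(paste(c("frame", colnames(rec$frames)), collapse = ","),
               paste(seq_len(nrow(vals)) - 1L,
                     apply(vals, 1L, paste, collapse = ","), sep = ","))
    writeLines(lines, file.path(path, file))
    entries[[i]] <- list(id = rec$recording_id, file = file,
                         subject = rec$subject_id, label = rec$label,
                         frame_rate = rec$frame_rate)
  }
  manifest <- list(recordings = entries, segments = as.list(segments))
  manifest_path <- file.path(path, manifest_name)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest_path)
}

#' Read a dataset from a pose-CSV + manifest directory
#'
#' Recordings are canonicalized on load; the frame rate comes from the
#' manifest. Round-trips with [write_dataset()] exactly on canonical data.
#'
#' @param manifest_path Path to the manifest JSON (or to its directory).
#' @return A `cav_dataset`.
#' @export
read_dataset <- function(manifest_path) {
  if (dir.exists(manifest_path))
    manifest_path <- file.path(manifest_path, "manifest.json")
  if (!file.exists(manifest_path))
    stop(sprintf("manifest not found: '%s'", manifest_path), call. = FALSE)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  segments <- as.character(unlist(manifest$segments))
  if (length(segments) != N_SEGMENTS)
    stop(sprintf("%s: manifest must declare exactly 9 segments, got %d",
                 manifest_path, length(segments)), call. = FALSE)
  base <- dirname(manifest_path)
  recordings <- lapply(manifest$recordings, function(e) {
    for (field in c("id", "file", "subject", "label", "frame_rate"))
      if (is.null(e[[field]]))
        stop(sprintf("%s: manifest entry missing field '%s'",
                     manifest_path, field), call. = FALSE)
    csv <- file.path(base, e$file)
    if (!file.exists(csv))
      stop(sprintf("%s: pose file '%s' not found", manifest_path, e$file),
           call. = FALSE)
    df <- utils::read.csv(csv, check.names = FALSE)
    expected <- c("frame", pose_colnames(segments))
    if (!identical(names(df), expected))
      stop(sprintf("%s: bad pose-CSV header (expected %d columns: frame + 36 quaternion components)",
                   csv, length(expected)), call. = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m))
      stop(sprintf("%s: non-numeric pose values", csv), call. = FALSE)
    if (!all(is.finite(m)))
      stop(sprintf("%s: non-finite pose values (first bad row: %d)",
                   csv, which(rowSums(!is.finite(m)) > 0)[1L]), call. = FALSE)
    cav_recording(m, frame_rate = e$frame_rate, label = e$label,
                  subject_id = e$subject, recording_id = e$id,
                  segments = segments)
  })
  cav_dataset(recordings)
}
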