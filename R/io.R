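#' A multichannel recording
#'
#' Lightweight container for one subject's multichannel series.
#'
#' @param subject subject identifier.
#' @param group group label.
#' @param fs sampling rate in Hz (> 0).
#' @param data channels x samples numeric matrix with channel row names.
#' @return A list of class `recording`.
#' @export
recording <- function(subject, group, fs, data) {
  fs <- as.numeric(fs)
  if (fs <= 0) stop_invalid("fs must be positive")
  if (!is.matrix(data)) stop_invalid("data must be a channels x samples matrix")
  if (is.null(rownames(data))) stop_invalid("data must carry channel row names")
  if (!all(is.finite(data))) stop_invalid("recording values must be finite")
  structure(list(subject = subject, group = group, fs = fs,
                 channels = rownames(data), data = data),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s (%s): %d channels x %d samples @ %g Hz\n",
              x$subject, x$group, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' Write a cohort to a plain-text directory container
#'
#' One tab-separated matrix per subject (channels in rows, first column the
#' channel name), a JSON sidecar with subject/group/fs metadata, plus
#' `layout.csv` and `truth.csv`.
#'
#' @param cohort list as returned by [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- lapply(cohort$recordings, function(r) {
    path <- file.path(dir, paste0(r$subject, ".tsv"))
    df <- data.frame(channel = r$channels, r$data, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    list(subject = r$subject, group = r$group, fs = r$fs,
         n_channels = nrow(r$data), n_samples = ncol(r$data),
         file = basename(path))
  })
  jsonlite::write_json(meta, file.path(dir, "subjects.json"), auto_unbox = TRUE)
  write.csv(cohort$layout, file.path(dir, "layout.csv"), row.names = FALSE)
  if (!is.null(cohort$truth)) {
    write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return List with `recordings`, `layout` and (if present) `truth`.
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "subjects.json")
  if (!file.exists(meta_path)) stop_invalid("no subjects.json in %s", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = FALSE)
  recordings <- lapply(meta, function(m) {
    read_recording(file.path(dir, m$file), fs = m$fs,
                   subject = m$subject, group = m$group)
  })
  layout <- tibble::as_tibble(read.csv(file.path(dir, "layout.csv")))
  truth_path <- file.path(dir, "truth.csv")
  out <- list(recordings = recordings, layout = layout)
  if (file.exists(truth_path)) out$truth <- tibble::as_tibble(read.csv(truth_path))
  out
}

#' Read a single recording from a delimited matrix
#'
#' Expects a tab- or comma-separated file with one row per channel, the
#' first column holding the channel name. The sampling rate must be given
#' (there is no place for it in a bare matrix).
#'
#' @param path file path.
#' @param fs sampling rate in Hz (required).
#' @param subject,group metadata labels.
#' @param sep field separator (default tab).
#' @return A [recording()].
#' @export
read_recording <- function(path, fs, subject = basename(path), group = NA_character_,
                           sep = "\t") {
  if (missing(fs) || is.null(fs)) stop_invalid("sampling rate fs is required")
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = FALSE,
                      colClasses = c("character", rep(NA, -1 + length(
                        strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]))),
                      check.names = FALSE),
    error = function(e) stop_invalid("cannot parse %s: %s", path, conditionMessage(e))
  )
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop_invalid("non-numeric values in %s", path)
  storage.mode(mat) <- "double"
  rownames(mat) <- df[[1]]
  colnames(mat) <- NULL
  recording(subject, group, fs, mat)
}
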