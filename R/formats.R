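# Text interchange formats: RTTM for segment-level diarization output,
# 3-column CSV for annotations, and frame-level label CSV for streams.

#' Read an RTTM file as an Annotation
#'
#' Reads `SPEAKER` records (`SPEAKER <file-id> 1 <tbeg> <tdur> <NA> <NA>
#' <speaker> <NA> <NA>`). Speaker names other than `P1`/`P2` are mapped to
#' `P1`/`P2` in order of first appearance.
#'
#' @param path path to an RTTM file.
#' @return An [Annotation-class].
#' @export
readRttm <- function(path) {
  if (!file.exists(path)) stopIO(sprintf("RTTM file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  spk <- lines[vapply(parts, function(p) identical(p[1], "SPEAKER"), logical(1))]
  parts <- parts[vapply(parts, function(p) identical(p[1], "SPEAKER"), logical(1))]
  if (length(parts) == 0L) stopValidation(sprintf("no SPEAKER records in %s", path))
  tbeg <- vapply(parts, function(p) as.numeric(p[4]), numeric(1))
  tdur <- vapply(parts, function(p) as.numeric(p[5]), numeric(1))
  name <- vapply(parts, function(p) p[8], character(1))
  if (!all(name %in% ALPHABET_SPEAKER)) {
    uniq <- unique(name)
    if (length(uniq) > 2L)
      stopValidation("RTTM contains more than two speakers; dyadic input required")
    name <- ALPHABET_SPEAKER[match(name, uniq)]
  }
  annotation(tbeg, tbeg + tdur, name)
}

#' Write an Annotation (or diarization stream) as RTTM
#'
#' For a [DiarizationStream-class], contiguous `P1`/`P2` runs are first
#' converted to segments via [streamToAnnotation()].
#'
#' @param x an [Annotation-class] or [DiarizationStream-class].
#' @param path output path.
#' @param fileId the RTTM `<file-id>` field.
#' @return `path`, invisibly.
#' @export
writeRttm <- function(x, path, fileId = "recording") {
  if (is(x, "DiarizationStream")) x <- streamToAnnotation(x@stream)
  assertThat(is(x, "Annotation"), "x must be an Annotation or DiarizationStream")
  lines <- sprintf(
    "SPEAKER %s 1 %.3f %.3f <NA> <NA> %s <NA> <NA>",
    fileId, x@startS, x@stopS - x@startS, x@speaker
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read/write annotations as 3-column CSV
#'
#' Columns `start_s`, `stop_s`, `speaker`.
#'
#' @param path CSV path.
#' @return [readAnnotationCsv()] returns an [Annotation-class];
#'   [writeAnnotationCsv()] returns `path` invisibly.
#' @export
readAnnotationCsv <- function(path) {
  if (!file.exists(path)) stopIO(sprintf("annotation CSV not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "stop_s", "speaker")
  assertThat(all(need %in% names(df)),
    "annotation CSV needs columns start_s, stop_s, speaker")
  annotation(df$start_s, df$stop_s, df$speaker)
}

#' @rdname readAnnotationCsv
#' @param ann an [Annotation-class].
#' @export
writeAnnotationCsv <- function(ann, path) {
  write.csv(utterances(ann), path, row.names = FALSE)
  invisible(path)
}

#' Read/write frame-level label streams as CSV
#'
#' Columns `frame_index` (0-based), `t_start_s`, `label`.
#'
#' @param path CSV path.
#' @param alphabet alphabet to validate against on read; inferred from the
#'   labels when `NULL`.
#' @return [readLabelCsv()] returns a [LabelStream-class];
#'   [writeLabelCsv()] returns `path` invisibly.
#' @export
readLabelCsv <- function(path, alphabet = NULL) {
  if (!file.exists(path)) stopIO(sprintf("label CSV not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_index", "t_start_s", "label")
  assertThat(all(need %in% names(df)),
    "label CSV needs columns frame_index, t_start_s, label")
  df <- df[order(df$frame_index), ]
  fr <- if (nrow(df) > 1L) 1 / (df$t_start_s[2] - df$t_start_s[1]) else 10
  if (is.null(alphabet)) alphabet <- sort(unique(df$label))
  labelStream(df$label, alphabet, fr)
}

#' @rdname readLabelCsv
#' @param stream a [LabelStream-class].
#' @export
writeLabelCsv <- function(stream, path) {
  n <- length(stream@labels)
  df <- data.frame(
    frame_index = seq_len(n) - 1L,
    t_start_s = (seq_len(n) - 1L) / stream@frameRate,
    label = stream@labels
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
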