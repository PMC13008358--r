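#' Read a transcript annotation table
#'
#' Reads the five-column tab-separated annotation dialect used throughout the
#' package: `transcript_id`, `gene_id`, `utr5_len`, `cds_len`, `utr3_len`.
#' Only segment lengths are consumed downstream; all coordinates in the
#' package are transcript-space, 0-based, half-open, with the 5'UTR first.
#'
#' @param path Path to a tab-separated annotation file with a header row.
#' @return A tibble with columns `transcript_id`, `gene_id`, `utr5_len`,
#'   `cds_len`, `utr3_len` and the derived `total_len`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("transcript_id\tgene_id\tutr5_len\tcds_len\tutr3_len",
#'              "tx1\tg1\t100\t900\t400"), tf)
#' read_annotation(tf)
read_annotation <- function(path) {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  # parse problems are surfaced as errors below, so silence readr's warning
  ann <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(
      transcript_id = readr::col_character(),
      gene_id = readr::col_character(),
      utr5_len = readr::col_double(),
      cds_len = readr::col_double(),
      utr3_len = readr::col_double()
    ),
    progress = FALSE
  ))
  prob <- readr::problems(ann)
  if (nrow(prob) > 0) {
    stop("malformed annotation line ", prob$row[1], " in ", path, call. = FALSE)
  }
  validate_annotation(ann)
}

#' Validate an annotation tibble
#'
#' Enforces the invariants every annotation must satisfy: unique transcript
#' ids, non-negative UTR lengths, strictly positive CDS length.
#'
#' @param annotation A data frame with the annotation columns of
#'   [read_annotation()].
#' @return The validated annotation as a tibble with `total_len` added.
#' @export
validate_annotation <- function(annotation) {
  ann <- tibble::as_tibble(annotation)
  required <- c("transcript_id", "gene_id", "utr5_len", "cds_len", "utr3_len")
  missing <- setdiff(required, names(ann))
  if (length(missing) > 0) {
    stop("annotation lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dup <- ann$transcript_id[duplicated(ann$transcript_id)]
  if (length(dup) > 0) {
    stop("duplicated transcript_id in annotation: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad_len <- !is.finite(ann$utr5_len) | !is.finite(ann$cds_len) |
    !is.finite(ann$utr3_len) | ann$utr5_len < 0 | ann$utr3_len < 0
  if (any(bad_len)) {
    stop("negative or non-finite segment length for transcript(s): ",
         paste(ann$transcript_id[bad_len], collapse = ", "), call. = FALSE)
  }
  if (any(ann$cds_len <= 0)) {
    stop("cds_len must be positive; offending transcript(s): ",
         paste(ann$transcript_id[ann$cds_len <= 0], collapse = ", "),
         call. = FALSE)
  }
  ann |>
    dplyr::mutate(dplyr::across(c("utr5_len", "cds_len", "utr3_len"),
                                as.integer)) |>
    dplyr::mutate(total_len = .data$utr5_len + .data$cds_len + .data$utr3_len)
}

#' Write an annotation table
#'
#' @param annotation Annotation tibble (see [read_annotation()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  ann <- validate_annotation(annotation)
  readr::write_tsv(
    ann[, c("transcript_id", "gene_id", "utr5_len", "cds_len", "utr3_len")],
    path, progress = FALSE
  )
  invisible(path)
}

#' Number of coverage windows per transcript
#'
#' @param annotation Annotation tibble.
#' @param window_size Window width in nt.
#' @return Named integer vector of window counts, `ceiling(total_len / window_size)`.
#' @export
n_windows <- function(annotation, window_size) {
  stopifnot(window_size >= 1)
  ann <- validate_annotation(annotation)
  stats::setNames(as.integer(ceiling(ann$total_len / window_size)),
                  ann$transcript_id)
}
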