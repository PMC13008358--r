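#' Write peaks to a BED6+3 file
#'
#' One line per peak: `transcript_id`, `start`, `end`, `name`, `score`
#' (fold enrichment rounded to 4 digits), `"."` strand, then `pvalue`,
#' `qvalue`, and the summit offset relative to `start`. Coordinates are
#' transcript-space, 0-based, half-open. A header line (prefixed `#`) names
#' the columns so the file round-trips with [read_peaks()].
#'
#' @param peaks Peak tibble with columns `transcript_id`, `start`, `end`,
#'   `summit`, `acrip_count`, `input_count`, `fe`, `pvalue`, `qvalue`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  peaks <- tibble::as_tibble(peaks)
  header <- paste0("#", paste(
    c("chrom", "chromStart", "chromEnd", "name", "score", "strand",
      "pvalue", "qvalue", "summitOffset"), collapse = "\t"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(peaks) == 0) return(invisible(path))
  check_peak_frame(peaks)
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%s\t.\t%s\t%s\t%d",
    peaks$transcript_id, as.integer(peaks$start), as.integer(peaks$end),
    sprintf("peak_%d", seq_len(nrow(peaks))),
    formatC(round(peaks$fe, 4), format = "fg", digits = 10),
    format_pval(peaks$pvalue), format_pval(peaks$qvalue),
    as.integer(peaks$summit - peaks$start)
  )
  writeLines(lines, con)
  invisible(path)
}

#' Read peaks from a BED6+3 file written by [write_peaks()]
#'
#' @param path Path to the peaks file.
#' @return A peak tibble with columns `transcript_id`, `start`, `end`,
#'   `summit`, `fe`, `pvalue`, `qvalue`.
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop("peak file not found: ", path, call. = FALSE)
  cols <- c("transcript_id", "start", "end", "name", "fe", "strand",
            "pvalue", "qvalue", "summit_offset")
  body <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  if (length(body) == 0) {
    return(tibble::tibble(
      transcript_id = character(), start = integer(), end = integer(),
      summit = integer(), fe = numeric(), pvalue = numeric(),
      qvalue = numeric()
    ))
  }
  raw <- utils::read.table(
    path, sep = "\t", comment.char = "#", col.names = cols,
    colClasses = c("character", "integer", "integer", "character", "numeric",
                   "character", "numeric", "numeric", "integer")
  ) |> tibble::as_tibble()
  if (nrow(raw) == 0) {
    return(tibble::tibble(
      transcript_id = character(), start = integer(), end = integer(),
      summit = integer(), fe = numeric(), pvalue = numeric(),
      qvalue = numeric()
    ))
  }
  raw |>
    dplyr::transmute(
      transcript_id = .data$transcript_id,
      start = .data$start, end = .data$end,
      summit = .data$start + .data$summit_offset,
      fe = .data$fe, pvalue = .data$pvalue, qvalue = .data$qvalue
    )
}

format_pval <- function(p) {
  formatC(p, format = "e", digits = 10)
}

check_peak_frame <- function(peaks) {
  stopifnot(all(c("transcript_id", "start", "end", "summit", "fe",
                  "pvalue", "qvalue") %in% names(peaks)))
  if (any(peaks$start >= peaks$end)) {
    stop("peak with start >= end", call. = FALSE)
  }
  if (any(peaks$summit < peaks$start | peaks$summit >= peaks$end)) {
    stop("peak summit outside [start, end)", call. = FALSE)
  }
  invisible(peaks)
}
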