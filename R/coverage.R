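#' Construct a coverage track
#'
#' A coverage track holds per-window read counts for one sequencing library
#' (acRIP or input) over a transcript annotation, together with library
#' metadata. Windows are 0-based indices of fixed width over each transcript.
#'
#' @param counts Tibble with columns `transcript_id`, `window`, `count`
#'   (dense: one row per window of every transcript).
#' @param window_size Window width in nt.
#' @param library_id Library identifier.
#' @param role `"acRIP"` or `"input"`.
#' @param condition Experimental condition label (e.g. `"control"`, `"memory"`).
#' @param timepoint One of `"day1"`, `"day6"`, `"day20"`, `"na"`.
#' @param replicate Positive integer replicate index.
#' @param library_size Total mapped reads; defaults to the sum of counts.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(counts, window_size, library_id = "lib",
                           role = c("acRIP", "input"), condition = "na",
                           timepoint = c("na", "day1", "day6", "day20"),
                           replicate = 1L, library_size = NULL) {
  role <- match.arg(role)
  timepoint <- match.arg(timepoint)
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("transcript_id", "window", "count") %in% names(counts)))
  if (any(counts$count < 0)) {
    stop("negative counts in coverage track", call. = FALSE)
  }
  total <- sum(counts$count)
  if (is.null(library_size)) library_size <- total
  if (library_size < total) {
    stop("library_size (", library_size, ") smaller than total counts (",
         total, ")", call. = FALSE)
  }
  if (library_size <= 0) {
    stop("coverage track with library_size 0 rejected", call. = FALSE)
  }
  structure(
    list(
      library_id = library_id, role = role, condition = condition,
      timepoint = timepoint, replicate = as.integer(replicate),
      window_size = as.integer(window_size),
      library_size = as.numeric(library_size),
      counts = counts[, c("transcript_id", "window", "count")]
    ),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "<coverage_track %s> role=%s condition=%s timepoint=%s rep=%d\n",
    x$library_id, x$role, x$condition, x$timepoint, x$replicate
  ))
  cat(sprintf("  %d transcripts, window %d nt, library size %s\n",
              dplyr::n_distinct(x$counts$transcript_id), x$window_size,
              format(x$library_size, big.mark = ",")))
  invisible(x)
}

#' Read a per-window count table into a coverage track
#'
#' The file is tab-separated with header `transcript_id`, `window_index`,
#' `count`. Windows absent from the file are padded with zero so every
#' transcript carries `ceiling(total_len / window_size)` windows.
#'
#' @param path Path to the TSV count table.
#' @param annotation Annotation tibble defining the transcripts and lengths.
#' @param window_size Window width in nt.
#' @param ... Metadata passed on to [coverage_track()] (`library_id`, `role`,
#'   `condition`, `timepoint`, `replicate`, `library_size`).
#' @return A `coverage_track`.
#' @export
read_counts <- function(path, annotation, window_size, ...) {
  if (!file.exists(path)) stop("count file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      transcript_id = readr::col_character(),
      window_index = readr::col_double(),
      count = readr::col_double()
    ),
    progress = FALSE
  )
  if (any(raw$count < 0)) {
    stop("negative count in ", path, call. = FALSE)
  }
  nw <- n_windows(annotation, window_size)
  unknown <- setdiff(raw$transcript_id, names(nw))
  if (length(unknown) > 0) {
    stop("count table references transcripts absent from annotation: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  out_of_bounds <- raw$window_index < 0 |
    raw$window_index >= nw[raw$transcript_id]
  if (any(out_of_bounds)) {
    stop("window_index beyond transcript length for: ",
         paste(utils::head(unique(raw$transcript_id[out_of_bounds]), 5),
               collapse = ", "), call. = FALSE)
  }
  dense <- dense_windows(names(nw), nw) |>
    dplyr::left_join(
      raw |> dplyr::rename(window = "window_index"),
      by = c("transcript_id", "window")
    ) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0))
  coverage_track(dense, window_size = window_size, ...)
}

#' Write a coverage track's counts as a TSV count table
#'
#' Only non-zero windows are written; [read_counts()] restores the zero
#' padding, so write/read round-trips the counts exactly.
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  track$counts |>
    dplyr::filter(.data$count > 0) |>
    dplyr::rename(window_index = "window") |>
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}

# dense (transcript_id, window) grid for a set of transcripts
dense_windows <- function(transcript_ids, nw) {
  tibble::tibble(
    transcript_id = rep(transcript_ids, times = nw[transcript_ids]),
    window = unlist(lapply(nw[transcript_ids], function(k) seq_len(k) - 1L),
                    use.names = FALSE)
  )
}
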