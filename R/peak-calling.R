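#' Peak caller parameters
#'
#' Defaults reproduce the published screen for a positive ac4C peak:
#' fold enrichment above 2 and Benjamini-Hochberg adjusted p below 0.05.
#'
#' @param min_fe Minimum fold enrichment for a significant window/peak.
#' @param max_q Maximum BH-adjusted p-value.
#' @param input_pseudocount Pseudocount added to the input count when
#'   estimating the background rate, avoiding a zero Poisson mean and
#'   infinite fold enrichment.
#' @param merge_gap Maximum number of non-significant windows allowed inside
#'   a merged peak.
#' @param normalize Scale counts by library size when computing fold
#'   enrichment (`FALSE` gives the raw acRIP/input ratio).
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(min_fe = 2, max_q = 0.05, input_pseudocount = 1,
                          merge_gap = 1, normalize = TRUE) {
  stopifnot(min_fe > 0, max_q > 0, max_q < 1, input_pseudocount >= 0,
            merge_gap >= 0)
  structure(
    list(min_fe = min_fe, max_q = max_q,
         input_pseudocount = input_pseudocount,
         merge_gap = as.integer(merge_gap), normalize = isTRUE(normalize)),
    class = "caller_params"
  )
}

#' Per-window Poisson enrichment test
#'
#' For each coverage window, the expected acRIP background is
#' `lambda = (input_count + pseudocount) * (acRIP library size / input
#' library size)` and the p-value is the upper-tail Poisson probability
#' `P(X >= acrip_count | lambda)`. Fold enrichment is the library-size
#' normalised acRIP/input ratio with the same pseudocount on the input.
#'
#' @param acrip,input `coverage_track`s on the same annotation and window
#'   grid.
#' @param params A [caller_params()].
#' @return A tibble with one row per window: `transcript_id`, `window`,
#'   `acrip_count`, `input_count`, `fe`, `pvalue`.
#' @export
window_enrichment <- function(acrip, input, params = caller_params()) {
  stopifnot(inherits(acrip, "coverage_track"),
            inherits(input, "coverage_track"),
            inherits(params, "caller_params"))
  if (acrip$window_size != input$window_size) {
    stop("acRIP and input tracks have different window sizes", call. = FALSE)
  }
  if (acrip$library_size <= 0 || input$library_size <= 0) {
    stop("library sizes must be positive", call. = FALSE)
  }
  a <- acrip$counts
  b <- input$counts
  if (nrow(a) != nrow(b) ||
      !identical(a$transcript_id, b$transcript_id) ||
      !identical(a$window, b$window)) {
    stop("acRIP and input tracks are on mismatched window grids",
         call. = FALSE)
  }
  ratio <- if (params$normalize) acrip$library_size / input$library_size else 1
  bg <- b$count + params$input_pseudocount
  lambda <- bg * ratio
  tibble::tibble(
    transcript_id = a$transcript_id,
    window = a$window,
    acrip_count = a$count,
    input_count = b$count,
    fe = a$count / lambda,
    pvalue = stats::ppois(a$count - 1, lambda, lower.tail = FALSE)
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (via [stats::p.adjust()]), with input
#' validation. Order-preserving and monotone.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) stop("empty p-value vector", call. = FALSE)
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Call enriched peaks from paired acRIP/input tracks
#'
#' Windows passing the screen (`q < max_q` and `fe > min_fe`) are merged
#' into peaks when separated by at most `merge_gap` non-significant windows.
#' Peak counts are summed over member windows and the peak fold enrichment
#' is recomputed from the summed counts; the peak p-/q-value is the minimum
#' over member windows; the summit is the start of the member window with
#' the maximal acRIP count (leftmost on ties). Returned peaks all satisfy
#' the screen.
#'
#' @inheritParams window_enrichment
#' @param annotation Optional annotation tibble used to clip peak ends to
#'   transcript length.
#' @return A peak tibble: `transcript_id`, `start`, `end`, `summit`,
#'   `acrip_count`, `input_count`, `fe`, `pvalue`, `qvalue`.
#' @export
call_peaks <- function(acrip, input, params = caller_params(),
                       annotation = NULL) {
  wins <- window_enrichment(acrip, input, params)
  wins$qvalue <- bh_adjust(wins$pvalue)
  wins$sig <- wins$qvalue < params$max_q & wins$fe > params$min_fe
  ws <- acrip$window_size
  ratio <- if (params$normalize) acrip$library_size / input$library_size else 1

  empty <- tibble::tibble(
    transcript_id = character(), start = integer(), end = integer(),
    summit = integer(), acrip_count = numeric(), input_count = numeric(),
    fe = numeric(), pvalue = numeric(), qvalue = numeric()
  )
  if (!any(wins$sig)) return(empty)

  total_len <- NULL
  if (!is.null(annotation)) {
    ann <- validate_annotation(annotation)
    total_len <- stats::setNames(ann$total_len, ann$transcript_id)
  }

  peaks <- merge_significant_windows(wins, params)
  if (nrow(peaks) == 0) return(empty)

  peaks <- peaks |>
    dplyr::mutate(
      start = .data$first_window * ws,
      end = (.data$last_window + 1L) * ws,
      summit = .data$summit_window * ws,
      fe = .data$acrip_count / ((.data$input_count + params$input_pseudocount *
                                   .data$n_windows) * ratio)
    )
  if (!is.null(total_len)) {
    peaks$end <- pmin(peaks$end, total_len[peaks$transcript_id])
  }
  peaks |>
    dplyr::filter(.data$fe > params$min_fe, .data$qvalue < params$max_q) |>
    dplyr::transmute(
      transcript_id = .data$transcript_id,
      start = as.integer(.data$start), end = as.integer(.data$end),
      summit = as.integer(.data$summit),
      acrip_count = .data$acrip_count, input_count = .data$input_count,
      fe = .data$fe, pvalue = .data$pvalue, qvalue = .data$qvalue
    )
}

# merge significant windows into peak spans, vectorised over the whole
# window table; `wins` is dense and ordered (transcript, window ascending)
merge_significant_windows <- function(wins, params) {
  sig_idx <- which(wins$sig)
  if (length(sig_idx) == 0) return(tibble::tibble())
  tx <- wins$transcript_id[sig_idx]
  w <- wins$window[sig_idx]
  new_cluster <- c(TRUE, tx[-1] != tx[-length(tx)] |
                     diff(w) > params$merge_gap + 1L)
  cluster <- cumsum(new_cluster)
  bounds <- tibble::tibble(
    cluster = cluster, tx = tx, w = w,
    row = sig_idx
  ) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      transcript_id = .data$tx[1],
      first_window = min(.data$w), last_window = max(.data$w),
      first_row = min(.data$row), last_row = max(.data$row),
      .groups = "drop"
    )
  # dense ordering makes span rows contiguous: row of (tx, w+1) = row + 1
  lens <- bounds$last_row - bounds$first_row + 1L
  member <- sequence(lens, from = bounds$first_row)
  span <- wins[member, c("window", "acrip_count", "input_count",
                         "pvalue", "qvalue")]
  span$cluster <- rep(bounds$cluster, lens)
  agg <- span |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      summit_window = .data$window[which.max(.data$acrip_count)],
      n_windows = dplyr::n(),
      acrip_count = sum(.data$acrip_count),
      input_count = sum(.data$input_count),
      pvalue = min(.data$pvalue), qvalue = min(.data$qvalue),
      .groups = "drop"
    )
  dplyr::inner_join(bounds[, c("cluster", "transcript_id", "first_window",
                               "last_window")],
                    agg, by = "cluster") |>
    dplyr::select(-"cluster")
}

#' Consensus peaks across biological replicates
#'
#' Peaks from different replicates on the same transcript that overlap by at
#' least 1 nt are clustered (single linkage); a cluster's interval is the
#' union of its members, its support the number of distinct replicates
#' contributing, and its fold enrichment the mean of member-peak values.
#' Only clusters supported by at least `min_support` replicates are
#' returned, the published reliability rule being 2 of 3.
#'
#' @param replicate_peaks List of peak tibbles, one per biological replicate.
#' @param min_support Minimum number of distinct supporting replicates.
#' @return A consensus tibble: `transcript_id`, `start`, `end`, `support`,
#'   `n_peaks`, `mean_fe`.
#' @export
consensus_peaks <- function(replicate_peaks, min_support = 2) {
  stopifnot(is.list(replicate_peaks), length(replicate_peaks) >= 1)
  if (min_support > length(replicate_peaks)) {
    stop("min_support (", min_support, ") exceeds the number of replicate ",
         "peak sets (", length(replicate_peaks), ")", call. = FALSE)
  }
  all_peaks <- purrr::imap_dfr(
    replicate_peaks,
    ~ dplyr::mutate(tibble::as_tibble(.x), .replicate = .y)
  )
  empty <- tibble::tibble(
    transcript_id = character(), start = integer(), end = integer(),
    support = integer(), n_peaks = integer(), mean_fe = numeric()
  )
  if (nrow(all_peaks) == 0) return(empty)
  # offset each transcript onto a disjoint stretch of one coordinate axis
  # so single-linkage clustering runs in one IRanges pass
  tx_levels <- unique(all_peaks$transcript_id)
  span <- max(all_peaks$end) + 2
  offset <- span * (match(all_peaks$transcript_id, tx_levels) - 1)
  ir <- IRanges::IRanges(start = all_peaks$start + offset + 1,
                         end = all_peaks$end + offset)
  merged <- IRanges::reduce(ir, min.gapwidth = 0L)
  hit <- IRanges::findOverlaps(ir, merged, minoverlap = 1L)
  cl <- integer(length(ir))
  cl[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
  out <- all_peaks |>
    dplyr::mutate(cluster = cl) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      transcript_id = .data$transcript_id[1],
      start = min(.data$start), end = max(.data$end),
      support = dplyr::n_distinct(.data$.replicate),
      n_peaks = dplyr::n(),
      mean_fe = mean(.data$fe),
      .groups = "drop"
    ) |>
    dplyr::select(-"cluster")
  out |>
    dplyr::filter(.data$support >= min_support) |>
    dplyr::arrange(.data$transcript_id, .data$start) |>
    dplyr::mutate(start = as.integer(.data$start), end = as.integer(.data$end))
}
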