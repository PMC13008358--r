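#' Transcripts-per-million expression quantification
#'
#' `rate_i = count_i / length_i`; `tpm_i = 1e6 * rate_i / sum(rates)`. A
#' transcript is called detected when its TPM exceeds 1; `log2_tpm` is
#' defined only for positive TPM.
#'
#' @param counts Tibble with columns `transcript_id` and `count`
#'   (per-transcript read counts).
#' @param annotation Annotation tibble supplying transcript lengths.
#' @return A tibble: `transcript_id`, `tpm`, `log2_tpm`, `detected`.
#' @export
compute_tpm <- function(counts, annotation) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("transcript_id", "count") %in% names(counts)))
  ann <- validate_annotation(annotation)
  j <- match(counts$transcript_id, ann$transcript_id)
  if (anyNA(j)) {
    stop("counts reference transcripts absent from annotation: ",
         paste(utils::head(counts$transcript_id[is.na(j)], 5),
               collapse = ", "), call. = FALSE)
  }
  if (any(counts$count < 0)) stop("negative counts", call. = FALSE)
  rate <- counts$count / ann$total_len[j]
  if (sum(rate) == 0) {
    stop("all counts are zero; TPM undefined", call. = FALSE)
  }
  tpm <- 1e6 * rate / sum(rate)
  tibble::tibble(
    transcript_id = counts$transcript_id,
    tpm = tpm,
    log2_tpm = ifelse(tpm > 0, log2(tpm), NA_real_),
    detected = tpm > 1
  )
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided two-sample KS statistic `D = sup |Fx - Fy|` with asymptotic
#' p-value (exact below a combined n of 50), as used for comparing
#' cumulative fold-enrichment distributions between conditions.
#'
#' @param x,y Numeric samples.
#' @return A one-row tibble: `D`, `p`.
#' @export
ks_compare <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  exact <- (length(x) + length(y)) < 50
  fit <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  tibble::tibble(D = unname(fit$statistic), p = fit$p.value)
}

#' Quartile summary of a sample
#'
#' Quartiles use linear interpolation of order statistics (type-7, the
#' convention behind quartile boxplots drawn with both median and mean).
#'
#' @param x Non-empty numeric vector.
#' @return A one-row tibble: `min`, `q1`, `median`, `mean`, `q3`, `max`.
#' @export
quartile_summary <- function(x) {
  stopifnot(length(x) > 0)
  q <- stats::quantile(x, probs = c(0, 0.25, 0.5, 0.75, 1), type = 7,
                       names = FALSE)
  tibble::tibble(min = q[1], q1 = q[2], median = q[3], mean = mean(x),
                 q3 = q[4], max = q[5])
}

#' Empirical cumulative distribution curve
#'
#' Right-continuous empirical CDF sampled at the sorted unique sample values
#' (or at a supplied grid), for plotting cumulative fold-enrichment curves.
#'
#' @param x Non-empty numeric vector.
#' @param grid Optional evaluation grid.
#' @return A tibble: `value`, `cdf`.
#' @export
cumulative_curve <- function(x, grid = NULL) {
  stopifnot(length(x) > 0)
  if (is.null(grid)) grid <- sort(unique(x))
  f <- stats::ecdf(x)
  tibble::tibble(value = grid, cdf = f(grid))
}
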