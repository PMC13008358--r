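#' Assign peaks to transcript regions by summit position
#'
#' The summit is compared with the cumulative 5'UTR / CDS / 3'UTR boundaries
#' of its transcript; a summit exactly on a boundary belongs to the
#' downstream segment (half-open convention). Assignment depends only on the
#' summit, never on peak width.
#'
#' @param peaks Peak tibble with `transcript_id` and `summit` columns.
#' @param annotation Annotation tibble covering every peak's transcript.
#' @return The peak tibble with a `region` factor column
#'   (`UTR5`/`CDS`/`UTR3`) added.
#' @export
assign_region <- function(peaks, annotation) {
  ann <- validate_annotation(annotation)
  peaks <- tibble::as_tibble(peaks)
  stopifnot(all(c("transcript_id", "summit") %in% names(peaks)))
  missing <- setdiff(peaks$transcript_id, ann$transcript_id)
  if (length(missing) > 0) {
    stop("peaks on transcripts absent from annotation: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  j <- match(peaks$transcript_id, ann$transcript_id)
  u5 <- ann$utr5_len[j]
  cds_end <- u5 + ann$cds_len[j]
  total <- ann$total_len[j]
  if (any(peaks$summit < 0 | peaks$summit >= total)) {
    stop("summit outside transcript bounds", call. = FALSE)
  }
  region <- ifelse(peaks$summit < u5, "UTR5",
                   ifelse(peaks$summit < cds_end, "CDS", "UTR3"))
  peaks$region <- factor(region, levels = c("UTR5", "CDS", "UTR3"))
  peaks
}

#' Metagene profile of peak summits
#'
#' Each summit is mapped to a fractional position within its region
#' (`(summit - region start) / region length`) and binned into
#' `bins_per_region` bins per segment; bin counts are normalised to a
#' density summing to 1 (all-zero when there are no peaks).
#'
#' @inheritParams assign_region
#' @param bins_per_region Bins per segment.
#' @return A tibble of class `ac4c_metagene` with one row per bin:
#'   `region`, `bin` (1..3*bins_per_region across the transcript), and
#'   `density`.
#' @export
metagene <- function(peaks, annotation, bins_per_region = 30) {
  stopifnot(bins_per_region >= 1)
  ann <- validate_annotation(annotation)
  b <- as.integer(bins_per_region)
  grid <- tibble::tibble(
    region = factor(rep(c("UTR5", "CDS", "UTR3"), each = b),
                    levels = c("UTR5", "CDS", "UTR3")),
    bin = seq_len(3L * b)
  )
  peaks <- tibble::as_tibble(peaks)
  if (nrow(peaks) == 0) {
    out <- dplyr::mutate(grid, density = 0)
    class(out) <- c("ac4c_metagene", class(out))
    return(out)
  }
  px <- assign_region(peaks, ann)
  j <- match(px$transcript_id, ann$transcript_id)
  reg_start <- ifelse(px$region == "UTR5", 0L,
               ifelse(px$region == "CDS", ann$utr5_len[j],
                      ann$utr5_len[j] + ann$cds_len[j]))
  reg_len <- ifelse(px$region == "UTR5", ann$utr5_len[j],
             ifelse(px$region == "CDS", ann$cds_len[j], ann$utr3_len[j]))
  frac <- (px$summit - reg_start) / reg_len
  local_bin <- pmin(b, as.integer(floor(frac * b)) + 1L)
  global_bin <- (as.integer(px$region) - 1L) * b + local_bin
  counts <- tabulate(global_bin, nbins = 3L * b)
  out <- dplyr::mutate(grid, density = counts / sum(counts))
  class(out) <- c("ac4c_metagene", class(out))
  out
}

#' Peaks-per-transcript summary
#'
#' Mean and standard error of the number of peaks over acetylated
#' transcripts (those with at least one peak), plus the acetylated fraction
#' of the detected transcript universe.
#'
#' @param peaks Peak or consensus-peak tibble with `transcript_id`.
#' @param annotation Annotation tibble; its transcripts define the detected
#'   universe unless `detected` is given.
#' @param detected Optional character vector of detected transcript ids.
#' @return A one-row tibble: `n_detected`, `n_acetylated`,
#'   `fraction_acetylated`, `mean_peaks`, `sem_peaks` (mean/SEM are `NA`
#'   when nothing is acetylated).
#' @export
peaks_per_transcript <- function(peaks, annotation, detected = NULL) {
  ann <- validate_annotation(annotation)
  if (is.null(detected)) detected <- ann$transcript_id
  stopifnot(length(detected) > 0)
  peaks <- tibble::as_tibble(peaks)
  counts <- peaks |>
    dplyr::filter(.data$transcript_id %in% detected) |>
    dplyr::count(.data$transcript_id)
  n_ace <- nrow(counts)
  tibble::tibble(
    n_detected = length(unique(detected)),
    n_acetylated = n_ace,
    fraction_acetylated = n_ace / length(unique(detected)),
    mean_peaks = if (n_ace > 0) mean(counts$n) else NA_real_,
    sem_peaks = if (n_ace > 1) stats::sd(counts$n) / sqrt(n_ace) else NA_real_
  )
}

#' Chi-square test of summit distribution over regions
#'
#' Observed summit counts per region are tested against expectation
#' proportional to the aggregate region lengths of the transcripts carrying
#' peaks. Regions absent from all such transcripts are collapsed out of the
#' table.
#'
#' @inheritParams assign_region
#' @return A one-row tibble: `chi2`, `df`, `p`, `status` (`"ok"` or
#'   `"skipped"` when fewer than two regions remain).
#' @export
region_chisq <- function(peaks, annotation) {
  peaks <- tibble::as_tibble(peaks)
  if (nrow(peaks) < 2) stop("need at least 2 peaks", call. = FALSE)
  ann <- validate_annotation(annotation)
  px <- assign_region(peaks, ann)
  tx <- ann[ann$transcript_id %in% unique(px$transcript_id), ]
  lens <- c(UTR5 = sum(tx$utr5_len), CDS = sum(tx$cds_len),
            UTR3 = sum(tx$utr3_len))
  obs <- table(px$region)[names(lens)]
  keep <- lens > 0
  if (sum(keep) < 2) {
    return(tibble::tibble(chi2 = NA_real_, df = NA_integer_, p = NA_real_,
                          status = "skipped"))
  }
  obs <- as.numeric(obs[keep])
  props <- lens[keep] / sum(lens[keep])
  fit <- suppressWarnings(stats::chisq.test(obs, p = props))
  tibble::tibble(
    chi2 = unname(fit$statistic),
    df = as.integer(unname(fit$parameter)),
    p = fit$p.value,
    status = "ok"
  )
}
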