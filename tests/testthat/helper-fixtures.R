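# small in-code fixtures shared across test files

toy_annotation <- function() {
  tibble::tibble(
    transcript_id = c("tx1", "tx2", "tx3"),
    gene_id = c("g1", "g2", "g3"),
    utr5_len = c(100L, 0L, 200L),
    cds_len = c(900L, 600L, 300L),
    utr3_len = c(400L, 150L, 0L)
  )
}

# build a coverage track from a named list of per-window count vectors
toy_track <- function(counts_by_tx, window_size = 50, ...) {
  counts <- tibble::tibble(
    transcript_id = rep(names(counts_by_tx),
                        lengths(counts_by_tx)),
    window = unlist(lapply(counts_by_tx, function(v) seq_along(v) - 1L),
                    use.names = FALSE),
    count = unlist(counts_by_tx, use.names = FALSE)
  )
  coverage_track(counts, window_size = window_size, ...)
}

random_peak_set <- function(n, transcript_ids = c("tx1", "tx2", "tx3"),
                            max_len = 1000) {
  start <- sample.int(max_len - 200, n, replace = TRUE)
  width <- sample(50:200, n, replace = TRUE)
  tibble::tibble(
    transcript_id = sample(transcript_ids, n, replace = TRUE),
    start = start,
    end = start + width,
    summit = start + sample.int(50, n, replace = TRUE) - 1L,
    acrip_count = sample.int(500, n, replace = TRUE),
    input_count = sample.int(100, n, replace = TRUE),
    fe = round(stats::runif(n, 0.1, 20), 4),
    pvalue = stats::runif(n, 1e-12, 0.04),
    qvalue = NA_real_
  ) |>
    dplyr::mutate(qvalue = pmin(1, pvalue * 2))
}
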