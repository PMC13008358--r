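#' Transcript-level cumulative fold enrichment
#'
#' The acetylation level of a transcript is summarised as the arithmetic sum
#' of the fold-enrichment values of all its peaks across the 5'UTR, CDS and
#' 3'UTR. Every transcript in the annotation receives a record; transcripts
#' without peaks get an explicit zero.
#'
#' @param peaks Peak tibble (`fe` column) or consensus tibble (`mean_fe`).
#' @param annotation Annotation tibble defining the transcript universe.
#' @return A tibble: `transcript_id`, `n_peaks`, `fe_sum`.
#' @export
transcript_fe <- function(peaks, annotation) {
  ann <- validate_annotation(annotation)
  peaks <- tibble::as_tibble(peaks)
  fe_col <- if ("fe" %in% names(peaks)) "fe"
            else if ("mean_fe" %in% names(peaks)) "mean_fe"
            else stop("peaks need an `fe` or `mean_fe` column", call. = FALSE)
  unknown <- setdiff(peaks$transcript_id, ann$transcript_id)
  if (length(unknown) > 0) {
    stop("peaks reference transcripts absent from annotation: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  agg <- peaks |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(n_peaks = dplyr::n(),
                     fe_sum = sum(.data[[fe_col]]), .groups = "drop")
  tibble::tibble(transcript_id = ann$transcript_id) |>
    dplyr::left_join(agg, by = "transcript_id") |>
    dplyr::mutate(
      n_peaks = dplyr::coalesce(.data$n_peaks, 0L),
      fe_sum = dplyr::coalesce(.data$fe_sum, 0)
    )
}

#' Pseudocount fold change of transcript acetylation
#'
#' `fc = (fe_case + 1) / (fe_ref + 1)`; the added 1 prevents a zero
#' denominator, so the ratio is always finite and positive. The transcript
#' universe is the union of both sides, a missing side contributing fe 0.
#'
#' @param case,ref Tibbles from [transcript_fe()] (columns `transcript_id`,
#'   `fe_sum`).
#' @return A tibble: `transcript_id`, `fe_case`, `fe_ref`, `fc`.
#' @export
fold_change <- function(case, ref) {
  case <- tibble::as_tibble(case)
  ref <- tibble::as_tibble(ref)
  stopifnot(all(c("transcript_id", "fe_sum") %in% names(case)),
            all(c("transcript_id", "fe_sum") %in% names(ref)))
  tibble::tibble(
    transcript_id = union(case$transcript_id, ref$transcript_id)
  ) |>
    dplyr::left_join(dplyr::select(case, "transcript_id", fe_case = "fe_sum"),
                     by = "transcript_id") |>
    dplyr::left_join(dplyr::select(ref, "transcript_id", fe_ref = "fe_sum"),
                     by = "transcript_id") |>
    dplyr::mutate(
      fe_case = dplyr::coalesce(.data$fe_case, 0),
      fe_ref = dplyr::coalesce(.data$fe_ref, 0),
      fc = (.data$fe_case + 1) / (.data$fe_ref + 1)
    )
}

#' Classify memory-induced synaptic ac4C (MISA) transcripts
#'
#' A transcript is MISA when its acetylation fold change (memory vs control)
#' exceeds the cutoff at day 6 but not at day 1 or day 20: the upregulation
#' must be specific to the memory time point. The day-6 comparison is strict
#' (`fc > cutoff`), days 1/20 non-strict (`fc <= cutoff`).
#'
#' @param fc_d1,fc_d6,fc_d20 Fold-change tibbles from [fold_change()] for
#'   the three day-wise memory-vs-control comparisons.
#' @param cutoff Upregulation cutoff (default 2).
#' @param missing How to treat transcripts absent from a day's comparison:
#'   `"neutral"` assigns fc = 1 (no evidence of change), `"strict"` drops
#'   them.
#' @return A tibble of class `misa_call`: `transcript_id`, `fc_d1`, `fc_d6`,
#'   `fc_d20`, `is_misa`.
#' @export
classify_misa <- function(fc_d1, fc_d6, fc_d20, cutoff = 2,
                          missing = c("neutral", "strict")) {
  missing <- match.arg(missing)
  stopifnot(cutoff > 0)
  days <- list(fc_d1 = fc_d1, fc_d6 = fc_d6, fc_d20 = fc_d20)
  days <- purrr::map(days, function(d) {
    d <- tibble::as_tibble(d)
    stopifnot(all(c("transcript_id", "fc") %in% names(d)))
    d[, c("transcript_id", "fc")]
  })
  ids <- if (missing == "strict") {
    Reduce(intersect, purrr::map(days, "transcript_id"))
  } else {
    Reduce(union, purrr::map(days, "transcript_id"))
  }
  out <- tibble::tibble(transcript_id = ids)
  for (nm in names(days)) {
    out <- dplyr::left_join(
      out, stats::setNames(days[[nm]], c("transcript_id", nm)),
      by = "transcript_id"
    )
    out[[nm]] <- dplyr::coalesce(out[[nm]], 1)
  }
  out <- out |>
    dplyr::mutate(is_misa = .data$fc_d6 > cutoff &
                    .data$fc_d1 <= cutoff & .data$fc_d20 <= cutoff)
  class(out) <- c("misa_call", class(out))
  out
}

#' Classify NAT10-dependent synaptic ac4C (NASA) transcripts
#'
#' Only transcripts acetylated in control (`fe_ctrl > 0`) are classifiable;
#' others are labelled `not_acetylated`. A classifiable transcript is
#' `diminished` when its knockout enrichment falls below the detection
#' threshold (`fe_cko < 1`) or its peaks are lost entirely; `downregulated`
#' when still detectable but attenuated, i.e. the pseudocount fold change
#' control-vs-knockout exceeds `attenuation_fc`; otherwise `unchanged`. The
#' NASA set is the union of diminished and downregulated transcripts.
#'
#' @param ctrl,cko Tibbles from [transcript_fe()] for control and Nat10
#'   knockout samples.
#' @param attenuation_fc Pseudocount fold-change cutoff for the
#'   downregulated branch (default 2, the same cutoff the MISA rule uses).
#' @return A tibble of class `nasa_call`: `transcript_id`, `fe_ctrl`,
#'   `fe_cko`, `n_peaks_cko`, `category`, `is_nasa`.
#' @export
classify_nasa <- function(ctrl, cko, attenuation_fc = 2) {
  ctrl <- tibble::as_tibble(ctrl)
  cko <- tibble::as_tibble(cko)
  stopifnot(all(c("transcript_id", "fe_sum", "n_peaks") %in% names(ctrl)),
            all(c("transcript_id", "fe_sum", "n_peaks") %in% names(cko)),
            attenuation_fc > 0)
  out <- tibble::tibble(
    transcript_id = union(ctrl$transcript_id, cko$transcript_id)
  ) |>
    dplyr::left_join(
      dplyr::select(ctrl, "transcript_id", fe_ctrl = "fe_sum"),
      by = "transcript_id"
    ) |>
    dplyr::left_join(
      dplyr::select(cko, "transcript_id", fe_cko = "fe_sum",
                    n_peaks_cko = "n_peaks"),
      by = "transcript_id"
    ) |>
    dplyr::mutate(
      fe_ctrl = dplyr::coalesce(.data$fe_ctrl, 0),
      fe_cko = dplyr::coalesce(.data$fe_cko, 0),
      n_peaks_cko = dplyr::coalesce(.data$n_peaks_cko, 0L),
      category = dplyr::case_when(
        .data$fe_ctrl <= 0 ~ "not_acetylated",
        .data$fe_cko < 1 | .data$n_peaks_cko == 0 ~ "diminished",
        (.data$fe_ctrl + 1) / (.data$fe_cko + 1) > attenuation_fc ~
          "downregulated",
        TRUE ~ "unchanged"
      ),
      is_nasa = .data$category %in% c("diminished", "downregulated")
    )
  class(out) <- c("nasa_call", class(out))
  out
}

#' Overlap of two transcript sets
#'
#' Exact set cardinalities for, e.g., the MISA-vs-NASA comparison.
#'
#' @param a,b Character vectors of transcript ids (duplicates ignored).
#' @return A one-row tibble: `n_a`, `n_b`, `n_intersection`, `n_a_only`,
#'   `n_b_only`.
#' @export
overlap_sets <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  n_int <- length(intersect(a, b))
  tibble::tibble(
    n_a = length(a), n_b = length(b), n_intersection = n_int,
    n_a_only = length(a) - n_int, n_b_only = length(b) - n_int
  )
}

#' Synaptosome-database reliability filter
#'
#' Keeps a transcript only when it was detected in the experiment at hand
#' and appears in at least `min_support` of the supplied reference lists
#' (the published rule: at least two of three synaptosome databases).
#'
#' @param detected Character vector of detected transcript ids.
#' @param reference_lists List of character vectors (the reference
#'   databases).
#' @param min_support Minimum number of reference lists containing the id.
#' @return Character vector of reliable transcript ids.
#' @export
syn_reliability_filter <- function(detected, reference_lists,
                                   min_support = 2) {
  if (!is.list(reference_lists) || length(reference_lists) == 0) {
    stop("reference_lists must be a non-empty list of id vectors",
         call. = FALSE)
  }
  if (length(reference_lists) < min_support) {
    stop("fewer reference lists (", length(reference_lists),
         ") than min_support (", min_support, ")", call. = FALSE)
  }
  detected <- unique(as.character(detected))
  if (length(detected) == 0) return(character())
  hits <- vapply(reference_lists, function(ref) detected %in% ref,
                 logical(length(detected)))
  hits <- matrix(hits, nrow = length(detected))
  detected[rowSums(hits) >= min_support]
}
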