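#' Run the full ac4C analysis workflow
#'
#' Orchestrates the decision flow on a set of paired acRIP/input coverage
#' tracks: per-replicate peak calling, replicate consensus (reliability
#' rule: a peak seen in at least `min_support` replicates), optional
#' synaptosome-database filtering, transcript-level cumulative fold
#' enrichment, day-wise pseudocount fold changes and MISA classification
#' (for `control`/`memory` designs), NASA classification (for `ctrl`/`cko`
#' designs), their overlap, and summit-level summaries (metagene, region
#' chi-square, peaks per transcript). The run is a pure function of its
#' inputs and parameters.
#'
#' @param tracks List of [coverage_track()]s; each (condition, timepoint,
#'   replicate) cell must contribute one acRIP and one input track.
#' @param annotation Annotation tibble.
#' @param params [caller_params()] for the peak caller.
#' @param min_support Replicate-consensus support threshold (cells with a
#'   single replicate pass through with support 1 and a report warning).
#' @param misa_cutoff Fold-change cutoff for MISA classification.
#' @param syn_reference Optional list of reference transcript-id sets; when
#'   given, only transcripts in at least `syn_min_support` of them are kept.
#' @param syn_min_support Reference-list support threshold.
#' @param out_dir Optional directory; when given, all intermediate tables
#'   and the run report are written there.
#' @return A list of class `ac4c_run` with elements `report`,
#'   `replicate_peaks`, `consensus`, `transcript_fe`, `fold_changes`,
#'   `misa`, `nasa`, `overlap`, `metagene`, `region_test`,
#'   `peak_summary`, `ks_day6`.
#' @export
run_ac4c_pipeline <- function(tracks, annotation, params = caller_params(),
                              min_support = 2, misa_cutoff = 2,
                              syn_reference = NULL, syn_min_support = 2,
                              out_dir = NULL) {
  ann <- validate_annotation(annotation)
  meta <- purrr::imap_dfr(tracks, function(tr, i) {
    tibble::tibble(idx = i, library_id = tr$library_id, role = tr$role,
                   condition = tr$condition, timepoint = tr$timepoint,
                   replicate = tr$replicate)
  })
  cells <- meta |>
    dplyr::distinct(.data$condition, .data$timepoint, .data$replicate)
  warnings <- character()

  # per-replicate peak calling ------------------------------------------
  replicate_peaks <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    sel <- meta$condition == cell$condition &
      meta$timepoint == cell$timepoint & meta$replicate == cell$replicate
    a <- meta$idx[sel & meta$role == "acRIP"]
    b <- meta$idx[sel & meta$role == "input"]
    if (length(a) != 1 || length(b) != 1) {
      stop("design cell (", cell$condition, ", ", cell$timepoint,
           ", rep ", cell$replicate, ") lacks a paired acRIP/input track",
           call. = FALSE)
    }
    key <- sprintf("%s.%s.rep%d", cell$condition, cell$timepoint,
                   cell$replicate)
    replicate_peaks[[key]] <- call_peaks(tracks[[a]], tracks[[b]], params,
                                         annotation = ann)
  }

  # consensus per condition x timepoint ---------------------------------
  groups <- cells |> dplyr::distinct(.data$condition, .data$timepoint)
  consensus <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    keys <- sprintf("%s.%s.rep%d", g$condition, g$timepoint,
                    sort(cells$replicate[cells$condition == g$condition &
                                           cells$timepoint == g$timepoint]))
    gkey <- paste(g$condition, g$timepoint, sep = ".")
    reps <- replicate_peaks[keys]
    if (length(reps) == 1) {
      warnings <- c(warnings, paste0(
        "cell ", gkey, " has a single replicate; peaks pass through ",
        "with support 1"))
      cons <- reps[[1]] |>
        dplyr::transmute(
          transcript_id = .data$transcript_id, start = .data$start,
          end = .data$end, support = 1L, n_peaks = 1L, mean_fe = .data$fe
        )
    } else {
      cons <- consensus_peaks(reps, min_support = min_support)
    }
    if (!is.null(syn_reference)) {
      reliable <- syn_reliability_filter(unique(cons$transcript_id),
                                         syn_reference, syn_min_support)
      cons <- dplyr::filter(cons, .data$transcript_id %in% reliable)
    }
    consensus[[gkey]] <- cons
  }

  # transcript-level FE per cell ----------------------------------------
  fe_tables <- purrr::map(consensus, transcript_fe, annotation = ann)

  # MISA branch ----------------------------------------------------------
  fold_changes <- list()
  misa <- NULL
  ks_day6 <- NULL
  if (all(c("control", "memory") %in% groups$condition)) {
    for (day in intersect(c("day1", "day6", "day20"), groups$timepoint)) {
      mkey <- paste("memory", day, sep = ".")
      ckey <- paste("control", day, sep = ".")
      if (!is.null(fe_tables[[mkey]]) && !is.null(fe_tables[[ckey]])) {
        fold_changes[[day]] <- fold_change(fe_tables[[mkey]],
                                           fe_tables[[ckey]])
      }
    }
    if (length(fold_changes) > 0) {
      unit_fc <- tibble::tibble(transcript_id = character(),
                                fe_case = numeric(), fe_ref = numeric(),
                                fc = numeric())
      misa <- classify_misa(
        fc_d1 = fold_changes$day1 %||% unit_fc,
        fc_d6 = fold_changes$day6 %||% unit_fc,
        fc_d20 = fold_changes$day20 %||% unit_fc,
        cutoff = misa_cutoff
      )
    }
    if (!is.null(fe_tables[["memory.day6"]]) &&
        !is.null(fe_tables[["control.day6"]])) {
      ks_day6 <- ks_compare(fe_tables[["memory.day6"]]$fe_sum,
                            fe_tables[["control.day6"]]$fe_sum)
    }
  }

  # NASA branch ----------------------------------------------------------
  nasa <- NULL
  if (all(c("ctrl", "cko") %in% groups$condition)) {
    ckey <- grep("^ctrl\\.", names(fe_tables), value = TRUE)[1]
    kkey <- grep("^cko\\.", names(fe_tables), value = TRUE)[1]
    nasa <- classify_nasa(fe_tables[[ckey]], fe_tables[[kkey]])
  }

  overlap <- NULL
  if (!is.null(misa) && !is.null(nasa)) {
    overlap <- overlap_sets(misa$transcript_id[misa$is_misa],
                            nasa$transcript_id[nasa$is_nasa])
  }

  # summit-level summaries over pooled replicate peaks -------------------
  pooled <- dplyr::bind_rows(replicate_peaks)
  profile <- metagene(pooled, ann)
  region_test <- if (nrow(pooled) >= 2) region_chisq(pooled, ann) else NULL
  peak_summary <- purrr::map_dfr(consensus, peaks_per_transcript,
                                 annotation = ann, .id = "cell")

  report <- list(
    version = as.character(utils::packageVersion("acripr")),
    thresholds = list(
      min_fe = params$min_fe, max_q = params$max_q,
      input_pseudocount = params$input_pseudocount,
      merge_gap = params$merge_gap, min_support = min_support,
      misa_cutoff = misa_cutoff
    ),
    n_tracks = length(tracks),
    n_transcripts = nrow(ann),
    n_peaks_per_replicate = purrr::map_int(replicate_peaks, nrow),
    n_consensus = purrr::map_int(consensus, nrow),
    n_acetylated = purrr::map_int(fe_tables, ~ sum(.x$n_peaks > 0)),
    n_misa = if (!is.null(misa)) sum(misa$is_misa) else NA_integer_,
    n_nasa = if (!is.null(nasa)) sum(nasa$is_nasa) else NA_integer_,
    nasa_categories = if (!is.null(nasa)) {
      as.list(table(nasa$category))
    } else NULL,
    overlap = if (!is.null(overlap)) as.list(overlap) else NULL,
    warnings = warnings
  )

  run <- structure(
    list(report = report, replicate_peaks = replicate_peaks,
         consensus = consensus, transcript_fe = fe_tables,
         fold_changes = fold_changes, misa = misa, nasa = nasa,
         overlap = overlap, metagene = profile, region_test = region_test,
         peak_summary = peak_summary, ks_day6 = ks_day6),
    class = "ac4c_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Serialise a run report as canonical JSON
#'
#' Deterministic (no timestamps): identical inputs give byte-identical
#' report text.
#'
#' @param run An `ac4c_run`.
#' @return A JSON string.
#' @export
report_json <- function(run) {
  stopifnot(inherits(run, "ac4c_run"))
  jsonlite::toJSON(run$report, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(run$replicate_peaks)) {
    write_peaks(run$replicate_peaks[[key]],
                file.path(dir, paste0("peaks_", key, ".bed")))
  }
  for (key in names(run$consensus)) {
    readr::write_tsv(run$consensus[[key]],
                     file.path(dir, paste0("consensus_", key, ".tsv")),
                     progress = FALSE)
    readr::write_tsv(run$transcript_fe[[key]],
                     file.path(dir, paste0("fe_", key, ".tsv")),
                     progress = FALSE)
  }
  if (!is.null(run$misa)) {
    readr::write_tsv(run$misa, file.path(dir, "misa.tsv"), progress = FALSE)
  }
  if (!is.null(run$nasa)) {
    readr::write_tsv(run$nasa, file.path(dir, "nasa.tsv"), progress = FALSE)
  }
  readr::write_tsv(run$metagene, file.path(dir, "metagene.tsv"),
                   progress = FALSE)
  writeLines(report_json(run), file.path(dir, "report.json"))
  invisible(dir)
}

#' @export
print.ac4c_run <- function(x, ...) {
  r <- x$report
  cat("<ac4c_run>\n")
  cat("  peaks/replicate:",
      paste(names(r$n_peaks_per_replicate), r$n_peaks_per_replicate,
            sep = "=", collapse = ", "), "\n")
  cat("  consensus:",
      paste(names(r$n_consensus), r$n_consensus, sep = "=",
            collapse = ", "), "\n")
  if (!is.na(r$n_misa)) cat("  MISA transcripts:", r$n_misa, "\n")
  if (!is.na(r$n_nasa)) cat("  NASA transcripts:", r$n_nasa, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
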