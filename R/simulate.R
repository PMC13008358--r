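#' Configuration for a synthetic acRIP-seq experiment
#'
#' Bundles every parameter of the generator. Generation is a pure function of
#' the configuration: the same `seed` yields bit-identical output. Defaults
#' describe a synaptosome-scale scenario: about half of transcripts
#' acetylated, ~1.8 planted peaks per acetylated transcript, ~200 nt peaks
#' biased into the CDS, negative-binomial count noise, a memory effect that
#' multiplies peak enrichment only in (memory, day6) samples of a designated
#' transcript subset, and a knockout regime that abolishes or attenuates
#' peaks on NAT10-dependent transcripts.
#'
#' @param n_transcripts Number of transcripts to simulate.
#' @param segment_length_params Named list with elements `utr5`, `cds`,
#'   `utr3`, each `c(mean =, cv =)`: arithmetic mean (nt) and coefficient of
#'   variation of a log-normal length distribution.
#' @param window_size Coverage window width in nt.
#' @param n_replicates Biological replicates per condition/timepoint cell.
#' @param mean_input_depth Mean input reads per window.
#' @param dispersion Negative-binomial size parameter; `Inf` gives Poisson
#'   counts.
#' @param peak_rate Expected planted peaks per acetylated transcript
#'   (zero-truncated: every acetylated transcript carries at least one).
#' @param acetylated_fraction Fraction of transcripts carrying any peak.
#' @param cds_placement_bias Probability a planted summit falls in the CDS.
#' @param baseline_enrichment acRIP/input signal ratio inside a planted peak
#'   relative to the acRIP background.
#' @param peak_width Mean planted peak width in nt (fragment scale).
#' @param peak_width_jitter Relative half-width of the uniform width jitter.
#' @param acrip_background_frac acRIP background depth as a fraction of input
#'   depth (IP depletes unmodified RNA).
#' @param misa_fraction Fraction of acetylated transcripts that are
#'   memory-responsive (MISA-true).
#' @param misa_effect Extra enrichment multiplier applied to MISA-true peaks
#'   in (memory, day6) samples only.
#' @param nat10_dependent_fraction Fraction of acetylated transcripts whose
#'   peaks depend on NAT10.
#' @param cko_diminish_prob Among peaks on NAT10-dependent transcripts, the
#'   probability of full abolition (vs attenuation) in knockout samples.
#' @param cko_attenuation Multiplier applied to surviving (attenuated) peak
#'   enrichment in knockout samples.
#' @param seed Integer seed controlling all randomness.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 1000,
                       segment_length_params = list(
                         utr5 = c(mean = 150, cv = 0.6),
                         cds = c(mean = 1200, cv = 0.4),
                         utr3 = c(mean = 500, cv = 0.6)
                       ),
                       window_size = 50,
                       n_replicates = 3,
                       mean_input_depth = 50,
                       dispersion = 100,
                       peak_rate = 1.8,
                       acetylated_fraction = 0.55,
                       cds_placement_bias = 0.8,
                       baseline_enrichment = 4,
                       peak_width = 200,
                       peak_width_jitter = 0.25,
                       acrip_background_frac = 0.25,
                       misa_fraction = 0.33,
                       misa_effect = 3,
                       nat10_dependent_fraction = 0.6,
                       cko_diminish_prob = 0.9,
                       cko_attenuation = 0.6,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_transcripts >= 0, cfg$window_size >= 1, cfg$n_replicates >= 1,
    cfg$mean_input_depth > 0, cfg$dispersion > 0, cfg$peak_rate >= 1,
    cfg$acetylated_fraction > 0, cfg$acetylated_fraction <= 1,
    cfg$cds_placement_bias >= 0, cfg$cds_placement_bias <= 1,
    cfg$baseline_enrichment >= 1,
    cfg$misa_fraction >= 0, cfg$misa_fraction < 1,
    cfg$misa_effect >= 1,
    cfg$nat10_dependent_fraction >= 0, cfg$nat10_dependent_fraction <= 1,
    cfg$cko_diminish_prob >= 0, cfg$cko_diminish_prob <= 1,
    cfg$cko_attenuation > 0, cfg$cko_attenuation < 1
  )
  for (seg in c("utr5", "cds", "utr3")) {
    p <- cfg$segment_length_params[[seg]]
    if (is.null(p) || !all(c("mean", "cv") %in% names(p)) ||
        p[["mean"]] <= 0 || p[["cv"]] <= 0) {
      stop("segment_length_params$", seg,
           " must supply positive mean and cv", call. = FALSE)
    }
  }
  structure(cfg, class = "sim_config")
}

# log-normal draw parameterized by arithmetic mean and cv
rlnorm_mean_cv <- function(n, mean, cv) {
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate a transcript annotation
#'
#' Segment lengths are drawn from log-normal distributions with the
#' configured means and coefficients of variation; transcripts shorter than
#' four coverage windows are redrawn so every transcript supports at least
#' one fragment-scale peak.
#'
#' @param config A [sim_config()].
#' @return An annotation tibble (see [read_annotation()]).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  draw_annotation(config)
}

draw_annotation <- function(config) {
  n <- config$n_transcripts
  empty <- tibble::tibble(
    transcript_id = character(), gene_id = character(),
    utr5_len = integer(), cds_len = integer(), utr3_len = integer()
  )
  if (n == 0) return(validate_annotation(empty))
  p <- config$segment_length_params
  min_total <- 4 * config$window_size
  draw <- function(k) {
    tibble::tibble(
      utr5_len = as.integer(round(rlnorm_mean_cv(k, p$utr5[["mean"]],
                                                 p$utr5[["cv"]]))),
      cds_len = pmax(1L, as.integer(round(rlnorm_mean_cv(k, p$cds[["mean"]],
                                                         p$cds[["cv"]])))),
      utr3_len = as.integer(round(rlnorm_mean_cv(k, p$utr3[["mean"]],
                                                 p$utr3[["cv"]])))
    )
  }
  segs <- draw(n)
  for (i in 1:50) {
    short <- (segs$utr5_len + segs$cds_len + segs$utr3_len) < min_total
    if (!any(short)) break
    segs[short, ] <- draw(sum(short))
  }
  if (any(segs$utr5_len + segs$cds_len + segs$utr3_len < min_total)) {
    stop("segment length parameters cannot reach the minimum transcript ",
         "length of 4 windows", call. = FALSE)
  }
  validate_annotation(tibble::tibble(
    transcript_id = sprintf("tx%04d", seq_len(n)),
    gene_id = sprintf("g%04d", seq_len(n)),
    segs
  ))
}

#' Experimental design helpers
#'
#' `memory_design()` lays out the memory time-course (control/memory at days
#' 1, 6, 20); `cko_design()` the knockout comparison (ctrl/cko at day 6).
#'
#' @param n_replicates Replicates per cell.
#' @return A design tibble with columns `condition`, `timepoint`, `replicate`.
#' @export
memory_design <- function(n_replicates = 3) {
  tidyr::expand_grid(
    condition = c("control", "memory"),
    timepoint = c("day1", "day6", "day20"),
    replicate = seq_len(n_replicates)
  )
}

#' @rdname memory_design
#' @export
cko_design <- function(n_replicates = 2) {
  tidyr::expand_grid(
    condition = c("ctrl", "cko"),
    timepoint = "day6",
    replicate = seq_len(n_replicates)
  )
}

sim_conditions <- c("control", "memory", "ctrl", "cko")

#' Simulate a complete paired acRIP/input experiment
#'
#' Generates an annotation, planted ground truth (which transcripts are
#' acetylated, memory-responsive, NAT10-dependent; where their peaks lie and
#' their knockout fate), and one acRIP + one input coverage track per design
#' cell. Input counts are negative-binomial around the configured depth;
#' acRIP counts follow the (lower) IP background outside peaks and
#' background x enrichment inside planted peaks, with the memory multiplier
#' applied only to MISA-true transcripts in (memory, day6) cells and the
#' knockout abolition/attenuation applied in `cko` cells.
#'
#' @param config A [sim_config()].
#' @param design A design tibble (see [memory_design()]); conditions must be
#'   among `control`, `memory`, `ctrl`, `cko`.
#' @return A list with elements `annotation`, `tracks` (list of
#'   [coverage_track()]s, acRIP and input per design row), and `truth` (list
#'   of tibbles `transcripts` and `peaks`).
#' @export
simulate_experiment <- function(config, design = memory_design(config$n_replicates)) {
  stopifnot(inherits(config, "sim_config"))
  design <- tibble::as_tibble(design)
  if (nrow(design) == 0) stop("design is empty", call. = FALSE)
  bad <- setdiff(unique(design$condition), sim_conditions)
  if (length(bad) > 0) {
    stop("unknown condition label(s) in design: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  set.seed(config$seed)
  annotation <- draw_annotation(config)
  truth <- draw_truth(config, annotation)
  grid <- window_grid(annotation, config$window_size)
  peak_windows <- peak_window_overlap(truth$peaks, grid, config$window_size)

  tracks <- vector("list", 2 * nrow(design))
  for (i in seq_len(nrow(design))) {
    cell <- design[i, ]
    mult <- cell_multiplier(peak_windows, truth, config, cell)
    inp_mu <- rep(config$mean_input_depth, nrow(grid))
    acr_mu <- config$mean_input_depth * config$acrip_background_frac *
      window_multiplier(grid, mult)
    inp <- draw_counts(inp_mu, config$dispersion)
    acr <- draw_counts(acr_mu, config$dispersion)
    # library sizes are nominal transcriptome-wide totals (the simulated
    # panel is a small subset of a real library, so its peak-mass excess
    # must not move the normalisation factor): 3x the expected background
    # mass of each role, floored at the realised panel total
    inp_lib <- max(round(3 * config$mean_input_depth * nrow(grid)), sum(inp))
    acr_lib <- max(round(3 * config$mean_input_depth *
                           config$acrip_background_frac * nrow(grid)),
                   sum(acr))
    tag <- sprintf("%s_%s_rep%d", cell$condition, cell$timepoint,
                   cell$replicate)
    tracks[[2 * i - 1]] <- coverage_track(
      tibble::tibble(transcript_id = grid$transcript_id,
                     window = grid$window, count = acr),
      window_size = config$window_size,
      library_id = paste0("acrip_", tag), role = "acRIP",
      condition = cell$condition, timepoint = cell$timepoint,
      replicate = cell$replicate, library_size = acr_lib
    )
    tracks[[2 * i]] <- coverage_track(
      tibble::tibble(transcript_id = grid$transcript_id,
                     window = grid$window, count = inp),
      window_size = config$window_size,
      library_id = paste0("input_", tag), role = "input",
      condition = cell$condition, timepoint = cell$timepoint,
      replicate = cell$replicate, library_size = inp_lib
    )
  }
  list(annotation = annotation, tracks = tracks, truth = truth)
}

draw_truth <- function(config, annotation) {
  n <- nrow(annotation)
  acetylated <- stats::runif(n) < config$acetylated_fraction
  is_misa <- acetylated & (stats::runif(n) < config$misa_fraction)
  nat10_dep <- acetylated & (stats::runif(n) < config$nat10_dependent_fraction)
  transcripts <- tibble::tibble(
    transcript_id = annotation$transcript_id,
    acetylated = acetylated,
    is_misa_true = is_misa,
    nat10_dependent = nat10_dep
  )
  ace <- annotation[acetylated, ]
  if (nrow(ace) == 0) {
    peaks <- tibble::tibble(
      transcript_id = character(), peak_id = character(), start = integer(),
      end = integer(), summit = integer(), cko_fate = character()
    )
    return(list(transcripts = transcripts, peaks = peaks))
  }
  n_peaks <- 1L + stats::rpois(nrow(ace), config$peak_rate - 1)
  idx <- rep(seq_len(nrow(ace)), n_peaks)
  tx <- ace[idx, ]
  m <- nrow(tx)
  width <- as.integer(round(stats::runif(
    m, config$peak_width * (1 - config$peak_width_jitter),
    config$peak_width * (1 + config$peak_width_jitter)
  )))
  draw_positions <- function(rows) {
    region <- pick_region(tx[rows, ], config$cds_placement_bias)
    reg_start <- ifelse(region == "UTR5", 0L,
                 ifelse(region == "CDS", tx$utr5_len[rows],
                        tx$utr5_len[rows] + tx$cds_len[rows]))
    reg_len <- ifelse(region == "UTR5", tx$utr5_len[rows],
               ifelse(region == "CDS", tx$cds_len[rows],
                      tx$utr3_len[rows]))
    summit <- reg_start + as.integer(floor(stats::runif(length(rows)) *
                                             reg_len))
    list(summit = summit,
         start = pmax(0L, summit - width[rows] %/% 2L),
         end = pmin(tx$total_len[rows],
                    summit + (width[rows] + 1L) %/% 2L))
  }
  pos <- draw_positions(seq_len(m))
  summit <- pos$summit; start <- pos$start; end <- pos$end
  # distinct modification sites: redraw peaks that collide with an
  # earlier-placed peak on the same transcript (bounded retries)
  for (iter in 1:20) {
    ord <- order(tx$transcript_id, start)
    clash <- logical(m)
    cur_tx <- ""
    cur_end <- -1L
    for (r in ord) {
      if (tx$transcript_id[r] != cur_tx) {
        cur_tx <- tx$transcript_id[r]
        cur_end <- end[r]
      } else if (start[r] < cur_end + config$window_size) {
        clash[r] <- TRUE   # within a window of an earlier peak: redraw
      } else {
        cur_end <- end[r]
      }
    }
    if (!any(clash)) break
    rows <- which(clash)
    new_pos <- draw_positions(rows)
    summit[rows] <- new_pos$summit
    start[rows] <- new_pos$start
    end[rows] <- new_pos$end
  }
  dep <- tx$transcript_id %in%
    transcripts$transcript_id[transcripts$nat10_dependent]
  fate <- ifelse(!dep, "kept",
                 ifelse(stats::runif(m) < config$cko_diminish_prob,
                        "abolished", "attenuated"))
  peaks <- tibble::tibble(
    transcript_id = tx$transcript_id,
    peak_id = sprintf("planted_%d", seq_len(m)),
    start = start, end = end, summit = summit, cko_fate = fate
  )
  list(transcripts = transcripts, peaks = peaks)
}

# choose the summit region: CDS with probability `bias`, otherwise one of
# the UTRs proportional to their lengths (CDS if both UTRs are empty)
pick_region <- function(tx, bias) {
  m <- nrow(tx)
  in_cds <- stats::runif(m) < bias
  utr_total <- tx$utr5_len + tx$utr3_len
  pick5 <- stats::runif(m) * utr_total < tx$utr5_len
  region <- ifelse(in_cds | utr_total == 0, "CDS",
                   ifelse(pick5, "UTR5", "UTR3"))
  region
}

window_grid <- function(annotation, window_size) {
  nw <- n_windows(annotation, window_size)
  dense_windows(annotation$transcript_id, nw)
}

# map each planted peak onto the windows it overlaps, with overlap fraction
peak_window_overlap <- function(peaks, grid, window_size) {
  if (nrow(peaks) == 0) {
    return(tibble::tibble(transcript_id = character(), window = integer(),
                          peak_id = character(), frac = numeric()))
  }
  first_w <- peaks$start %/% window_size
  last_w <- (peaks$end - 1L) %/% window_size
  reps <- last_w - first_w + 1L
  idx <- rep(seq_len(nrow(peaks)), reps)
  win <- unlist(lapply(seq_len(nrow(peaks)),
                       function(i) seq.int(first_w[i], last_w[i])),
                use.names = FALSE)
  ws <- win * window_size
  ov <- (pmin(peaks$end[idx], ws + window_size) - pmax(peaks$start[idx], ws)) /
    window_size
  tibble::tibble(
    transcript_id = peaks$transcript_id[idx],
    window = win,
    peak_id = peaks$peak_id[idx],
    frac = ov
  )
}

# per-peak enrichment for one design cell, then per-window multiplier
cell_multiplier <- function(peak_windows, truth, config, cell) {
  if (nrow(peak_windows) == 0) {
    return(dplyr::mutate(peak_windows, mult = numeric(0)))
  }
  peaks <- truth$peaks
  misa_ids <- truth$transcripts$transcript_id[truth$transcripts$is_misa_true]
  e <- rep(config$baseline_enrichment, nrow(peaks))
  if (cell$condition == "memory" && cell$timepoint == "day6") {
    on_misa <- peaks$transcript_id %in% misa_ids
    e[on_misa] <- e[on_misa] * config$misa_effect
  }
  if (cell$condition == "cko") {
    e[peaks$cko_fate == "abolished"] <- 1
    att <- peaks$cko_fate == "attenuated"
    e[att] <- pmax(1, e[att] * config$cko_attenuation)
  }
  enr <- stats::setNames(e, peaks$peak_id)
  dplyr::mutate(peak_windows,
                mult = 1 + .data$frac * (enr[.data$peak_id] - 1))
}

window_multiplier <- function(grid, peak_mult) {
  mult <- rep(1, nrow(grid))
  if (is.null(peak_mult) || nrow(peak_mult) == 0) return(mult)
  agg <- peak_mult |>
    dplyr::group_by(.data$transcript_id, .data$window) |>
    dplyr::summarise(mult = max(.data$mult), .groups = "drop")
  key <- paste(grid$transcript_id, grid$window)
  hit <- match(paste(agg$transcript_id, agg$window), key)
  mult[hit] <- agg$mult
  mult
}

draw_counts <- function(mu, dispersion) {
  if (is.infinite(dispersion)) {
    stats::rpois(length(mu), mu)
  } else {
    stats::rnbinom(length(mu), mu = mu, size = dispersion)
  }
}

#' Write a simulated experiment to a directory
#'
#' Emits the annotation, one count TSV per library, and the ground-truth
#' tables, mirroring what a real pipeline run would consume.
#'
#' @param experiment Result of [simulate_experiment()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_annotation(experiment$annotation, file.path(dir, "annotation.tsv"))
  for (tr in experiment$tracks) {
    write_counts(tr, file.path(dir, paste0(tr$library_id, ".tsv")))
  }
  readr::write_tsv(experiment$truth$transcripts,
                   file.path(dir, "truth_transcripts.tsv"), progress = FALSE)
  readr::write_tsv(experiment$truth$peaks,
                   file.path(dir, "truth_peaks.tsv"), progress = FALSE)
  invisible(dir)
}
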