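test_that("window enrichment matches the Poisson background model", {
  # equal library sizes, input 4 + pseudocount 1 -> lambda 5; acrip 20
  acrip <- toy_track(list(tx1 = c(20, 0, 10)), library_size = 1000)
  input <- toy_track(list(tx1 = c(4, 4, 20)), role = "input",
                     library_size = 1000)
  we <- window_enrichment(acrip, input)
  expect_equal(we$fe[1], 4)
  expect_equal(we$pvalue[1], 3.452136e-07, tolerance = 1e-6)
  expect_equal(we$pvalue[1], pois_tail_oracle(20, 5), tolerance = 1e-12)

  # zero acRIP count: degenerate tail
  expect_equal(we$fe[2], 0)
  expect_equal(we$pvalue[2], 1)
})

test_that("fold enrichment scales with library size", {
  acrip <- toy_track(list(tx1 = c(10, 10)), library_size = 2000)
  input <- toy_track(list(tx1 = c(10, 10)), role = "input",
                     library_size = 1000)
  we <- window_enrichment(acrip, input,
                          caller_params(input_pseudocount = 0))
  expect_equal(we$fe, c(0.5, 0.5))
})

test_that("window p-values agree with brute-force tail summation", {
  acrip <- toy_track(list(tx1 = rep(c(0, 1, 5, 20, 50, 100, 200), 3)),
                     library_size = 5000)
  input <- toy_track(list(tx1 = rep(c(0, 3, 10, 40, 80, 150, 30), 3)),
                     role = "input", library_size = 8000)
  we <- window_enrichment(acrip, input)
  lambda <- (we$input_count + 1) * 5000 / 8000
  for (i in seq_len(nrow(we))) {
    expect_equal(we$pvalue[i], pois_tail_oracle(we$acrip_count[i], lambda[i]),
                 tolerance = 1e-9)
  }
})

test_that("mismatched tracks are rejected", {
  a <- toy_track(list(tx1 = c(1, 2)))
  b <- toy_track(list(tx1 = c(1, 2, 3)), role = "input")
  expect_error(window_enrichment(a, b), "mismatched")
  b2 <- toy_track(list(tx1 = c(1, 2)), role = "input", window_size = 25)
  expect_error(window_enrichment(a, b2), "window size")
})

test_that("BH adjustment reproduces the hand step-up and its symmetries", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(numeric()), "empty")

  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(2:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p))
    # order preservation: sorting p sorts q identically
    expect_equal(q[order(p)], sort(q))
  }
})

test_that("adjacent significant windows merge into single screened peaks", {
  # tx with one strong 3-window block; equal library sizes
  acrip <- toy_track(list(tx1 = c(5, 100, 120, 90, 5, 5, 5, 5)),
                     library_size = 1e5)
  input <- toy_track(list(tx1 = rep(10, 8)), role = "input",
                     library_size = 1e5)
  peaks <- call_peaks(acrip, input)
  expect_equal(nrow(peaks), 1)
  expect_equal(peaks$start, 50L)
  expect_equal(peaks$end, 200L)
  expect_equal(peaks$summit, 100L)  # leftmost window with max acRIP count
  expect_equal(peaks$acrip_count, 310)
  expect_true(peaks$fe > 2 && peaks$qvalue < 0.05)

  # nothing significant -> empty set
  flat <- toy_track(list(tx1 = rep(10, 8)), library_size = 1e5)
  expect_equal(nrow(call_peaks(flat, input)), 0)
})

test_that("merge_gap bridges single non-significant windows", {
  acrip <- toy_track(list(tx1 = c(100, 8, 100, 5, 5, 5, 5, 5)),
                     library_size = 1e5)
  input <- toy_track(list(tx1 = rep(10, 8)), role = "input",
                     library_size = 1e5)
  one <- call_peaks(acrip, input, caller_params(merge_gap = 1))
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start, one$end), c(0L, 150L))
  two <- call_peaks(acrip, input, caller_params(merge_gap = 0))
  expect_equal(nrow(two), 2)
})

test_that("every returned peak satisfies the published screen", {
  cfg <- sim_config(n_transcripts = 150, seed = 31)
  ex <- simulate_experiment(cfg, memory_design(1)[1:2, ])
  peaks <- call_peaks(ex$tracks[[1]], ex$tracks[[2]],
                      annotation = ex$annotation)
  expect_gt(nrow(peaks), 0)
  expect_true(all(peaks$fe > 2))
  expect_true(all(peaks$qvalue < 0.05))
  expect_true(all(peaks$qvalue >= peaks$pvalue))
  expect_true(all(peaks$start < peaks$end))
  expect_true(all(peaks$summit >= peaks$start & peaks$summit < peaks$end))
  j <- match(peaks$transcript_id, ex$annotation$transcript_id)
  expect_true(all(peaks$end <= ex$annotation$total_len[j]))
})

test_that("planted peaks at default depth and enrichment are recovered", {
  cfg <- sim_config(n_transcripts = 300, seed = 17)
  ex <- simulate_experiment(cfg, memory_design(1)[1, ])
  called <- call_peaks(ex$tracks[[1]], ex$tracks[[2]],
                       annotation = ex$annotation)
  planted <- ex$truth$peaks
  overlapped <- vapply(seq_len(nrow(planted)), function(i) {
    hit <- called$transcript_id == planted$transcript_id[i] &
      called$start < planted$end[i] & called$end > planted$start[i]
    any(hit)
  }, logical(1))
  expect_true(all(overlapped))
})

test_that("consensus clustering applies the 2-of-3 reliability rule", {
  peak <- function(tx, s, e, fe = 5) {
    tibble::tibble(transcript_id = tx, start = s, end = e,
                   summit = s, fe = fe, pvalue = 1e-6, qvalue = 1e-5)
  }
  # identical peak in 3/3 replicates
  reps <- list(peak("tx1", 100, 300), peak("tx1", 100, 300),
               peak("tx1", 100, 300, fe = 8))
  cons <- consensus_peaks(reps)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$support, 3L)
  expect_equal(cons$mean_fe, 6)

  # peak in only 1/3 replicates is dropped at min_support 2
  reps1 <- list(peak("tx1", 100, 300), peak("tx2", 100, 300),
                peak("tx3", 100, 300))
  expect_equal(nrow(consensus_peaks(reps1)), 0)

  # hand-traced single-linkage case: [100,300) + [250,450) cluster and are
  # kept with support 2; [800,900) in one replicate only is dropped
  reps2 <- list(peak("tx1", 100, 300),
                dplyr::bind_rows(peak("tx1", 250, 450), peak("tx1", 800, 900)),
                peak("tx1", 2000, 2100))
  cons2 <- consensus_peaks(reps2)
  expect_equal(nrow(cons2), 1)
  expect_equal(c(cons2$start, cons2$end), c(100L, 450L))
  expect_equal(cons2$support, 2L)

  # abutting half-open intervals share no nucleotide and do not cluster
  reps3 <- list(peak("tx1", 100, 300), peak("tx1", 300, 400))
  expect_equal(nrow(consensus_peaks(reps3)), 0)

  expect_error(consensus_peaks(list(peak("tx1", 1, 2)), min_support = 2),
               "min_support")
})

test_that("consensus peaks are invariant to replicate ordering", {
  set.seed(8)
  reps <- lapply(1:3, function(i) random_peak_set(15))
  a <- consensus_peaks(reps)
  b <- consensus_peaks(reps[c(3, 1, 2)])
  expect_equal(a, b)
})

test_that("the BH-screened caller is quiet under the global null", {
  # enrichment 1 everywhere, Poisson noise: the screen the caller actually
  # applies (BH q < 0.05 and FE > 2) yields at most a stray window
  n_called <- vapply(1:10, function(s) {
    cfg <- sim_config(n_transcripts = 50, baseline_enrichment = 1,
                      dispersion = Inf, misa_effect = 1, seed = s)
    ex <- simulate_experiment(cfg, memory_design(1)[1, ])
    nrow(call_peaks(ex$tracks[[1]], ex$tracks[[2]]))
  }, numeric(1))
  expect_lte(mean(n_called), 1)
})
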