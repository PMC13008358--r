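test_that("summit region assignment follows half-open boundaries", {
  ann <- tibble::tibble(transcript_id = "tx1", gene_id = "g1",
                        utr5_len = 100L, cds_len = 900L, utr3_len = 400L)
  pk <- function(s) tibble::tibble(transcript_id = "tx1", summit = s)
  expect_equal(as.character(assign_region(pk(50), ann)$region), "UTR5")
  expect_equal(as.character(assign_region(pk(100), ann)$region), "CDS")
  expect_equal(as.character(assign_region(pk(999), ann)$region), "CDS")
  expect_equal(as.character(assign_region(pk(1000), ann)$region), "UTR3")
  expect_error(assign_region(pk(1400), ann), "outside")
  expect_error(
    assign_region(tibble::tibble(transcript_id = "nope", summit = 1), ann),
    "absent"
  )
})

test_that("region assignment ignores peak width", {
  ann <- toy_annotation()
  wide <- tibble::tibble(transcript_id = "tx1", start = 0L, end = 1300L,
                         summit = 150L)
  narrow <- tibble::tibble(transcript_id = "tx1", start = 140L, end = 160L,
                           summit = 150L)
  expect_equal(assign_region(wide, ann)$region,
               assign_region(narrow, ann)$region)
})

test_that("metagene puts a CDS-midpoint summit in the middle CDS bin", {
  ann <- tibble::tibble(transcript_id = "tx1", gene_id = "g1",
                        utr5_len = 100L, cds_len = 900L, utr3_len = 400L)
  pk <- tibble::tibble(transcript_id = "tx1", summit = 550L)  # CDS midpoint
  prof <- metagene(pk, ann, bins_per_region = 31)
  expect_equal(sum(prof$density), 1)
  mid <- prof$bin[prof$region == "CDS"][16]
  expect_equal(prof$density[prof$bin == mid], 1)

  none <- metagene(pk[0, ], ann)
  expect_true(all(none$density == 0))
  expect_equal(nrow(none), 90)
})

test_that("uniform summits give a length-weighted uniform metagene", {
  ann <- tibble::tibble(transcript_id = "tx1", gene_id = "g1",
                        utr5_len = 300L, cds_len = 900L, utr3_len = 300L)
  set.seed(4)
  n <- 10000
  pk <- tibble::tibble(transcript_id = "tx1",
                       summit = sample.int(1500, n, replace = TRUE) - 1L)
  prof <- metagene(pk, ann, bins_per_region = 30)
  # per-bin expected mass: region length / (total x bins); binomial 99% bounds
  exp_mass <- rep(c(300, 900, 300) / 1500 / 30, each = 30)
  half <- 2.58 * sqrt(exp_mass * (1 - exp_mass) / n)
  expect_true(all(abs(prof$density - exp_mass) < half + 1e-3))
})

test_that("peaks-per-transcript summarises acetylated transcripts", {
  ann <- toy_annotation()
  pk <- tibble::tibble(
    transcript_id = c("tx1", "tx1", "tx3"),
    summit = c(10L, 500L, 100L)
  )
  s <- peaks_per_transcript(pk, ann)
  expect_equal(s$n_detected, 3)
  expect_equal(s$n_acetylated, 2)
  expect_equal(s$fraction_acetylated, 2 / 3)
  expect_equal(s$mean_peaks, 1.5)

  s0 <- peaks_per_transcript(pk[0, ], ann)
  expect_equal(s0$fraction_acetylated, 0)
  expect_true(is.na(s0$mean_peaks))
})

test_that("peaks-per-transcript recovers the planted rate", {
  cfg <- sim_config(n_transcripts = 500, seed = 23)
  ex <- simulate_experiment(cfg, memory_design(1)[1, ])
  called <- call_peaks(ex$tracks[[1]], ex$tracks[[2]],
                       annotation = ex$annotation)
  s <- peaks_per_transcript(called, ex$annotation)
  expect_lt(abs(s$mean_peaks - cfg$peak_rate), 0.3)
})

test_that("region chi-square matches the textbook computation", {
  # single transcript with region lengths in 1:2:1 proportion
  ann <- tibble::tibble(transcript_id = "tx1", gene_id = "g1",
                        utr5_len = 250L, cds_len = 500L, utr3_len = 250L)
  mk <- function(n5, nc, n3) {
    tibble::tibble(
      transcript_id = "tx1",
      summit = c(sample.int(250, n5, replace = TRUE) - 1L,
                 250L + sample.int(500, nc, replace = TRUE) - 1L,
                 750L + sample.int(250, n3, replace = TRUE) - 1L)
    )
  }
  set.seed(2)
  # observed [10, 80, 10] vs expected [25, 50, 25]: chi2 = 9 + 18 + 9 = 36
  res <- region_chisq(mk(10, 80, 10), ann)
  expect_equal(res$chi2, 36)
  expect_equal(res$df, 2L)
  expect_equal(res$p, pchisq(36, 2, lower.tail = FALSE))

  # observed exactly proportional to lengths -> chi2 0, p 1
  res0 <- region_chisq(mk(25, 50, 25), ann)
  expect_equal(res0$chi2, 0)
  expect_equal(res0$p, 1)

  expect_error(region_chisq(mk(1, 0, 0), ann), "at least 2")
})

test_that("region chi-square collapses absent regions", {
  ann <- tibble::tibble(transcript_id = "tx1", gene_id = "g1",
                        utr5_len = 0L, cds_len = 1000L, utr3_len = 0L)
  pk <- tibble::tibble(transcript_id = "tx1", summit = c(10L, 500L, 900L))
  res <- region_chisq(pk, ann)
  expect_equal(res$status, "skipped")
})
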