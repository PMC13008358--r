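test_that("transcript FE sums member-peak fold enrichments", {
  ann <- toy_annotation()
  pk <- tibble::tibble(
    transcript_id = c("tx1", "tx1", "tx3"),
    fe = c(3.0, 2.5, 4.0)
  )
  fe <- transcript_fe(pk, ann)
  expect_equal(fe$fe_sum[fe$transcript_id == "tx1"], 5.5)
  expect_equal(fe$n_peaks[fe$transcript_id == "tx1"], 2L)
  expect_equal(fe$fe_sum[fe$transcript_id == "tx2"], 0)
  expect_equal(fe$n_peaks[fe$transcript_id == "tx2"], 0L)
  # n_peaks = 0 <=> fe_sum = 0
  expect_equal(fe$n_peaks == 0, fe$fe_sum == 0)
  # consensus tables (mean_fe) are accepted too
  cons <- dplyr::rename(pk, mean_fe = fe)
  expect_equal(transcript_fe(cons, ann), fe)
})

test_that("transcript FE equals a brute-force grouping oracle", {
  set.seed(11)
  for (i in 1:10) {
    pk <- random_peak_set(sample(1:40, 1))
    got <- transcript_fe(pk, toy_annotation())
    want <- fe_sum_oracle(pk, toy_annotation()$transcript_id)
    expect_equal(got$fe_sum, want$fe_sum)
    expect_equal(got$n_peaks, want$n_peaks)
  }
})

test_that("pseudocount fold change is always finite and directional", {
  fe_tbl <- function(ids, fe) {
    tibble::tibble(transcript_id = ids, n_peaks = as.integer(fe > 0),
                   fe_sum = fe)
  }
  fc <- fold_change(fe_tbl("a", 3), fe_tbl("a", 1))
  expect_equal(fc$fc, 2)
  expect_equal(fold_change(fe_tbl("a", 0), fe_tbl("a", 0))$fc, 1)
  expect_equal(fold_change(fe_tbl("a", 5), fe_tbl("a", 0))$fc, 6)

  # union universe with the missing side treated as fe 0
  fc2 <- fold_change(fe_tbl("a", 5), fe_tbl("b", 3))
  expect_equal(sort(fc2$transcript_id), c("a", "b"))
  expect_equal(fc2$fc[fc2$transcript_id == "a"], 6)
  expect_equal(fc2$fc[fc2$transcript_id == "b"], 1 / 4)

  # strictly increasing in the case FE, decreasing in the reference FE
  x <- seq(0, 10, by = 0.5)
  up <- fold_change(fe_tbl(as.character(x), x),
                    fe_tbl(as.character(x), rep(2, length(x))))
  expect_true(all(diff(up$fc[order(x)]) > 0))
})

test_that("MISA calls require day-6-specific upregulation", {
  fc_tbl <- function(fc) {
    tibble::tibble(transcript_id = sprintf("t%d", seq_along(fc)), fc = fc)
  }
  calls <- classify_misa(
    fc_d1 = fc_tbl(c(1.1, 2.5, 0.9, 1.0)),
    fc_d6 = fc_tbl(c(2.5, 2.5, 2.01, 2.0)),
    fc_d20 = fc_tbl(c(0.9, 1.0, 2.2, 1.0))
  )
  # day-6 only -> MISA; day-1 elevation or day-20 elevation -> not;
  # fc_d6 exactly at the cutoff -> not (strict inequality)
  expect_equal(calls$is_misa, c(TRUE, FALSE, FALSE, FALSE))

  # a transcript missing from one day defaults to fc 1 there
  partial <- classify_misa(fc_d1 = fc_tbl(1)[0, ], fc_d6 = fc_tbl(3),
                           fc_d20 = fc_tbl(1)[0, ])
  expect_true(partial$is_misa)
  expect_equal(partial$fc_d1, 1)

  strict <- classify_misa(fc_d1 = fc_tbl(1)[0, ], fc_d6 = fc_tbl(3),
                          fc_d20 = fc_tbl(1)[0, ], missing = "strict")
  expect_equal(nrow(strict), 0)
})

test_that("NASA categories are exhaustive and follow the detection rules", {
  fe_tbl <- function(ids, fe, np = as.integer(fe > 0)) {
    tibble::tibble(transcript_id = ids, n_peaks = np, fe_sum = fe)
  }
  ids <- c("lost", "weak", "down", "same", "never")
  ctrl <- fe_tbl(ids, c(5, 4, 9, 4, 0))
  cko <- fe_tbl(ids, c(0, 0.5, 3, 3.5, 0))
  calls <- classify_nasa(ctrl, cko)
  expect_equal(
    calls$category[match(ids, calls$transcript_id)],
    c("diminished",     # peaks lost entirely
      "diminished",     # fe_cko < 1
      "downregulated",  # (9+1)/(3+1) = 2.5 > 2 and fe_cko >= 1
      "unchanged",      # (4+1)/(3.5+1) = 1.1
      "not_acetylated") # never acetylated in control
  )
  expect_equal(calls$is_nasa[match(ids, calls$transcript_id)],
               c(TRUE, TRUE, TRUE, FALSE, FALSE))

  # every control-acetylated transcript gets exactly one category
  set.seed(3)
  n <- 200
  rids <- sprintf("r%d", 1:n)
  rctrl <- fe_tbl(rids, round(runif(n, 0, 10), 2))
  rcko <- fe_tbl(rids, round(runif(n, 0, 10), 2))
  rcalls <- classify_nasa(rctrl, rcko)
  classifiable <- rcalls[rcalls$fe_ctrl > 0, ]
  expect_true(all(classifiable$category %in%
                    c("diminished", "downregulated", "unchanged")))
  expect_equal(nrow(classifiable),
               sum(classifiable$category == "diminished") +
                 sum(classifiable$category == "downregulated") +
                 sum(classifiable$category == "unchanged"))
})

test_that("classifications are deterministic and order-independent", {
  fe_tbl <- function(ids, fe) {
    tibble::tibble(transcript_id = ids, n_peaks = as.integer(fe > 0),
                   fe_sum = fe)
  }
  set.seed(9)
  ids <- sprintf("t%d", 1:50)
  a <- fe_tbl(ids, runif(50, 0, 8))
  b <- fe_tbl(ids, runif(50, 0, 8))
  shuffle <- sample(50)
  c1 <- classify_nasa(a, b)
  c2 <- classify_nasa(a[shuffle, ], b[rev(shuffle), ])
  expect_equal(dplyr::arrange(c1, transcript_id),
               dplyr::arrange(c2, transcript_id))
})

test_that("set overlap returns exact cardinalities", {
  ov <- overlap_sets(c("x", "y", "z"), c("y", "z", "w"))
  expect_equal(ov$n_intersection, 2)
  expect_equal(ov$n_a_only, 1)
  expect_equal(ov$n_b_only, 1)
  expect_equal(ov$n_intersection + ov$n_a_only, ov$n_a)

  same <- overlap_sets(letters[1:5], letters[1:5])
  expect_equal(same$n_a_only, 0)
  expect_equal(same$n_b_only, 0)
})

test_that("the synaptosome reliability filter needs detection plus support", {
  refs <- list(c("a", "b", "c"), c("a", "c"), c("a", "d"))
  kept <- syn_reliability_filter(c("a", "b", "d", "e"), refs)
  expect_equal(kept, "a")             # detected + 3/3
  expect_false("b" %in% kept)         # detected but only 1/3
  expect_false("c" %in% kept)         # 2/3 but not detected
  expect_error(syn_reliability_filter("a", list()), "non-empty")
  expect_error(syn_reliability_filter("a", refs[1], min_support = 2),
               "fewer reference lists")
})
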