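test_that("counting-slice selection follows the anatomical rules", {
  lm <- list(bg_slice_index = 23L, ventricle_top_index = 40L)
  expect_equal(select_slice(lm, "BG"), 23L)
  # 1 cm above the ventricle top at 2 mm slices = 5 slices
  expect_equal(select_slice(lm, "CSO", slice_thickness_mm = 2), 45L)
  expect_equal(select_slice(lm, "CSO", slice_thickness_mm = 3), 44L)
  expect_warning(got <- select_slice(lm, "CSO", 2, n_slices = 42),
                 "clamped")
  expect_equal(got, 42L)
  expect_error(select_slice(list(), "BG"), "bg_slice_index")
  expect_error(select_slice(list(), "CSO"), "ventricle_top_index")
  # explicit landmark passes through unchanged
  expect_equal(select_slice(list(bg_slice_index = 7), "BG"), 7L)
})

test_that("slice counting matches the flood-fill oracle", {
  empty <- matrix(0, 12, 12)
  expect_equal(count_on_slice(empty), 0L)
  three <- matrix(0, 12, 12)
  three[2:3, 2:3] <- 1; three[8:9, 2:3] <- 1; three[5, 10] <- 1
  expect_equal(count_on_slice(three), 3L)
  # diagonal touch: one component at 8-connectivity, two at 4
  diagonal <- matrix(0, 4, 4)
  diagonal[1, 1] <- 1; diagonal[2, 2] <- 1
  expect_equal(count_on_slice(diagonal, connectivity = 8), 1L)
  expect_equal(count_on_slice(diagonal, connectivity = 4), 2L)
  # minimum-area filter
  expect_equal(count_on_slice(three, min_area = 2), 2L)

  set.seed(50)
  for (rep in 1:15) {
    m <- matrix(as.numeric(runif(20 * 20) < 0.25), 20, 20)
    expect_equal(count_on_slice(m, connectivity = 8),
                 flood_count_2d(m, 8))
    expect_equal(count_on_slice(m, connectivity = 4),
                 flood_count_2d(m, 4))
  }
  arr <- array(0, c(4, 4, 3)); arr[2, 2, 2] <- 1
  expect_equal(count_on_slice(arr, 2), 1L)
  expect_error(count_on_slice(arr, 9), "out of range")
})

test_that("phantom truth counts are reproduced on every slice", {
  sub <- phantom_subject(tiny_phantom_spec(seed = 55))
  tr <- sub$truth
  counts <- vapply(seq_len(dim(tr$mask)[3]), function(k) {
    count_on_slice(tr$mask, k, connectivity = 8)
  }, integer(1))
  expect_identical(counts, tr$per_slice_counts)
})

test_that("spearman handles perfect order, reversal, and ties", {
  r <- spearman_counts(c(3, 9, 14, 20), c(1, 2, 5, 9))
  expect_equal(r$rs, 1)
  expect_equal(spearman_counts(c(1, 2, 3), c(3, 2, 1))$rs, -1)

  set.seed(51)
  for (rep in 1:10) {
    x <- sample(0:5, 9, replace = TRUE)  # heavy ties
    y <- sample(0:5, 9, replace = TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    expect_equal(spearman_counts(x, y)$rs, spearman_oracle(x, y))
  }
  expect_error(spearman_counts(1:4, 1:5), "equal length")
  expect_error(spearman_counts(1:2, 2:1), "at least 3")
  expect_warning(rc <- spearman_counts(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_true(is.na(rc$rs))
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(52)
  x <- rpois(12, 8); y <- rpois(12, 8)
  base <- spearman_counts(x, y)$rs
  expect_equal(spearman_counts(exp(x / 3), y)$rs, base)
  expect_equal(spearman_counts(x, 5 * y + 2)$rs, base)
})

test_that("permutation and t-approximation p-values agree near n = 8", {
  set.seed(53)
  diffs <- replicate(12, {
    x <- sample(1:50, 8); y <- sample(1:50, 8)
    p_perm <- spearman_counts(x, y)$p_value
    rs <- spearman_oracle(x, y)
    tstat <- rs * sqrt((8 - 2) / (1 - rs^2))
    abs(p_perm - 2 * stats::pt(-abs(tstat), df = 6))
  })
  expect_lt(median(diffs), 0.02)
  expect_lt(max(diffs), 0.06)
})

test_that("agreement report relates model and rater counts per region", {
  counts <- expand.grid(subject_id = sprintf("s%02d", 1:10),
                        region = c("BG", "CSO"),
                        source = c("model", "rater1", "rater2"),
                        stringsAsFactors = FALSE)
  set.seed(54)
  base <- rpois(20, 12)
  counts$count <- base[as.integer(factor(paste(counts$subject_id,
                                               counts$region)))]
  rep <- agreement_report(counts)
  expect_true(all(rep$rs == 1))  # identical counts everywhere
  expect_setequal(unique(rep$kind), c("model_vs_rater", "rater_vs_rater"))
  expect_equal(nrow(rep), 6)  # (2 model-rater + 1 rater-rater) x 2 regions

  # independent counts decorrelate on average
  set.seed(55)
  nulls <- replicate(20, {
    spearman_counts(rpois(20, 10), rpois(20, 10))$rs
  })
  expect_lt(mean(abs(nulls)), 0.3)

  # missing subjects are excluded with a warning
  broken <- counts[!(counts$subject_id == "s01" & counts$source == "model"), ]
  w <- capture_warnings(rep2 <- agreement_report(broken))
  expect_true(length(w) > 0 && all(grepl("excluded", w)))
  expect_equal(min(rep2$n), 9)
})
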