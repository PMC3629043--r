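test_that("Bland-Altman bias and limits of agreement follow the definitions", {
  x <- c(3, 7, 12, 20, 33)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_half_width, 0)

  ba5 <- bland_altman(x, x + 5)
  expect_equal(ba5$bias, 5)
  expect_equal(ba5$loa_half_width, 0)

  ba <- bland_altman(c(0, 0), c(-1, 1))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_half_width, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_half_width, 2.771859, tolerance = 1e-6)

  expect_error(bland_altman(1, 2), "at least 2")
  expect_error(bland_altman(1:3, 1:4), "equal length")

  # recovery of an arbitrary constant shift, exactly
  set.seed(12)
  y <- rnorm(40)
  for (cc in c(-2.5, 0.4, 17)) {
    bac <- bland_altman(y, y + cc)
    expect_equal(bac$bias, cc)
    expect_equal(bac$loa_half_width, 0, tolerance = 1e-12)
  }
})

test_that("map correlation matches the covariance-ratio formula", {
  a <- margin_map(matrix(c(1, 4, 2, 8, 5, 7, 3, 6, 9), 3))
  expect_equal(map_correlation(a, a), 1)
  neg <- margin_map(-a$values)
  expect_equal(map_correlation(a, neg), -1)

  b <- margin_map(matrix(c(2, 2, 5, 7, 4, 9, 1, 3, 8), 3))
  av <- as.vector(a$values); bv <- as.vector(b$values)
  want <- sum((av - mean(av)) * (bv - mean(bv))) /
    sqrt(sum((av - mean(av))^2) * sum((bv - mean(bv))^2))
  expect_equal(map_correlation(a, b), want)

  expect_error(map_correlation(a, margin_map(matrix(1, 3, 3))), "constant")
  mask <- matrix(TRUE, 3, 3); mask[1, 1] <- FALSE
  expect_error(map_correlation(a, margin_map(b$values, mask)), "mask")
})

test_that("margin classification applies the pixel-fraction rule at the ratio threshold", {
  expect_equal(classify_margin(margin_map(matrix(0, 10, 10))), "positive")
  expect_equal(classify_margin(margin_map(matrix(10, 10, 10))), "negative")

  m <- matrix(1, 10, 10)
  m[1:3] <- 9          # 97 of 100 pixels below the threshold
  expect_equal(classify_margin(margin_map(m)), "negative")
  m[3] <- 1            # 98 of 100
  expect_equal(classify_margin(margin_map(m)), "positive")

  # monotone in the ratio threshold: raising it never flips positive -> negative
  set.seed(77)
  vals <- margin_map(matrix(runif(100, 0, 12), 10))
  cls <- vapply(seq(1, 12, by = 0.5), function(th) {
    classify_margin(vals, ratio_threshold = th)
  }, character(1))
  expect_false(any(cls == "positive" & c(cls[-1], "positive") == "negative"))

  empty <- margin_map(matrix(1, 2, 2), matrix(FALSE, 2, 2))
  expect_error(classify_margin(empty), "empty")
})

test_that("rank-sum comparison matches exhaustive enumeration on separated groups", {
  rs <- rank_sum_compare(c(1, 2, 3), c(10, 11, 12))
  # enumeration oracle: all choose(6, 3) assignments of pooled ranks
  pooled <- c(1, 2, 3, 10, 11, 12)
  combos <- utils::combn(6, 3)
  sums <- apply(combos, 2, function(ix) sum(rank(pooled)[ix]))
  expect_equal(rs$rank_sum, min(sums))
  expect_equal(rs$statistic, 0)
  # two-sided exact p under enumeration: both extreme tails
  p_exact <- mean(sums <= min(sums) | sums >= max(sums))
  expect_equal(p_exact, 0.1)
  expect_lte(rs$p_value, p_exact)

  # rank statistics are invariant under strictly monotone transforms
  rs2 <- rank_sum_compare(exp(c(1, 2, 3)), exp(c(10, 11, 12)))
  expect_equal(rs2$rank_sum, rs$rank_sum)
  expect_equal(rs2$p_value, rs$p_value)

  expect_equal(rank_sum_compare(c(4), c(4))$p_value, 1)
  expect_error(rank_sum_compare(numeric(0), 1), "nonempty")
})

test_that("a zero-bandpass full-grid study reproduces closure end to end", {
  params <- training_tissue_fixture()[c(2, 8, 13)]
  bs <- suppressWarnings(
    run_bandpass_study(params, sets = list(full = grid_wavelengths(tt_grid())),
                       fwhms = 0))
  expect_equal(nrow(bs$table), 1L)
  expect_lt(bs$table$mean_abs_error_pct, 0.5)
  expect_true(bs$table$acceptable)
  expect_equal(dim(bs$details[["full@0"]]), c(3L, 3L))
})

test_that("tissue-type error reports stratify signed and absolute means", {
  errs <- rbind(c(10, -10, 5), c(-10, -30, 5), c(2, 4, -6))
  colnames(errs) <- c("thb_uM", "bc_uM", "mean_musp")
  rep_ <- tissue_error_report(errs, c("adipose", "adipose", "malignant"))
  expect_equal(nrow(rep_), 6L)
  row <- rep_[rep_$tissue == "adipose" & rep_$parameter == "thb_uM", ]
  expect_equal(row$mean_signed_error_pct, 0)
  expect_equal(row$mean_abs_error_pct, 10)
})
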