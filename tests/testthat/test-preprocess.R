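test_that("Box-Cox transform matches its closed form, limit and inverse", {
  expect_equal(boxcox_transform(c(1, 2), transform_params(1, 0)), c(0, 1))
  # lam -> 0 logarithm limit
  expect_equal(boxcox_transform(1, transform_params(0, 0)), 0)
  expect_equal(boxcox_transform(c(0.5, 2), transform_params(1e-6, 0)),
               log(c(0.5, 2)), tolerance = 1e-5)
  expect_error(boxcox_transform(c(1, -2), transform_params(0.5, 0)), "> 0")
  # strict monotonicity / rank preservation for random valid params
  set.seed(1)
  for (i in 1:10) {
    p <- transform_params(runif(1, 0, 1.5), runif(1, 0, 0.2))
    x <- rexp(50)
    y <- boxcox_transform(x, p)
    expect_identical(order(y), order(x))
    expect_equal(boxcox_inverse(y, p), x, tolerance = 1e-10)
  }
})

test_that("calibration recovers the generating transform and rejects degenerate input", {
  # positions generated normal on the transformed scale, inverse-transformed
  # with known params; calibration should recover lam to +/- 0.1 and leave
  # near-zero median skewness (averaged over seeds for the lam recovery)
  gen <- transform_params(0.2, 0.05)
  lams <- vapply(1:4, function(seed) {
    set.seed(seed)
    pp <- lapply(1:120, function(i)
      boxcox_inverse(rnorm(60, runif(1, 0.5, 1.5), 0.1), gen))
    p <- calibrate_transform(pp)
    expect_lt(abs(p$median_skewness), 0.1)
    p$lam
  }, 1.0)
  expect_lt(abs(mean(lams) - gen$lam), 0.1)

  # feeding already-normal data: the chosen params do at least as well as
  # the identity point (lam = 1, shift = 0)
  set.seed(2)
  pp <- lapply(1:80, function(i) rnorm(40, 10, 0.5))
  p <- calibrate_transform(pp)
  sk <- function(x) { m <- mean(x); mean((x - m)^3) / mean((x - m)^2)^1.5 }
  at_identity <- abs(median(vapply(pp, sk, 1.0)))
  expect_lte(abs(p$median_skewness), at_identity + 1e-8)

  expect_error(calibrate_transform(lapply(1:60, function(i) rep(1, 20))),
               "constant")
  expect_error(calibrate_transform(list(rexp(100))), ">= 50 positions")
})

test_that("per-position moment profile uses raw moments and the coverage filter", {
  tab <- ipd_table(data.frame(
    ref_name = "c",
    position = rep(c(0L, 1L), c(5L, 3L)),
    strand = "+", movie_id = "m",
    ipd = c(1, 2, 3, 2, 2, 5, 6, 7)))
  prof <- skewness_kurtosis_profile(tab, transform_params(1, 0), min_cov = 5L)
  expect_equal(nrow(prof), 1L)          # position 1 below min_cov
  expect_equal(prof$position, 0L)
  # symmetric values have zero skewness
  p0 <- skewness_kurtosis_profile(
    ipd_table(data.frame(ref_name = "c", position = 0L, strand = "+",
                         movie_id = "m", ipd = c(2, 3, 4, 3, 3))),
    transform_params(1, 0), min_cov = 5L)
  expect_equal(p0$skewness, 0, tolerance = 1e-12)

  # on normal data the medians sit at the normal reference values (high
  # coverage: small-sample kurtosis bias decays like 1/n)
  set.seed(3)
  n_obs <- 1500L * 200L
  big <- ipd_table(data.frame(
    ref_name = "c", position = rep(seq_len(1500L) - 1L, each = 200L),
    strand = "+", movie_id = "m",
    ipd = exp(rnorm(n_obs))), scale = "raw")   # lognormal -> normal under log
  prof <- skewness_kurtosis_profile(big, transform_params(0, 0), min_cov = 5L)
  expect_gt(median(prof$skewness), -0.05)
  expect_lt(median(prof$skewness), 0.05)
  expect_gt(median(prof$kurtosis), 2.8)
  expect_lt(median(prof$kurtosis), 3.2)
})

test_that("movie centering is exact, idempotent, and separates batch shifts", {
  tab <- ipd_table(data.frame(ref_name = "c", position = 0:2, strand = "+",
                              movie_id = "m1", ipd = c(1, 2, 3)),
                   scale = "transformed")
  res <- normalize_movies(tab)
  expect_equal(res$table$ipd, c(-1, 0, 1))
  expect_equal(unname(res$offsets), 2)

  # two movies offset by a constant from a shared base signal
  base <- c(0.3, -0.1, 0.6, 0.2)
  two <- ipd_table(data.frame(
    ref_name = "c", position = rep(0:3, 2L), strand = "+",
    movie_id = rep(c("a", "b"), each = 4L),
    ipd = c(base, base + 0.7)), scale = "transformed")
  res2 <- normalize_movies(two)
  expect_equal(unname(diff(res2$offsets)), 0.7)
  expect_equal(res2$table$ipd[1:4], res2$table$ipd[5:8])

  # exactness and idempotence
  set.seed(4)
  big <- ipd_table(data.frame(
    ref_name = "c", position = sample(0:99, 3000, TRUE), strand = "+",
    movie_id = sample(sprintf("m%d", 1:6), 3000, TRUE),
    ipd = rnorm(3000)), scale = "transformed")
  c1 <- normalize_movies(big)
  percent <- tapply(c1$table$ipd, c1$table$movie_id, mean)
  expect_true(all(abs(percent) < 1e-12))
  c2 <- normalize_movies(c1$table)
  expect_equal(c2$table$ipd, c1$table$ipd, tolerance = 1e-12)
  expect_true(all(abs(c2$offsets) < 1e-12))

  # degenerate cases
  empty <- ipd_table(data.frame(ref_name = character(), position = integer(),
                                strand = character(), movie_id = character(),
                                ipd = numeric()), scale = "transformed")
  res0 <- normalize_movies(empty)
  expect_equal(nrow(res0$table), 0L)
  expect_length(res0$offsets, 0L)
  single <- ipd_table(data.frame(ref_name = "c", position = 0L, strand = "+",
                                 movie_id = "m", ipd = 5),
                      scale = "transformed")
  expect_warning(res1 <- normalize_movies(single), "single observation")
  expect_equal(res1$table$ipd, 0)
})

test_that("position rates honour coverage floors and strand separation", {
  tab <- ipd_table(data.frame(
    ref_name = "c", position = c(0L, 0L, 0L, 1L), strand = c("+", "+", "-", "+"),
    movie_id = "m", ipd = c(0.2, 0.4, 0.9, 0.5)), scale = "centered")
  r <- position_rates(tab)
  expect_equal(nrow(r), 3L)
  plus0 <- r[r$position == 0L & r$strand == "+", ]
  expect_equal(plus0$rate, 0.3)
  expect_equal(plus0$coverage, 2L)
  expect_equal(r$rate[r$strand == "-"], 0.9)

  # the >35-reads filter boundary: coverage 35 excluded at min_cov 36
  cov_tab <- ipd_table(data.frame(
    ref_name = "c", position = rep(c(0L, 1L), c(35L, 36L)), strand = "+",
    movie_id = "m", ipd = rnorm(71)), scale = "centered")
  r36 <- position_rates(cov_tab, min_cov = 36L)
  expect_equal(r36$position, 1L)
})

test_that("outlier removal is robust and conservative on clean data", {
  expect_equal(remove_outliers(c(0, 0, 0, 0, 100)), c(0, 0, 0, 0))
  expect_equal(remove_outliers(rep(2, 10)), rep(2, 10))   # MAD = 0 guard
  expect_equal(remove_outliers(c(1, 9, 3)), c(1, 9, 3))   # length < 4
  set.seed(5)
  x <- rnorm(1000)
  expect_lt(1 - length(remove_outliers(x)) / 1000, 0.01)
})
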