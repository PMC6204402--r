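test_that("weighted mean and SD match their worked examples", {
  # three equal-weight lots reduce to the plain mean
  expect_equal(weighted_mean(c(16.6, 19.4, 21.0), c(44, 44, 44)), 19)
  # vote expansion: mean/population-SD of (2, 4, 4, 4)
  expect_equal(weighted_mean(c(2, 4), c(1, 3)), 3.5)
  expect_equal(weighted_sd(c(2, 4), c(1, 3)), sqrt(3) / 2)
  expect_equal(weighted_sd(c(5, 5, 5), c(1, 2, 3)), 0)
  # equal weights give the population SD of the values
  x <- c(1.2, 3.4, 2.2, 0.4)
  expect_equal(weighted_sd(x, rep(7, 4)), sqrt(mean((x - mean(x))^2)))
})

test_that("weighted statistics equal the vote-expansion oracle", {
  set.seed(17)
  for (i in 1:300) {
    n <- sample(2:8, 1)
    x <- round(stats::runif(n, 0, 20), 3)
    w <- sample(1:50, n, replace = TRUE)
    expect_equal(weighted_mean(x, w), expanded_mean(x, w))
    expect_equal(weighted_sd(x, w), expanded_sd(x, w))
  }
})

test_that("weighted statistics are scale-invariant, bounded, monotone", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample(2:6, 1)
    x <- stats::runif(n, 0, 5)
    w <- stats::runif(n, 0.1, 10)
    expect_equal(weighted_mean(x, w * 3.7), weighted_mean(x, w))
    expect_equal(weighted_sd(x, w * 3.7), weighted_sd(x, w))
    m <- weighted_mean(x, w)
    expect_gte(m, min(x))
    expect_lte(m, max(x))
    # more weight on the largest value never lowers the mean
    w2 <- w
    w2[which.max(x)] <- w2[which.max(x)] + 1
    expect_gte(weighted_mean(x, w2), m - 1e-12)
  }
})

test_that("degenerate weight inputs are rejected", {
  expect_error(weighted_mean(1:3, 1:2), "equal length")
  expect_error(weighted_mean(1:2, c(0, 0)), "positive")
  expect_error(weighted_sd(1:2, c(-1, 2)), "non-negative")
})

test_that("group profiles pool lots with strain vote weights", {
  vals <- list(
    A = list(THC = c(16.6, 19.4, 21.0), Myrcene = c(0.3, 0.4, 0.5)),
    B = list(THC = c(14.0, 15.0, 16.0), Myrcene = c(0.2, 0.2, 0.2)),
    C = list(THC = c(10.0, 11.0, 12.0), Myrcene = c(0.1, 0.1, 0.4)),
    D = list(THC = c(19.8, 14.2, 20.1), Myrcene = c(0.6, 0.5, 0.4))
  )
  assays <- make_assays(vals)
  tally <- make_tally(c(A = 44, B = 39, C = 36, D = 33),
                      n_respondents = 219)
  prof <- build_group_profile(assays, tally, top_k = 4)
  thc <- prof[prof$analyte == "delta9-Tetrahydrocannabinol", ]
  expect_equal(thc$n_measurements, 12L)
  # oracle: each lot value replicated by its strain's votes
  x <- unlist(lapply(names(vals), function(s) vals[[s]]$THC))
  w <- rep(c(44, 39, 36, 33), each = 3)
  expect_equal(thc$weighted_mean, expanded_mean(x, w))
  expect_equal(thc$weighted_sd, expanded_sd(x, w))
  expect_equal(thc$weighted_se, expanded_sd(x, w) / sqrt(12))
  expect_equal(thc$n_eff, sum(w)^2 / sum(w^2))
  # the denominator is 3 x the vote total, seen through equal values
  ones <- make_assays(lapply(vals, function(v)
    list(THC = c(1, 1, 1))))
  p1 <- build_group_profile(ones, tally, top_k = 4)
  expect_equal(p1$weighted_mean[p1$analyte == "delta9-Tetrahydrocannabinol"],
               1)
})

test_that("not-tested cells drop their weight for that analyte only", {
  vals <- list(
    A = list(THC = c(16.6, 19.4, 21.0), Guaiol = c(0.1, NA, 0.3)),
    B = list(THC = c(14.0, 15.0, 16.0), Guaiol = c(0.2, 0.2, NA)),
    C = list(THC = c(10.0, 11.0, 12.0), Guaiol = c(0.1, 0.1, 0.1)),
    D = list(THC = c(19.8, 14.2, 20.1), Guaiol = c(0.4, 0.5, 0.6))
  )
  assays <- make_assays(vals)
  tally <- make_tally(c(A = 44, B = 39, C = 36, D = 33),
                      n_respondents = 219)
  prof <- build_group_profile(assays, tally, top_k = 4)
  gua <- prof[prof$analyte == "Guaiol", ]
  expect_equal(gua$n_measurements, 10L)
  x <- c(0.1, 0.3, 0.2, 0.2, 0.1, 0.1, 0.1, 0.4, 0.5, 0.6)
  w <- c(44, 44, 39, 39, 36, 36, 36, 33, 33, 33)
  expect_equal(gua$weighted_mean, expanded_mean(x, w))
  # the fully measured analyte is untouched
  thc <- prof[prof$analyte == "delta9-Tetrahydrocannabinol", ]
  expect_equal(thc$n_measurements, 12L)
  # as_zero sensitivity mode treats the two cells as measured zeros
  prof0 <- build_group_profile(assays, tally, top_k = 4,
                               missing = "as_zero")
  gua0 <- prof0[prof0$analyte == "Guaiol", ]
  expect_equal(gua0$n_measurements, 12L)
  expect_equal(gua0$weighted_mean,
               expanded_mean(c(0.1, 0, 0.3, 0.2, 0.2, 0, 0.1, 0.1, 0.1,
                               0.4, 0.5, 0.6),
                             rep(c(44, 39, 36, 33), each = 3)))
})

test_that("an analyte tested nowhere is flagged absent, not zero", {
  vals <- list(
    A = list(THC = c(1, 2), Cedrol = c(NA, NA)),
    B = list(THC = c(3, 4), Cedrol = c(NA, NA))
  )
  assays <- make_assays(vals)
  tally <- make_tally(c(A = 10, B = 5), n_respondents = 15)
  prof <- build_group_profile(assays, tally, top_k = 2)
  ced <- prof[prof$analyte == "Cedrol", ]
  expect_equal(ced$n_measurements, 0L)
  expect_true(is.na(ced$weighted_mean))
})

test_that("profiles require enough voted strains with assays", {
  assays <- make_assays(list(A = list(THC = c(1, 2))))
  expect_error(
    build_group_profile(assays, make_tally(c(A = 3), 5), top_k = 4),
    "top-4")
  expect_error(
    build_group_profile(assays, make_tally(c(A = 3, B = 2), 5), top_k = 2),
    "B")
})
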