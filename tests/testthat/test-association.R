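test_that("difference-over-sum coefficient matches published pairs", {
  expect_equal(round(correlation_coefficient(18.01, 13.67), 3), 0.137)
  expect_equal(round(correlation_coefficient(0.075, 2.62), 3), -0.944)
  expect_equal(round(correlation_coefficient(1.850, 1.621), 3), 0.066)
  expect_equal(correlation_coefficient(0, 0.069), -1)
  expect_equal(correlation_coefficient(0.013, 0), 1)
  expect_true(is.na(correlation_coefficient(0, 0)))
  expect_equal(correlation_coefficient(3.14, 3.14), 0)
  expect_error(correlation_coefficient(-0.1, 2), "non-negative")
})

test_that("coefficient properties hold over a random sweep", {
  set.seed(41)
  a <- stats::runif(500, 0, 20)
  b <- stats::runif(500, 0, 20)
  cc <- correlation_coefficient(a, b)
  expect_true(all(cc >= -1 & cc <= 1))
  # antisymmetry and scale invariance
  expect_equal(correlation_coefficient(b, a), -cc)
  expect_equal(correlation_coefficient(3.7 * a, 3.7 * b), cc)
  # the +/-1 boundary occurs exactly when one side is zero
  expect_equal(correlation_coefficient(a, rep(0, 500)), rep(1, 500))
  expect_equal(correlation_coefficient(rep(0, 500), b), rep(-1, 500))
  expect_true(all(abs(cc) < 1))
})

test_that("summary-level Welch test matches the closed-form example", {
  res <- difference_of_means_test(5, 1, 12, 4, 1, 12)
  expect_equal(res$t_stat, sqrt(6), tolerance = 1e-12)
  expect_equal(res$df, 22)
  expect_equal(res$p_value, 2 * stats::pt(-sqrt(6), 22))
  expect_equal(round(res$p_value, 4), 0.0227)
})

test_that("test identities: null, antisymmetry, degenerate variance", {
  id <- difference_of_means_test(3.3, 0.7, 9, 3.3, 0.7, 9)
  expect_equal(id$t_stat, 0)
  expect_equal(id$p_value, 1)
  set.seed(43)
  for (i in 1:50) {
    m <- stats::runif(2, 0, 10)
    s <- stats::runif(2, 0.1, 2)
    n <- sample(2:30, 2, replace = TRUE)
    f <- difference_of_means_test(m[1], s[1], n[1], m[2], s[2], n[2])
    r <- difference_of_means_test(m[2], s[2], n[2], m[1], s[1], n[1])
    expect_equal(r$t_stat, -f$t_stat)
    expect_equal(r$p_value, f$p_value)
    expect_equal(r$df, f$df)
  }
  deg <- difference_of_means_test(2, 0, 5, 1, 0, 5)
  expect_equal(deg$p_value, 0)
  expect_true(deg$degenerate)
  same <- difference_of_means_test(2, 0, 5, 2, 0, 5)
  expect_equal(same$p_value, 1)
  expect_false(same$degenerate)
  expect_error(difference_of_means_test(1, 1, 1, 2, 1, 12), "at least 2")
})

make_profiles <- function() {
  vals_me <- list(
    A = list(THC = c(16, 19, 21), Guaiol = c(0, 0, 0),
             Myrcene = c(0.3, 0.4, 0.35), Cedrol = c(0, 0, 0)),
    B = list(THC = c(17, 18, 19), Guaiol = c(0, 0, 0),
             Myrcene = c(0.2, 0.25, 0.3), Cedrol = c(0, 0, 0))
  )
  vals_le <- list(
    C = list(THC = c(12, 13, 14), Guaiol = c(0.06, 0.07, 0.08),
             Myrcene = c(0.5, 0.45, 0.55), Cedrol = c(0, 0, 0)),
    D = list(THC = c(13, 14, 15), Guaiol = c(0.05, 0.06, 0.07),
             Myrcene = c(0.4, 0.5, 0.6), Cedrol = c(0, 0, 0))
  )
  list(
    me = build_group_profile(make_assays(vals_me),
                             make_tally(c(A = 40, B = 30), 100), top_k = 2),
    le = build_group_profile(make_assays(vals_le),
                             make_tally(c(C = 20, D = 10), 80,
                                        category = "least_effective"),
                             top_k = 2)
  )
}

test_that("association table classifies rows and flags significance", {
  p <- make_profiles()
  tab <- build_association_table(p$me, p$le)
  expect_s3_class(tab, "association_tbl")
  expect_equal(tab$analyte, analyte_panel()$analyte)
  thc <- tab[tab$analyte == "delta9-Tetrahydrocannabinol", ]
  expect_equal(thc$status, "valid")
  expect_equal(thc$cc, correlation_coefficient(thc$wa_me, thc$wa_le))
  expect_true(thc$significant)
  # absent from most-effective only: cc exactly -1
  gua <- tab[tab$analyte == "Guaiol", ]
  expect_equal(gua$cc, -1)
  # measured zero in both groups: no coefficient, no test
  ced <- tab[tab$analyte == "Cedrol", ]
  expect_equal(ced$status, "NA_zero_both")
  expect_true(is.na(ced$cc) && is.na(ced$p_value))
  expect_false(ced$significant)
  # analytes never assayed are insufficient_data
  lin <- tab[tab$analyte == "Linalool", ]
  expect_equal(lin$status, "insufficient_data")
  # alpha = 0 flags nothing
  tab0 <- build_association_table(p$me, p$le, alpha = 0,
                                  marginal_band = 1e-9)
  expect_false(any(tab0$significant))
})

test_that("association requires matching panels", {
  p <- make_profiles()
  short <- p$le[p$le$analyte != "Guaiol", ]
  expect_error(build_association_table(p$me, short), "Guaiol")
})

test_that("adjusted p-values cover exactly the valid rows", {
  p <- make_profiles()
  tab <- build_association_table(p$me, p$le)
  valid <- tab$status == "valid"
  expect_true(all(!is.na(tab$p_adjusted[valid])))
  expect_true(all(is.na(tab$p_adjusted[!valid])))
  expect_equal(tab$p_adjusted[valid],
               stats::p.adjust(tab$p_value[valid], method = "BH"))
})

test_that("terpene partition splits on the concentration threshold", {
  p <- make_profiles()
  tab <- build_association_table(p$me, p$le)
  part <- partition_terpenes(tab, threshold = 0.05)
  expect_true("Myrcene" %in% part$major)     # ~0.5 in least effective
  expect_true("Guaiol" %in% part$major)      # 0.065 > 0.05 on one side
  expect_true("Linalool" %in% part$minor)
  # cannabinoids and the aggregate never partition
  expect_false(any(c("delta9-Tetrahydrocannabinol", "Total terpenes") %in%
                     c(part$major, part$minor)))
  expect_length(intersect(part$major, part$minor), 0)
  # a threshold above every value empties the major set
  expect_length(partition_terpenes(tab, threshold = 99)$major, 0)
})

test_that("published-magnitude partition examples fall on the right side", {
  # trans-nerolidol (0.444, 0.146) is major; eucalyptol (0.000, 0.005) minor
  expect_true(max(0.444, 0.146) > 0.05)
  p <- make_profiles()
  tab <- build_association_table(p$me, p$le)
  tab$wa_me[tab$analyte == "trans-Nerolidol"] <- 0.444
  tab$wa_le[tab$analyte == "trans-Nerolidol"] <- 0.146
  tab$wa_me[tab$analyte == "Eucalyptol"] <- 0
  tab$wa_le[tab$analyte == "Eucalyptol"] <- 0.005
  part <- partition_terpenes(tab, threshold = 0.05)
  expect_true("trans-Nerolidol" %in% part$major)
  expect_true("Eucalyptol" %in% part$minor)
})
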