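# The exact two-library statistic, fold changes, FDR and the DE call.

test_that("poisson_pmf matches closed forms and sums to one", {
  expect_identical(poisson_pmf(0, 0), 1)
  expect_equal(poisson_pmf(0, 2), exp(-2))
  expect_equal(poisson_pmf(3, 2), 0.1804470443154836)
  expect_equal(sum(poisson_pmf(0:200, 13.7)), 1, tolerance = 1e-12)
  expect_error(poisson_pmf(-1, 2))
  expect_error(poisson_pmf(2, -1))
})

test_that("conditional pmf and cumulative match exact rational values", {
  # values computed once with exact rational arithmetic
  expect_equal(ac_pmf(5, 5, 1e6, 1e6), 252 / 2048, tolerance = 1e-12)
  expect_equal(ac_pmf(2, 3, 100, 200), 80 / 729, tolerance = 1e-12)
  expect_equal(ac_pmf(0, 0, 7, 7), 0.5, tolerance = 1e-15)
  expect_equal(ac_cumulative(10, 0, 1e6, 1e6), 1 / 2048, tolerance = 1e-12)
  expect_equal(ac_cumulative(0, 0, 5e5, 5e5), 0.5, tolerance = 1e-15)
  expect_equal(ac_cumulative(5, 5, 1e6, 1e6), 0.5, tolerance = 1e-12)

  frozen <- data.frame(
    x = c(7, 13, 50, 0, 25, 40, 3),
    y = c(13, 7, 50, 17, 3, 12, 49),
    n1 = c(3, 3, 1, 2, 1, 1, 1) * 1e6,
    n2 = c(1, 1, 3, 1, 2, 1, 3) * 1e6,
    pmf = c(1.15644234028877690e-04, 8.43046466070518363e-02,
            1.12682771877159570e-08, 5.16234958342639412e-09,
            3.81871716378033357e-10, 2.29127169315557211e-05,
            6.51859823283089672e-05),
    cum = c(9.99931940175883938e-01, 8.70086594208260067e-01,
            3.25801932716186407e-08, 9.99999997418825171e-01,
            4.50456506098401251e-10, 4.08566749963146236e-05,
            9.99751667953656775e-01))
  for (i in seq_len(nrow(frozen))) {
    expect_equal(ac_pmf(frozen$x[i], frozen$y[i], frozen$n1[i], frozen$n2[i]),
                 frozen$pmf[i], tolerance = 1e-12)
    expect_equal(ac_cumulative(frozen$x[i], frozen$y[i], frozen$n1[i],
                               frozen$n2[i]),
                 frozen$cum[i], tolerance = 1e-12)
  }
})

test_that("log-space evaluation agrees with the negative-binomial reference", {
  # p(y|x) is NB(size = x+1, prob = N1/(N1+N2)); an independent code path
  for (r in c(1/3, 1/2, 1, 2, 3)) {
    n1 <- 3e6; n2 <- r * 3e6
    x <- rep(0:50, each = 6)
    y <- rep(c(0, 1, 7, 19, 33, 50), 51)
    expect_equal(ac_pmf(x, y, n1, n2), nb_pmf(x, y, n1, n2),
                 tolerance = 1e-12)
    expect_equal(ac_cumulative(x, y, n1, n2), nb_cdf(x, y, n1, n2),
                 tolerance = 1e-12)
  }
})

test_that("conditional pmf normalizes over y with an adaptive tail", {
  for (x in c(0, 1, 7, 33, 100)) {
    for (r in c(0.5, 1, 2)) {
      n1 <- 1e6; n2 <- r * 1e6
      y_max <- ceiling(r * (x + 1) + 40 * sqrt(r * (x + 1) + 1) + 50)
      s <- ac_cumulative(x, y_max, n1, n2)
      expect_lt(abs(s - 1), 1e-9)
    }
  }
})

test_that("pmf contract holds deep into the large-count regime", {
  p <- ac_pmf(1e6, 1e6, 5e6, 5e6)
  expect_true(is.finite(p) && p > 0 && p < 1)
})

test_that("two-sided doubling rule: symmetry, exact unity, monotonicity", {
  for (x in c(0, 1, 5, 17, 50))
    expect_identical(ac_two_sided_p(x, x, 1e6, 1e6), 1)
  expect_equal(ac_two_sided_p(10, 0, 1e6, 1e6), 2 / 2048, tolerance = 1e-12)
  # symmetric in (x, y) with equal library sizes
  for (i in 1:20) {
    x <- (i * 7) %% 41; y <- (i * 13) %% 37
    expect_equal(ac_two_sided_p(x, y, 2e6, 2e6),
                 ac_two_sided_p(y, x, 2e6, 2e6), tolerance = 1e-10)
  }
  # decreases as y moves away from its conditional expectation, x fixed
  x <- 20
  p_up <- ac_two_sided_p(x, 20:60, 1e6, 1e6)
  expect_true(all(diff(p_up) < 0))
  p_dn <- ac_two_sided_p(x, 20:0, 1e6, 1e6)
  expect_true(all(diff(p_dn) < 0))
  # valid probabilities throughout
  expect_true(all(p_up > 0 & p_up <= 1))
})

test_that("small upper-branch p-values keep relative accuracy", {
  # upper tail summed directly, not as 1 - cumulative
  p <- ac_two_sided_p(0, 60, 1e6, 1e6)
  exact <- 2 * (1 - nb_cdf(0, 59, 1e6, 1e6))  # 2 * 2^-60
  expect_equal(p, exact, tolerance = 1e-10)
  expect_lt(p, 1e-15)
})

test_that("fold change normalizes by library size and handles zeros", {
  expect_equal(fold_change(30, 10, 1000, 1000, pseudocount = 0), 3)
  expect_equal(fold_change(10, 10, 2000, 1000, pseudocount = 0), 0.5)
  expect_equal(fold_change(0, 10, 1000, 1000, pseudocount = 0.5), 0.5 / 10.5)
  # pseudocount only engages when a zero is present
  expect_equal(fold_change(30, 10, 1000, 1000, pseudocount = 0.5), 3)
  expect_error(fold_change(0, 10, 1000, 1000, pseudocount = 0),
               "zero count")
  expect_error(fold_change(-1, 10, 1000, 1000))
  expect_error(fold_change(10, 2000, 1000, 1000), "exceed")
})

test_that("benjamini_hochberg matches an independent step-up oracle", {
  expect_equal(benjamini_hochberg(0.05), 0.05)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(rep(0.2, 7)), rep(0.2, 7))
  set.seed(11)
  for (i in 1:5) {
    p <- runif(50)^2
    expect_equal(benjamini_hochberg(p), bh_oracle(p))
  }
  expect_error(benjamini_hochberg(numeric(0)))
  expect_error(benjamini_hochberg(c(0.5, 1.5)))
})

test_that("ac_test applies the strict more-than-twofold rule with FDR", {
  cts <- make_counts(x = c(500, 100, 60, 10),
                     y = c(100, 100, 29, 40))
  fit <- ac_test(cts, n1 = 1e5, n2 = 1e5)
  tab <- fit$table
  expect_s3_class(fit, "ac_test")
  expect_equal(tab$fold_change, c(5, 1, 60 / 29, 0.25))
  expect_equal(tab$direction, c("up", "none", "up", "down"))
  # g3 has fold just above 2 but weak evidence is irrelevant here: check the
  # boundary explicitly instead
  at_two <- ac_test(make_counts(2000, 1000), n1 = 1e5, n2 = 1e5)
  expect_false(at_two$table$is_de)   # exactly 2.0 is not "more than twofold"
  expect_true(tab$is_de[1])
  expect_true(tab$is_de[4])
  expect_false(tab$is_de[2])
})

test_that("ac_test on identical libraries is the null identity", {
  x <- c(10, 200, 3000, 0, 57)
  fit <- ac_test(make_counts(x, x), n1 = 1e6, n2 = 1e6)
  expect_true(all(fit$table$p_two_sided == 1))
  expect_true(all(!fit$table$is_de))
  expect_true(all(fit$table$fold_change == 1))
})

test_that("ac_test validates its inputs", {
  expect_error(ac_test(make_counts(c(1, 2), c(3, 4), ids = c("a", "a"))),
               "duplicate")
  expect_error(ac_test(make_counts(1, 2), fold_threshold = 1))
  expect_error(ac_test(data.frame(bad = 1)))
})

test_that("ac_test methods print, summarize and convert", {
  fit <- ac_test(make_counts(c(500, 10), c(100, 10)), n1 = 1e4, n2 = 1e4)
  expect_output(print(fit), "2 genes")
  expect_output(print(summary(fit)), "up-")
  expect_identical(as.data.frame(fit), fit$table)
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
  unlink(f)
})

test_that("alpha = 1 reduces the call to the pure fold rule", {
  cts <- make_counts(x = c(9, 300), y = c(4, 310))
  fit <- ac_test(cts, n1 = 1e6, n2 = 1e6, alpha = 1)
  expect_equal(fit$table$is_de, c(TRUE, FALSE))
})
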