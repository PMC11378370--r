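test_that("Welch's test handles identical groups and matches t.test on raw data", {
  same <- list(n = 10, ave = 1.5, sd = 0.2)
  w <- welch_test(same, same)
  expect_identical(w$t, 0)
  expect_identical(w$p, 1)
  expect_error(welch_test(list(n = 1, ave = 0, sd = 1), same), "n >= 2")

  set.seed(12)
  for (rep in 1:20) {
    x <- rnorm(sample(5:40, 1), 0, runif(1, 0.5, 2))
    y <- rnorm(sample(5:40, 1), runif(1, -1, 1), runif(1, 0.5, 2))
    w <- welch_test(x, y)
    ref <- stats::t.test(x, y)
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(w$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Welch's test matches the arbitrary-precision reference from summaries", {
  set.seed(8)
  n1 <- sample(5:500, 300, replace = TRUE)
  n2 <- sample(5:500, 300, replace = TRUE)
  m1 <- runif(300, -1, 1); m2 <- m1 + runif(300, -0.5, 0.5)
  s1 <- runif(300, 0.1, 2); s2 <- runif(300, 0.1, 2)
  ref <- welch_reference(n1, m1, s1, n2, m2, s2)
  for (i in seq_len(300)) {
    w <- welch_test(list(n = n1[i], ave = m1[i], sd = s1[i]),
                    list(n = n2[i], ave = m2[i], sd = s2[i]))
    expect_equal(w$t, ref$t[i], tolerance = 1e-10)
    expect_equal(w$p, ref$p[i], tolerance = 1e-8)
  }
})

test_that("the binomial trend test gives exact tails and sane degenerate cases", {
  ## symmetric null: as many extends as shrinks can never look like a trend
  expect_gte(binomial_trend_test(10, 10, 0.5)$p, 0.5)
  ## frozen exact value: P(X >= 24 | n = 27, p = 1/2) = 3304 / 2^27
  t1 <- binomial_trend_test(24, 3, 0.5)
  expect_equal(t1$p, 3304 / 2^27, tolerance = 1e-12)
  ## strong extension trend is detected under any plausible background
  expect_lt(binomial_trend_test(83, 21, 0.55)$p, 1e-6)
  expect_lt(binomial_trend_test(83, 21, c(extend = 10, shrink = 10))$p, 1e-6)
  ## background from tallies uses half pseudo-counts
  t2 <- binomial_trend_test(5, 5, c(extend = 0, shrink = 10))
  expect_equal(t2$p0, 0.5 / 11)
  expect_error(binomial_trend_test(0, 0, 0.5), "zero trials")
})

test_that("the Kozak trend test treats appearances as successes", {
  expect_gte(kozak_trend_test(10, 10, 0.5)$p, 0.5)
  ## an excess of disappearances gives no appearance trend at all
  t <- kozak_trend_test(78, 227, 0.5)
  expect_gt(t$p, 0.999)
  expect_error(kozak_trend_test(0, 0, 0.5), "zero trials")
  expect_identical(kozak_trend_test(3, 7, c(appear = 4, disappear = 4))$p0,
                   binomial_trend_test(3, 7, c(extend = 4, shrink = 4))$p0)
})

test_that("the scenario report keeps the fixed stage order and rejects gaps", {
  wt <- welch_test(list(n = 50, ave = 0.38, sd = 0.08),
                   list(n = 200, ave = 0.31, sd = 0.05))
  nt <- welch_test(list(n = 50, ave = 3.0, sd = 2.0),
                   list(n = 200, ave = 3.1, sd = 2.0))
  tt <- binomial_trend_test(40, 5, 0.5)
  kt <- kozak_trend_test(4, 5, 0.5)
  rep <- build_report(list(S1 = wt), list(S1 = list(transition = nt)),
                      list(`S1 ATG` = tt), list(`S1 A..ATG` = kt))
  labs <- vapply(rep$stages, `[[`, "", "label")
  expect_identical(vapply(rep$stages, `[[`, 1L, "stage"), 1:4)
  expect_match(labs[1], "GC-rich")
  expect_match(labs[2], "neutral")
  expect_match(labs[3], "extension")
  expect_match(labs[4], "Kozak")
  expect_true(rep$stages[[1]]$supported)
  expect_true(rep$stages[[2]]$supported)   # non-significant = neutral
  expect_true(rep$stages[[3]]$supported)
  expect_false(rep$stages[[4]]$supported)  # Kozak recruitment comes later
  expect_error(build_report(list(), list(a = nt), list(a = tt), list(a = kt)),
               "incomplete")
})

test_that("the published GC summary tables load with the printed group sizes", {
  ext <- gc_reference_summary("extant")
  expect_identical(ext$n[ext$region == "intergene"], 6006L)
  a1 <- gc_reference_summary("A1")
  expect_identical(a1$n[a1$region == "intergene"], 5283L)
  expect_identical(nrow(gc_reference_summary("A2")), 4L)
})
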