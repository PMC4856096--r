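test_that("testcross and selfing expectations follow the gamete algebra", {
  expect_equal(testcross_freq(0.5), c(H = 0.5, JJ = 0.5))
  expect_equal(testcross_freq(0.89), c(H = 0.89, JJ = 0.11))
  expect_equal(testcross_freq(1), c(H = 1, JJ = 0))
  expect_error(testcross_freq(1.2), "k must")

  expect_equal(unclass(selfing_freq(0.5)), c(II = 0.25, H = 0.5, JJ = 0.25))
  # derived by enumerating the 2x2 gamete table at k = 0.89
  expect_equal(unclass(selfing_freq(0.89)), c(II = 0.445, H = 0.5, JJ = 0.055))
  for (k in seq(0.5, 1, by = 0.1)) {
    p <- selfing_freq(k)
    expect_equal(p[["H"]], 0.5) # female side is Mendelian for every k
    expect_equal(sum(p), 1)
  }
})

test_that("SSD recursion halves heterozygosity and converges to (k, 0, 1-k)", {
  expect_equal(unclass(ssd_freq(0.89, 0)), c(II = 0, H = 1, JJ = 0))
  expect_equal(unclass(ssd_freq(0.89, 1)), unclass(selfing_freq(0.89)))
  for (k in seq(0.5, 1, by = 0.1)) {
    for (g in c(1, 2, 5, 13)) {
      p <- ssd_freq(k, g)
      expect_identical(p[["H"]], 2^-g) # exact halving each generation
      # closed form for the fixed classes
      expect_equal(p[["II"]], k * (1 - 2^-g))
      expect_equal(p[["JJ"]], (1 - k) * (1 - 2^-g))
      expect_equal(sum(p), 1)
    }
    expect_true(max(abs(ssd_freq(k, 20) - ssd_freq(k, Inf))) < 1e-6)
  }
  expect_equal(unclass(ssd_freq(0.89, Inf)), c(II = 0.89, H = 0, JJ = 0.11))
  expect_error(ssd_freq(0.89, -1), "generations")
})

test_that("RI fixation counts use round-half-away-from-zero", {
  expect_equal(ri_fixation(0.89, 148), c(II = 132L, JJ = 16L))
  expect_equal(ri_fixation(0.5, 100), c(II = 50L, JJ = 50L))
  expect_equal(ri_fixation(0.75, 8), c(II = 6L, JJ = 2L))
  expect_error(ri_fixation(0.89, 0), "n_lines")
})

test_that("k estimation matches the paper-scale testcross counts", {
  est1 <- estimate_k(count_data(n_H = 134, n_JJ = 17), "testcross")
  expect_equal(round(est1$k_hat, 2), 0.89)
  est2 <- estimate_k(count_data(n_H = 43, n_JJ = 28), "testcross")
  expect_equal(round(est2$k_hat, 2), 0.61)
  expect_true(est1$ci_low <= est1$k_hat && est1$k_hat <= est1$ci_high)
  expect_equal(est1$n, 151L)
})

test_that("estimate_k is the identity on expected counts over a k grid", {
  for (k in seq(0.5, 1, by = 0.1)) {
    # testcross at n = 200: expected counts are integers on this grid
    tc <- estimate_k(count_data(n_H = 200 * k, n_JJ = 200 * (1 - k)), "testcross")
    expect_equal(tc$k_hat, k)
    # selfing at n = 200: n_II = 100 k, n_H = 100, n_JJ = 100 (1 - k)
    sf <- estimate_k(count_data(n_II = 100 * k, n_H = 100,
                                n_JJ = 100 * (1 - k)), "selfing")
    expect_equal(sf$k_hat, k)
  }
})

test_that("selfing estimator ignores heterozygotes and errors without information", {
  a <- estimate_k(count_data(n_II = 89, n_H = 100, n_JJ = 11), "selfing")
  b <- estimate_k(count_data(n_II = 89, n_H = 5, n_JJ = 11), "selfing")
  expect_equal(a$k_hat, b$k_hat)
  expect_error(estimate_k(count_data(n_H = 50), "selfing"), "informative")
  # boundary estimates keep the CI inside [0, 1]
  e0 <- estimate_k(count_data(n_H = 20, n_JJ = 0), "testcross")
  expect_equal(e0$k_hat, 1)
  expect_equal(e0$ci_high, 1)
})

test_that("Clopper-Pearson interval widens as confidence grows", {
  cd <- count_data(n_H = 134, n_JJ = 17)
  w <- vapply(c(0.8, 0.95, 0.99), function(cl) {
    e <- estimate_k(cd, "testcross", conf_level = cl)
    e$ci_high - e$ci_low
  }, numeric(1))
  expect_true(all(diff(w) > 0))
})

test_that("Pearson goodness of fit matches the longhand formula", {
  expect_equal(gof_test(c(75, 75), c(1, 1))$statistic, 0)
  expect_equal(gof_test(c(75, 75), c(1, 1))$p_value, 1)
  expect_equal(round(gof_test(c(17, 134), c(1, 1))$statistic, 2), 90.66)
  expect_equal(gof_test(c(25, 50, 25), c(1, 2, 1))$statistic, 0)
  set.seed(7)
  for (rep in 1:50) {
    m <- sample(2:4, 1)
    obs <- rmultinom(1, sample(20:300, 1), prob = runif(m, 0.1, 1))[, 1]
    ratio <- sample(1:4, m, replace = TRUE)
    g <- gof_test(obs, ratio)
    expect_equal(g$statistic, oracle_pearson(obs, ratio))
    expect_identical(g$df, m - 1L)
  }
  expect_error(gof_test(c(1, 2, 3), c(1, 1)), "same number")
  expect_error(gof_test(c(1, 2), c(1, 0)), "ratio")
})

test_that("exact multinomial p equals full enumeration for small totals", {
  set.seed(11)
  cases <- list(
    list(obs = c(3, 9), ratio = c(1, 1)),
    list(obs = c(17, 3), ratio = c(3, 1)),
    list(obs = c(2, 11, 4), ratio = c(1, 2, 1)),
    list(obs = c(10, 10, 10), ratio = c(1, 2, 1))
  )
  for (rep in 1:10) {
    m <- sample(2:3, 1)
    n <- sample(5:30, 1)
    ratio <- sample(1:3, m, replace = TRUE)
    obs <- rmultinom(1, n, ratio / sum(ratio))[, 1]
    cases <- c(cases, list(list(obs = obs, ratio = ratio)))
  }
  for (cs in cases) {
    probs <- cs$ratio / sum(cs$ratio)
    expect_equal(
      gof_test(cs$obs, cs$ratio, "exact_multinomial")$p_value,
      oracle_exact_multinomial(cs$obs, probs),
      tolerance = 1e-12
    )
  }
})

test_that("exact and Pearson p-values converge for large totals under 1:1", {
  # Exhaustive sweep at n = 200: the worst disagreement (~0.056) sits at the
  # counts adjacent to the centre, where the exact test drops the centre
  # point mass while the asymptotic chi-square does not; away from there the
  # two agree to ~0.02, and the worst case shrinks with n.
  disagreement <- function(n) {
    pr <- dbinom(0:n, n, 0.5)
    vapply(0:n, function(x) {
      exact <- sum(pr[pr <= pr[x + 1] * (1 + 1e-7)])
      abs(min(exact, 1) - gof_test(c(x, n - x), c(1, 1))$p_value)
    }, numeric(1))
  }
  d200 <- disagreement(200)
  expect_lt(max(d200), 0.06)
  expect_lt(stats::median(d200), 0.02)
  expect_lt(max(disagreement(400)), max(d200))
})

test_that("count and frequency helpers validate and normalise", {
  expect_error(count_data(), "positive")
  expect_error(count_data(n_H = -1, n_JJ = 5), "non-negative")
  f <- genotype_frequencies(count_data(27, 100, 25))
  expect_equal(sum(f), 1)
  expect_equal(genotype_class_percent(27, 225), 12)
  expect_equal(round(genotype_class_percent(31, 161), 1), 19.3)
  expect_error(genotype_class_percent(5, 0))
})
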