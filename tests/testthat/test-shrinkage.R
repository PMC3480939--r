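# Robust scale estimation, shrinkage splits, and the adaptive threshold loop.

test_that("madn matches hand calculations and is unbiased for normal data", {
  expect_identical(madn(c(5, 5, 5)), 0)
  expect_equal(madn(c(1, 2, 3, 4, 100)), 1 / 0.6745)
  set.seed(3)
  expect_equal(madn(rnorm(1e5)), 1, tolerance = 0.02)
  expect_error(madn(numeric(0)), "non-empty")
})

test_that("universal threshold follows the closed form and scales linearly", {
  x <- rep(c(-1, 1), 64) * 0.6745       # madn = 1 by construction
  expect_equal(madn(x), 1)
  expect_equal(universal_threshold(x), sqrt(2 * log(128)))  # ~3.1151
  set.seed(8)
  y <- rnorm(128)
  expect_equal(universal_threshold(3 * y), 3 * universal_threshold(y))
  expect_identical(universal_threshold(numeric(128)), 0)
  expect_error(universal_threshold(1), "at least 2")
})

test_that("shrinkage functions reproduce their defining formulas", {
  for (kind in c("hard", "soft", "garrote", "sbss")) {
    s <- shrink_coefficients(0.5, T = 1, kind = kind)
    expect_identical(s$a_bar, 0)      # sub-threshold passthrough, all kinds
    expect_identical(s$a_ring, 0.5)
  }
  g <- shrink_coefficients(2, T = 1, kind = "garrote")
  expect_equal(g$a_bar, 1.5)          # x - T^2/x
  expect_equal(g$a_ring, 0.5)
  so <- shrink_coefficients(3, T = 1, kind = "soft")
  expect_equal(so$a_bar, 2)
  expect_equal(so$a_ring, 1)          # signal clipped at T
  h <- shrink_coefficients(c(-3, 3), T = 1, kind = "hard")
  expect_equal(h$a_bar, c(-3, 3))
  # garrote at the origin with T = 0 is defined as 0
  expect_identical(shrink_coefficients(0, T = 0, kind = "garrote")$a_bar, 0)
})

test_that("split conservation a = a_bar + a_ring holds exactly", {
  set.seed(21)
  for (i in 1:20) {
    a <- rnorm(256, sd = runif(1, 0.1, 20))
    T <- runif(1, 0, 3)
    for (kind in c("hard", "soft", "garrote", "sbss")) {
      s <- shrink_coefficients(a, T, kind, lambda = 2 * T, tau = runif(1, 0.1, 5))
      # a_ring is defined as a - a_bar, so the split is conservative by
      # construction (up to one floating-point rounding)
      expect_equal(s$a_bar + s$a_ring, a, tolerance = 1e-14)
    }
  }
})

test_that("retained signal power is monotone non-increasing as T decreases", {
  set.seed(33)
  for (i in 1:10) {
    a <- rnorm(128, sd = runif(1, 0.5, 10))
    Ts <- sort(runif(25, 0, 3 * sd(a)), decreasing = TRUE)
    for (kind in c("hard", "soft", "garrote", "sbss")) {
      p <- vapply(Ts, function(T) p_ring_direct(a, T, kind, seq_along(a)), 0)
      expect_true(all(diff(p) <= 1e-12))
    }
  }
})

test_that("fast retained-power computation agrees with the direct split", {
  set.seed(55)
  a <- rnorm(256, sd = 5)
  span <- 1:128
  pre <- aswtd:::.adapt_precompute(a[span])
  for (kind in c("hard", "soft", "garrote")) {
    for (T in c(0, 0.5, 2, 5, 20)) {
      expect_equal(aswtd:::.p_ring_fast(pre, T, kind, tau = 1),
                   p_ring_direct(a, T, kind, span), tolerance = 1e-12)
    }
  }
  # sbss couples lambda = 2T; compare against the same convention
  for (T in c(0.5, 2, 5))
    expect_equal(aswtd:::.p_ring_fast(pre, T, "sbss", tau = 0.7),
                 p_ring_direct(a, T, "sbss", span, tau = 0.7),
                 tolerance = 1e-12)
})

test_that("adaptive loop terminates at the stated geometric schedule", {
  set.seed(70)
  a <- rnorm(256, sd = 4)
  # generous ThP: loop never entered, threshold stays at T0
  ad <- adapt_level(a, ThP = 1e6, kind = "garrote")
  expect_identical(ad$iterations, 0L)
  expect_equal(ad$T, ad$T0)
  expect_false(ad$capped)
  # one-step arithmetic: T drops by exactly (1 - mu) per iteration
  ad <- adapt_level(a, ThP = 1e-4, kind = "hard", mu = 0.1)
  expect_equal(ad$T, ad$T0 * 0.9^ad$iterations, tolerance = 1e-12)
  expect_true(ad$p_ring <= 1e-4 || ad$capped)
  # tiny ThP with hard shrinkage: nearly everything becomes artefact
  expect_lt(mean(ad$split$a_ring^2), 1e-4)
  expect_error(adapt_level(a, ThP = 0), "ThP")
  expect_error(adapt_level(a, ThP = 1, mu = 1.5), "mu")
})

test_that("adaptation always ends with admissible power or a flagged cap", {
  set.seed(71)
  for (i in 1:25) {
    a <- rnorm(256, sd = runif(1, 0.1, 30))
    ThP <- 10^runif(1, -6, 2)
    kind <- sample(c("hard", "soft", "garrote", "sbss"), 1)
    ad <- adapt_level(a, ThP, kind)
    expect_true(ad$p_ring <= ThP || ad$capped)
    expect_true(ad$T <= ad$T0)
  }
})

test_that("per-kind learning-rate defaults are as documented", {
  expect_identical(default_mu("soft"), 0.5)
  expect_identical(default_mu("hard"), 0.1)
  expect_identical(default_mu("garrote"), 0.1)
  expect_identical(default_mu("sbss"), 0.1)
})
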