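# Pipeline components: segmentation, derivations, features, selection,
# decision chain.

test_that("segmentation yields 8 windows per covered second", {
  expect_identical(length(segment_starts(10 * 128)), 1L + 9L * 8L)  # 73
  st <- segment_starts(3 * 128)
  expect_identical(st[1], 1L)
  expect_true(all(diff(st) == 16L))
  # consecutive windows share 112 samples (87.5% of 128)
  expect_identical(128L - diff(st)[1], 112L)
  expect_identical(segment_starts(100), integer(0))
})

test_that("bipolar derivation produces the 30 ordered pairs", {
  pairs <- bipolar_pairs()
  expect_identical(nrow(pairs), 30L)
  expect_identical(rownames(pairs)[1], "Cz-C1")
  expect_identical(rownames(pairs)[11], "FCz-Cz")
  seg <- matrix(rnorm(15 * 128), 15, 128, dimnames = list(eeg_montage(), NULL))
  bip <- bipolar_derive(seg)
  expect_identical(dim(bip), c(30L, 128L))
  expect_equal(bip["Cz-C1", ], seg["Cz", ] - seg["C1", ])
  # identical channels -> all derivations zero
  same <- matrix(rep(rnorm(128), each = 15), 15, 128,
                 dimnames = list(eeg_montage(), NULL))
  expect_true(all(bipolar_derive(same) == 0))
  # +1 uV offset shows up with the documented sign
  seg2 <- seg; seg2["Cz", ] <- seg2["C1", ] + 1
  expect_equal(unname(bipolar_derive(seg2)["Cz-C1", ]), rep(1, 128))
  bad <- seg[-3, ]
  expect_error(bipolar_derive(bad), rownames(seg)[3])
})

test_that("feature vector is 1050 non-negative powers in pair-major order", {
  seg <- matrix(rnorm(15 * 128), 15, 128, dimnames = list(eeg_montage(), NULL))
  v <- psd_features(bipolar_derive(seg))
  expect_length(v, 1050L)
  expect_true(all(v >= 0))
  expect_identical(names(v)[1:2], c("Cz-C1.1", "Cz-C1.2"))
  expect_identical(names(v)[36], "Cz-C2.1")
  expect_identical(unname(psd_features(matrix(0, 30, 128))), rep(0, 1050))
  # a pure 10 Hz tone in one derivation peaks at its 10 Hz feature
  seg0 <- matrix(0, 15, 128, dimnames = list(eeg_montage(), NULL))
  seg0["Cz", ] <- sin(2 * pi * 10 * (0:127) / 128)
  v <- psd_features(bipolar_derive(seg0))
  pair1 <- v[1:35]                       # Cz-C1 derivation
  expect_identical(which.max(pair1), c(`Cz-C1.10` = 10L))
})

test_that("stepwise selection finds a planted feature and honours its caps", {
  set.seed(31)
  n <- 200
  x <- matrix(rnorm(n * 50), n, 50)
  y <- rep(0:1, each = n / 2)
  x[, 17] <- x[, 17] + 3 * y             # one strongly separating feature
  sel <- stepwise_select(x, y)
  expect_identical(sel[1], 17L)
  expect_lte(length(sel), 140L)
  expect_identical(stepwise_select(x, y), sel)    # deterministic
  expect_lte(length(stepwise_select(x, y, max_features = 3L)), 3L)
  expect_error(stepwise_select(x, rep(1, n)), "both classes")
})

test_that("decision chain: moving average, threshold, debounce", {
  # constant scores: moving average of (s, s) is s
  dec <- classify_stream(rep(2, 20), threshold = 1, t_db = 8)
  expect_identical(dec[1], 1L)
  # a held activation emits 1, then exactly eight forced 0s, then 1 again
  expect_identical(dec[1:18], c(1L, rep(0L, 8L), 1L, rep(0L, 8L)))
  # all no-control scores stay silent
  expect_identical(classify_stream(rep(-1, 10), threshold = 0), rep(0L, 10))
  # debounce enforces the minimum spacing between activations
  set.seed(40)
  dec <- classify_stream(rnorm(400), threshold = 0.2, t_db = 8)
  gaps <- diff(which(dec == 1))
  if (length(gaps)) expect_gte(min(gaps), 9L)
  # blocking forces rejected segments to zero before debouncing
  dec <- classify_stream(rep(2, 10), threshold = 1, t_db = 0,
                         block = c(TRUE, rep(FALSE, 9)))
  expect_identical(dec[1], 0L)
  expect_identical(dec[2], 1L)
})

test_that("dwell gating suppresses decisions outside qualifying fixations", {
  times <- seq(0.125, 5, by = 0.125)
  ones <- rep(1L, length(times))
  gaze <- data.frame(start = 1, end = 3, clickable = TRUE)
  # T_dwell = 0: passthrough inside the clickable interval only
  g0 <- dwell_gate(ones, times, gaze, t_dwell = 0)
  expect_identical(g0, as.integer(times >= 1 & times <= 3))
  # dwell requirement delays eligibility by T_dwell
  g1 <- dwell_gate(ones, times, gaze, t_dwell = 1)
  expect_identical(g1, as.integer(times >= 2 & times <= 3))
  # a fixation shorter than the dwell time is fully suppressed
  short <- data.frame(start = 1, end = 1.9, clickable = TRUE)
  expect_identical(sum(dwell_gate(ones, times, short, t_dwell = 1)), 0L)
  # non-clickable gaze never qualifies
  nc <- data.frame(start = 1, end = 3, clickable = FALSE)
  expect_identical(sum(dwell_gate(ones, times, nc, t_dwell = 0)), 0L)
})

test_that("segment labelling matches the TP-window geometry", {
  lab <- aswtd:::.label_segments(times = seq(1, 20, by = 0.125), events = 10)
  t <- seq(1, 20, by = 0.125)
  expect_identical(lab$y == 1L, t >= 10.5 & t <= 11)
  # ambiguous flanks are excluded from training
  expect_false(any(lab$keep[t > 9.5 & t < 10.5]))
  expect_false(any(lab$keep[t > 11 & t < 11.5]))
  expect_true(all(lab$keep[t < 9.5 | t > 11.5]))
})
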