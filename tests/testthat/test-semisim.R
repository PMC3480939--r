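# Generators: determinism, spectral contracts, exact mixing ledger.

test_that("generators are deterministic given parameters and seed", {
  expect_identical(sim_clean_eeg(duration = 2, seed = 5),
                   sim_clean_eeg(duration = 2, seed = 5))
  expect_identical(sim_artefact("ocular", 640, seed = 5),
                   sim_artefact("ocular", 640, seed = 5))
  s1 <- sim_session(130, 10, seed = 9)
  s2 <- sim_session(130, 10, seed = 9)
  expect_identical(s1$eeg, s2$eeg)
  expect_identical(s1$events, s2$events)
  expect_false(identical(sim_clean_eeg(duration = 1, seed = 1),
                         sim_clean_eeg(duration = 1, seed = 2)))
})

test_that("surrogate clean EEG has the advertised amplitude and spectrum", {
  eeg <- sim_clean_eeg(duration = 8, seed = 42)
  expect_identical(rownames(eeg), eeg_montage())
  rms <- sqrt(rowMeans(eeg^2))
  expect_true(all(rms > 3 & rms < 10))
  # spectrum decreases with frequency above the idle-rhythm bump
  p <- spectral_power(eeg[1, ], fmax = 63)
  expect_gt(mean(p[13:20]), mean(p[30:45]))
  expect_gt(mean(p[30:45]), mean(p[50:63]))
  expect_error(sim_clean_eeg(duration = 0.5), "at least 1")
})

test_that("artefact templates concentrate power in their stated bands", {
  oc <- sim_artefact("ocular", 1024, seed = 3)
  mu <- sim_artefact("muscle", 1024, seed = 3)
  expect_equal(mean(oc), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(oc^2)), 1, tolerance = 1e-12)
  expect_gte(band_fraction(oc, c(1, 3)), 0.95)
  expect_gte(band_fraction(mu, c(20, 60)), 0.95)
  expect_error(sim_artefact("ocular", 100), "numtaps")
  expect_error(sim_artefact("blink", 1024), "arg")
})

test_that("mixing hits the worst-channel SNR exactly and keeps the ledger", {
  cl <- sim_clean_eeg(duration = 1, seed = 8)
  tpl <- sim_artefact("ocular", 640, seed = 9)
  tr <- mix_artefact(cl, tpl, shift = 37, kind = "ocular")
  expect_equal(tr$snr_db, 0, tolerance = 0.01)
  # exact ledger: mixed - clean is the injected artefact, bit for bit
  expect_identical(tr$mixed - tr$clean, tr$artefact)
  j <- which.max(tr$gains)
  expect_equal(10 * log10(mean(cl[j, ]^2) / mean(tr$artefact[j, ]^2)), 0,
               tolerance = 1e-10)
  # non-default target
  tr6 <- mix_artefact(cl, tpl, target_snr_db = 6, kind = "ocular")
  expect_equal(10 * log10(mean(cl[j, ]^2) / mean(tr6$artefact[j, ]^2)), 6,
               tolerance = 1e-10)
  # single contaminated channel
  g <- c(rep(0, 2), 1, rep(0, 12))
  tr1 <- mix_artefact(cl, tpl, gains = g, kind = "ocular")
  expect_identical(tr1$mixed[-3, ], cl[-3, ])
  expect_false(identical(tr1$mixed[3, ], cl[3, ]))
  # circular shift semantics: row is the shifted template up to one scale
  a <- mix_artefact(cl, tpl, shift = 50, kind = "ocular")$artefact
  idx <- ((seq_len(128) - 1 + 50) %% 640) + 1
  expect_equal(unname(a[1, ] / tpl[idx]),
               rep(unname(a[1, 1] / tpl[idx[1]]), 128), tolerance = 1e-9)
  expect_error(mix_artefact(cl, numeric(640)), "zero power")
  expect_error(mix_artefact(cl, tpl, gains = rep(0, 15)), "max gain")
})

test_that("reference segments are 1-second cuts that calibrate cleanly", {
  ref <- ref_segments_fixture()
  expect_true(all(vapply(ref, ncol, 0L) == 128L))
  expect_true(all(vapply(ref, nrow, 0L) == 15L))
  model <- detection_model_fixture()
  clean_rate <- mean(vapply(ref, function(s)
    detect_segment(s, model)$clean, logical(1)))
  expect_gte(clean_rate, 0.9)
})

test_that("sessions realise the requested structure", {
  s <- sim_session(200, n_ic = 16, contamination_ic_pct = 50,
                   contamination_nc_pct = 20, seed = 77)
  expect_length(s$events, 16)
  expect_true(all(diff(s$events) > 2.5))
  # realised IC contamination matches the request exactly by count
  ic_rows <- s$contamination$trial == "IC"
  expect_identical(sum(ic_rows), 8L)
  # gaze intervals are ordered and non-overlapping, and cover every event
  g <- s$gaze
  expect_true(all(g$start[-1] >= utils::head(g$end, -1)))
  covered <- vapply(s$events, function(e)
    any(g$start <= e & g$end >= e & g$clickable), logical(1))
  expect_true(all(covered))
  expect_error(sim_session(200, 16, contamination_ic_pct = 150), "rates")
  expect_error(sim_session(30, 16), "too short")

  # zero contamination: detection flags few segments outside IC windows
  s0 <- sim_session(80, n_ic = 6, contamination_ic_pct = 0,
                    contamination_nc_pct = 0, seed = 78)
  expect_identical(nrow(s0$contamination), 0L)
  model <- detection_model_fixture()
  segs <- cut_segments(s0$eeg)
  flagged <- vapply(segs, function(x) !detect_segment(x, model)$clean,
                    logical(1))
  expect_lte(mean(flagged), 0.1)
})
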