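test_that("generation is deterministic and respects the config", {
  cfg <- synth_config(seed = 13, duration_s = 20, seizure_windows = list(c(5, 15)))
  r1 <- generate_recording(cfg)
  r2 <- generate_recording(cfg)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$annotations, r2$annotations)
  r3 <- generate_recording(synth_config(seed = 14, duration_s = 20,
                                        seizure_windows = list(c(5, 15))))
  expect_false(identical(r3$data, r1$data))

  expect_error(synth_config(seizure_windows = list(c(10, 5))),
               class = "config_error")
  expect_error(synth_config(seizure_windows = list(c(0, 200))),
               class = "config_error")
  expect_error(synth_config(asymmetry_factor = 0.5), class = "config_error")
})

test_that("no seizure windows means no ictal epochs after segmentation", {
  cfg <- synth_config(seed = 3, duration_s = 40, seizure_windows = list())
  rec <- generate_recording(cfg)
  expect_equal(nrow(rec$annotations), 0)
  es <- preprocess_recording(rec)
  expect_true(all(es$labels == "interictal"))
})

test_that("focus-side channels carry more ictal energy in every pair", {
  m <- montage_spec()
  cfg <- synth_config(seed = 5, duration_s = 60,
                      seizure_windows = list(c(10, 50)),
                      focus_side = "left", asymmetry_factor = 1.5)
  rec <- generate_recording(cfg)
  win <- (rec$annotations$start + 1):rec$annotations$end
  li <- match(m$pairs$left, rec$channel_names)
  ri <- match(m$pairs$right, rec$channel_names)
  for (p in 1:8) {
    eL <- sum(rec$data[li[p], win]^2)
    eR <- sum(rec$data[ri[p], win]^2)
    expect_gt(eL, eR)
  }
})

test_that("annotations and ground truth round-trip through the matrix format", {
  cfg <- synth_config(seed = 9, duration_s = 20, seizure_windows = list(c(4, 12)),
                      focus_side = "left")
  rec <- generate_recording(cfg)
  path <- file.path(withr::local_tempdir(), "syn.csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$annotations, rec$annotations)
  expect_identical(back$true_laterality, "left")
})

test_that("cohorts share the focus side within a patient and reproduce", {
  cfg <- synth_config(duration_s = 10, seizure_windows = list(c(2, 8)))
  recs <- generate_cohort(6, 2, cfg, left_fraction = 0.5, seed = 21)
  expect_length(recs, 12)
  pats <- attr(recs, "patients")
  expect_equal(sum(pats$focus_side == "left"), 3)
  for (k in seq_along(recs)) {
    p <- match(recs[[k]]$subject_id, pats$subject_id)
    expect_identical(recs[[k]]$true_laterality, pats$focus_side[p])
  }
  recs2 <- generate_cohort(6, 2, cfg, left_fraction = 0.5, seed = 21)
  expect_identical(lapply(recs2, `[[`, "data"), lapply(recs, `[[`, "data"))
  # vector recordings_per_patient expresses uneven series
  recs3 <- generate_cohort(3, c(2, 1, 1), cfg, seed = 21)
  expect_length(recs3, 4)
})

test_that("ictal epochs carry more beta energy than interictal ones", {
  # sign test at the epoch level across seeded recordings
  wins <- losses <- 0
  for (seed in 1:12) {
    cfg <- synth_config(seed = seed, duration_s = 48,
                        seizure_windows = list(c(16, 32)))
    es <- preprocess_recording(generate_recording(cfg))
    fm <- extract_features(es, "Beta")
    ict <- fm$energy[fm$labels == "ictal", , drop = FALSE]
    int <- fm$energy[fm$labels == "interictal", , drop = FALSE]
    for (i in seq_len(nrow(ict)))
      for (j in seq_len(nrow(int))) {
        d <- mean(ict[i, ]) - mean(int[j, ])
        if (d > 0) wins <- wins + 1 else losses <- losses + 1
      }
  }
  # one-sided binomial sign test on the paired comparisons
  p <- binom.test(wins, wins + losses, alternative = "greater")$p.value
  expect_lt(p, 1e-6)
})
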