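test_that("phantom generation is deterministic under a seed", {
  cfg <- small_config()
  v1 <- generate_phantom(cfg, 0, 42)
  v2 <- generate_phantom(cfg, 0, 42)
  expect_identical(v1$intensities, v2$intensities)
  expect_identical(v1$mask, v2$mask)
  v3 <- generate_phantom(cfg, 0, 43)
  expect_false(identical(v1$intensities, v3$intensities))
})

test_that("noise-free phantom has contrast-level tumor and zero background", {
  cfg <- small_config(noise_sd = 0, tumor_contrast = 10, background_level = 0)
  v <- generate_phantom(cfg, 0, 7)
  inside <- v$intensities[1, , , ][v$mask == 1]
  outside <- v$intensities[1, , , ][v$mask == 0]
  expect_equal(mean(inside), 10, tolerance = 0.05)
  expect_identical(unique(outside), 0)
  expect_true(all(v$mask %in% c(0, 1)))
})

test_that("short-correlation class carries more in-mask high-frequency energy", {
  cfg <- small_config()
  e0 <- vapply(1:20, function(i)
    mask_highfreq_energy(generate_phantom(cfg, 0, i)), 0)
  e1 <- vapply(1:20, function(i)
    mask_highfreq_energy(generate_phantom(cfg, 1, 100 + i)), 0)
  expect_gt(mean(e1), mean(e0))
  expect_true(all(e1 > max(e0) - diff(range(e0))))  # clear separation
})

test_that("texture statistic distributions converge as the class contrast vanishes", {
  cfg_same <- small_config(texture_corr_length = c(2, 2))
  e0 <- vapply(1:12, function(i)
    mask_highfreq_energy(generate_phantom(cfg_same, 0, i)), 0)
  e1 <- vapply(1:12, function(i)
    mask_highfreq_energy(generate_phantom(cfg_same, 1, 200 + i)), 0)
  expect_gt(t.test(e0, e1)$p.value, 0.05)
})

test_that("cohorts alternate labels with unique ids and monotone diagnosis time", {
  coh <- generate_cohort(5, small_config(), seed = 9)
  expect_length(coh$volumes, 10L)
  expect_equal(sum(coh$manifest$label == 0), 5L)
  expect_equal(sum(coh$manifest$label == 1), 5L)
  expect_false(anyDuplicated(coh$manifest$case_id) > 0)
  expect_identical(coh$manifest$diagnosis_time, 1:10)
  expect_equal(nrow(coh$manifest), 10L)
  # disjoint per-case seeds: no two volumes identical
  for (i in 1:9) for (j in (i + 1):10) {
    expect_false(identical(coh$volumes[[i]]$intensities,
                           coh$volumes[[j]]$intensities))
  }
  # whole-cohort determinism
  coh2 <- generate_cohort(5, small_config(), seed = 9)
  expect_identical(coh$volumes[[3]]$intensities, coh2$volumes[[3]]$intensities)
})

test_that("invalid phantom configurations are rejected", {
  expect_error(phantom_config(tumor_radius_range = c(10, 40)), "margin")
  expect_error(phantom_config(texture_corr_length = c(0, 1)), "positive")
  expect_error(phantom_config(noise_sd = -1), ">= 0")
  expect_error(phantom_config(n_channels = 3), "1 or 2")
})
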