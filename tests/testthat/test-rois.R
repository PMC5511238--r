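test_that("scale ratios are geometric and span the requested range", {
  r <- scale_ratios(10, c(0.5, 2))
  expect_length(r, 10L)
  expect_equal(r[1], 0.5)
  expect_equal(r[10], 2.0)
  q <- r[-1] / r[-10]
  expect_equal(q, rep((2 / 0.5)^(1 / 9), 9), tolerance = 1e-12)
})

test_that("bicubic resampling scales crops as expected", {
  img <- matrix(rnorm(1600), 40, 40)
  out <- resize_bicubic(img, 20, 20)
  expect_identical(dim(out), c(20L, 20L))
  # constants are reproduced exactly
  expect_equal(resize_bicubic(matrix(3, 8, 8), 15, 17),
               matrix(3, 15, 17), tolerance = 1e-12)
})

test_that("ROI sets cover every tumor slice at every retained scale", {
  vol <- generate_phantom(small_config(), 0, 11)
  rs <- multiscale_rois(vol, n_scales = 10, min_input = 5L)
  tumor_slices <- which(apply(vol$mask, 1, sum) > 0)
  expect_setequal(vapply(rs$slices, `[[`, 0L, "z"), tumor_slices)
  for (sl in rs$slices) {
    expect_true(all(vapply(sl$images, function(i) min(dim(i)[1:2]), 0L) >= 5L))
  }
  expect_error(multiscale_rois(vol, mask = array(0, dim(vol$mask))), "empty")
  # a 40x40 crop at ratio 0.5 becomes 20x20 (round(40 * 0.5))
  big <- vol
  big$mask[] <- 0; big$mask[3, 11:50, 11:50] <- 1
  rs2 <- multiscale_rois(big, mask = big$mask, n_scales = 2,
                         scale_range = c(0.5, 2), min_input = 5L)
  expect_identical(dim(rs2$slices[[1]]$images[[1]])[1:2], c(20L, 20L))
})

test_that("filter responses are nonnegative with equal counts across filters", {
  vol <- generate_phantom(small_config(), 0, 12)
  net <- build_network(tiny_spec(), seed = 3)
  rs <- multiscale_rois(vol, n_scales = 4, min_input = 5L)
  fr <- extract_filter_responses(net, rs)
  expect_identical(ncol(fr$responses), 6L)          # last conv width
  expect_true(all(fr$responses >= 0))               # post-ReLU
  expect_identical(nrow(fr$responses), fr$n_responses)
  # doubling the number of scales strictly increases T
  rs8 <- multiscale_rois(vol, n_scales = 8, min_input = 5L)
  fr8 <- extract_filter_responses(net, rs8)
  expect_gt(fr8$n_responses, fr$n_responses)
})

test_that("slice order permutation leaves the Fisher descriptor unchanged", {
  vol <- generate_phantom(small_config(), 1, 13)
  net <- build_network(tiny_spec(), seed = 3)
  rs <- multiscale_rois(vol, n_scales = 3, min_input = 5L)
  rs_perm <- rs
  rs_perm$slices <- rev(rs_perm$slices)
  fr <- extract_filter_responses(net, rs)
  frp <- extract_filter_responses(net, rs_perm)
  gmm <- manual_gmm(c(0.4, 0.6), c(0.1, 1), c(0.2, 0.5))
  d1 <- encode_case(fr, gmm)
  d2 <- encode_case(frp, gmm)
  expect_equal(d1$values, d2$values, tolerance = 1e-10)
})
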