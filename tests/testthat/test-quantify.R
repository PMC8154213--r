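make_image <- function(values, channel = channel_spec("ch", 100),
                       pixel_size = 500) {
  structure(list(values = values, channel = channel,
                 pixel_size = pixel_size),
            class = "IonImage")
}

test_that("ion image extraction respects the half-open m/z window", {
  # empty dataset -> all-zero image
  empty <- imaging_dataset(replicate(4, list(mz = numeric(0),
                                             intensity = numeric(0)),
                                     simplify = FALSE), 2, 2)
  ch <- channel_spec("x", 100, window = 0.2)
  expect_true(all(extract_ion_image(empty, ch)$values == 0))

  # two peaks 0.3 Da apart with the channel centered between them: neither
  # falls inside the 0.2 Da window
  ds <- imaging_dataset(list(list(mz = c(99.85, 100.15),
                                  intensity = c(5, 7))), 1, 1)
  expect_identical(extract_ion_image(ds, ch)$values[1, 1], 0)
  # half-open bounds, probed with binary-exact masses: a peak at the lower
  # edge counts, a peak at the upper edge does not
  ds2 <- imaging_dataset(list(list(mz = c(99.875, 100.125),
                                   intensity = c(5, 7))), 1, 1)
  edge <- channel_spec("x", 100, window = 0.25)  # [99.875, 100.125)
  expect_identical(extract_ion_image(ds2, edge)$values[1, 1], 5)

  neg <- imaging_dataset(list(list(mz = 100, intensity = 1)), 1, 1,
                         polarity = -1L)
  expect_error(extract_ion_image(neg, ch), "polarity")
})

test_that("synthetic spots produce signal only within their footprints", {
  layout <- build_layout(1, 2)
  sim <- sim_ired_plate(layout, c(A1 = 1), seed = 1L,
                        instrument = quiet_instrument(),
                        responses = quiet_response())
  img <- extract_ion_image(sim$dataset, sim$product)
  # A2 carries species but zero concentration is not simulated here; only the
  # A1 half of the membrane may contain intensity
  expect_gt(sum(img$values[, 1:10]), 0)
  expect_equal(sum(img$values[, 11:20]), 0)
})

test_that("well sums follow raw = value * pixels with border-frame background", {
  layout <- build_layout(1, 1)
  v <- matrix(7, 10, 10)
  q <- quantify_wells(make_image(v), layout, margin = 0.1)
  expect_identical(q$n_roi, 64L)         # 8x8 after 10% trim per side
  expect_equal(q$raw, 7 * 64)
  expect_equal(q$background, 7)          # border frame is also 7
  expect_equal(q$corrected, 0)           # uniform field has no spot signal
  expect_true(q$empty)

  # spot on zero background
  v2 <- matrix(0, 10, 10); v2[4:7, 4:7] <- 10
  q2 <- quantify_wells(make_image(v2), layout)
  expect_equal(q2$raw, 160)
  expect_equal(q2$background, 0)
  expect_equal(q2$corrected, 160)
  expect_false(q2$empty)

  bad_reg <- structure(list(dx = 0, dy = 0, residual = 4, n_spots_used = 1L),
                       class = "Registration")
  expect_error(quantify_wells(make_image(v), layout, bad_reg), "residual")
})

test_that("quantification is additive over images on noise-free input", {
  layout <- build_layout(2, 2)
  set.seed(3)
  a <- matrix(runif(400), 20, 20)
  b <- matrix(runif(400), 20, 20)
  qa <- quantify_wells(make_image(a), layout)
  qb <- quantify_wells(make_image(b), layout)
  qab <- quantify_wells(make_image(a + b), layout)
  expect_equal(qab$raw, qa$raw + qb$raw, tolerance = 1e-12)
  # background medians are not exactly additive, but raw sums are
})

test_that("registration recovers the null and a known sub-cell offset", {
  layout <- build_layout(2, 3)
  conv <- stats::setNames(runif(6, 0.3, 1), well_labels(layout))
  sim0 <- sim_ired_plate(layout, conv, seed = 2L)
  reg0 <- register_grid(total_ion_image(sim0$dataset), layout)
  expect_lt(abs(reg0$dx), 0.25)
  expect_lt(abs(reg0$dy), 0.25)

  sim1 <- sim_ired_plate(layout, conv, seed = 3L, offset = c(0.3, -0.2))
  reg1 <- register_grid(total_ion_image(sim1$dataset), layout)
  expect_lt(abs(reg1$dx - 0.3), 0.25)
  expect_lt(abs(reg1$dy + 0.2), 0.25)

  blank <- make_image(matrix(0, 20, 30))
  expect_error(register_grid(blank, layout), "manual offset")
})

test_that("calibration fitting flags saturation and reports LOD", {
  concs <- c(1, 2, 3, 4, 5)
  fit <- fit_calibration(concs, 10 * concs)
  expect_equal(fit$slope, 10, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$lod, 0, tolerance = 1e-9)
  expect_length(fit$saturated_points, 0L)
  expect_equal(fit$linear_range, c(1, 5))

  # a heavily saturated top point is excluded from the final fit
  concs2 <- c(0.005, 0.01, 0.025, 0.05, 0.075, 0.1, 2)
  resp <- concs2 / (1 + concs2 / 1.0) * 1e5
  fit2 <- fit_calibration(concs2, resp)
  expect_identical(fit2$saturated_points, 7L)
  expect_equal(fit2$linear_range, c(0.005, 0.1))
  expect_gt(fit2$r_squared, 0.999)

  expect_error(fit_calibration(1:2, 1:2), "at least 3")
  expect_error(fit_calibration(1:3, c(1, 2)), "length")
})

test_that("conversion estimates follow P / (P + r S) and respect flags", {
  q <- data.frame(well = c("A1", "A1", "A2", "A2"),
                  channel = rep(c("sub", "prod"), 2),
                  raw = c(20, 80, 0, 0), background = 0,
                  corrected = c(20, 80, 0, 0), noise = c(1, 1, 1, 1),
                  n_roi = 64L, empty = FALSE, saturated = FALSE,
                  isotope_false_positive = FALSE, conversion = NA_real_)
  class(q) <- c("WellQuant", "data.frame")
  out <- estimate_conversion(q, "sub", "prod")
  expect_equal(out$conversion[out$well == "A1" & out$channel == "prod"], 0.8)
  # empty well: undefined and flagged
  a2 <- out[out$well == "A2" & out$channel == "prod", ]
  expect_true(is.na(a2$conversion))
  expect_true(a2$empty)
  # response ratio rescales the substrate term
  out2 <- estimate_conversion(q, "sub", "prod", response_ratio = 4)
  expect_equal(out2$conversion[out2$well == "A1" & out2$channel == "prod"],
               80 / (80 + 4 * 20))
  # P = 0 with substrate present is exactly zero
  q$corrected <- c(50, 0, 0, 0); q$raw <- q$corrected
  out3 <- estimate_conversion(q, "sub", "prod")
  expect_equal(out3$conversion[out3$well == "A1" & out3$channel == "prod"], 0)
  expect_error(estimate_conversion(q, "sub", "missing"), "missing")
  expect_error(estimate_conversion(q, "sub", "prod", response_ratio = 0),
               "response_ratio")
})

test_that("estimated conversion is monotone in true conversion (noise-free)", {
  layout <- build_layout(1, 6)
  conv <- stats::setNames(seq(0, 1, length.out = 6), well_labels(layout))
  sim <- sim_ired_plate(layout, conv, seed = 1L,
                        instrument = quiet_instrument(),
                        responses = quiet_response())
  q <- quantify_ired(sim)
  q <- subtract_isotope_interference(q, isotope_envelope(IRED_SUB, "M+H"),
                                     sim$product$label, sim$substrate$label,
                                     product_mz = sim$product$target_mz)
  q <- estimate_conversion(q, sim$substrate$label, sim$product$label)
  est <- q$conversion[q$channel == sim$product$label]
  expect_false(is.unsorted(est))
  expect_equal(est[[1]], 0)
  expect_equal(est[[6]], 1)
})

test_that("known non-unit response ratios are recovered when supplied", {
  layout <- build_layout(2, 3)
  wells <- well_labels(layout)
  conv <- stats::setNames(seq(0.1, 0.9, length.out = 6), wells)
  responses <- list(response_model(response_factor = 2e4, noise_scale = 0,
                                   baseline = 0, saturation_level = Inf),
                    response_model(response_factor = 5e4, noise_scale = 0,
                                   baseline = 0, saturation_level = Inf))
  names(responses) <- c(IRED_SUB, IRED_PROD)
  sim <- sim_ired_plate(layout, conv, seed = 4L,
                        instrument = quiet_instrument(),
                        responses = responses)
  q <- quantify_ired(sim)
  q <- subtract_isotope_interference(q, isotope_envelope(IRED_SUB, "M+H"),
                                     sim$product$label, sim$substrate$label,
                                     product_mz = sim$product$target_mz)
  # r = product/substrate response ratio; also fold in the envelope base-peak
  # fractions each channel actually captures
  a0s <- max(isotope_envelope(IRED_SUB, "M+H")$abundance)
  a0p <- max(isotope_envelope(IRED_PROD, "M+H")$abundance)
  r <- (5e4 * a0p) / (2e4 * a0s)
  q <- estimate_conversion(q, sim$substrate$label, sim$product$label,
                           response_ratio = r)
  est <- q$conversion[q$channel == sim$product$label]
  expect_equal(est, unname(conv), tolerance = 0.01)
})
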