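drift_inst <- function(...) {
  instrument_params(drift_bins = 15L, drift_start = 3, drift_resolution = 0.5,
                    drift_sd = 0.5, ...)
}

test_that("drift profiles reflect the generated mobility structure", {
  layout <- build_layout(1, 3)
  sim <- sim_ired_plate(layout, c(A1 = 0.5, A2 = 0, A3 = 1), seed = 8L,
                        instrument = drift_inst())
  # half-converted well: both species -> bimodal profile near 5 and 8 ms
  profS <- extract_drift_profile(sim$dataset, sim$substrate, layout, "A1")
  profP <- extract_drift_profile(sim$dataset, sim$product, layout, "A1")
  mode_at <- function(p) p$centers[[which.max(p$intensity)]]
  expect_lt(abs(mode_at(profS) - 5), 0.51)
  expect_lt(abs(mode_at(profP) - 8), 0.51)
  # product channel over a substrate-only well: leakage peaks at the
  # substrate drift time, a second mode appears only in converted wells
  leak <- extract_drift_profile(sim$dataset, sim$product, layout, "A2")
  expect_lt(abs(mode_at(leak) - 5), 0.51)
  # single-species (full conversion) well: unimodal product profile
  uni <- extract_drift_profile(sim$dataset, sim$product, layout, "A3")
  modes <- desiscreen:::profile_modes(uni$intensity)
  big <- modes[uni$intensity[modes] > 0.1 * max(uni$intensity)]
  expect_length(big, 1L)
  # wells with no species at all give an all-zero profile
  layout2 <- build_layout(1, 2)
  sim2 <- sim_ired_plate(layout2, c(A1 = 1), seed = 1L,
                         instrument = drift_inst())
  zero <- extract_drift_profile(sim2$dataset, sim2$product, layout2, "A2")
  expect_true(all(zero$intensity == 0))

  nodrift <- sim_ired_plate(layout2, c(A1 = 1), seed = 1L)
  expect_error(extract_drift_profile(nodrift$dataset, nodrift$product,
                                     layout2, "A1"),
               "subtract_isotope_interference")
})

test_that("gates bracket the expected mode and exclude competing modes", {
  layout <- build_layout(1, 1)
  sim <- sim_ired_plate(layout, c(A1 = 0.5), seed = 9L,
                        instrument = drift_inst())
  prof <- extract_drift_profile(sim$dataset, sim$product, layout, "A1")
  gate <- fit_gate(prof, 8)
  expect_lt(abs(gate$lo - 7), 0.5)
  expect_lt(abs(gate$hi - 9), 0.5)
  expect_false(gate$lo <= 5 && 5 <= gate$hi)  # excludes the substrate mode
  gate5 <- fit_gate(prof, 5)
  expect_true(gate5$lo < 5 && 5 < gate5$hi)
  expect_false(gate5$lo <= 8 && 8 <= gate5$hi)

  expect_error(fit_gate(prof, 20), "outside")
  flat <- prof
  flat$intensity <- rep(0, length(flat$intensity))
  expect_error(fit_gate(flat, 8), "flat")
  expect_error(drift_gate(2, 1), "lo < hi")
})

test_that("gating removes substrate M+2 false positives but keeps product signal", {
  layout <- build_layout(1, 2)
  sim <- sim_ired_plate(layout, c(A1 = 0, A2 = 1), seed = 10L,
                        instrument = drift_inst())
  ungated <- extract_ion_image(sim$dataset, sim$product)
  prof <- extract_drift_profile(sim$dataset, sim$product, layout, "A2")
  gate <- fit_gate(prof, 8)
  gated <- gate_image(sim$dataset, sim$product, gate)
  qu <- quantify_wells(list(ungated), layout)
  qg <- quantify_wells(list(gated), layout)
  # substrate-only well is a false positive without gating, empty with it
  expect_false(qu$empty[qu$well == "A1"])
  expect_true(qg$empty[qg$well == "A1"])
  # genuine product wells retain >= 90% of their signal (2 SD gate ~95%)
  expect_gt(qg$corrected[qg$well == "A2"], 0.9 * qu$corrected[qu$well == "A2"])

  # a gate spanning every bin reproduces the ungated image bit-exactly
  all_gate <- drift_gate(min(sim$dataset$drift_centers) - 1,
                         max(sim$dataset$drift_centers) + 1)
  expect_identical(gate_image(sim$dataset, sim$product, all_gate)$values,
                   ungated$values)
  # a gate disjoint from the bins warns and returns zeros
  expect_warning(z <- gate_image(sim$dataset, sim$product,
                                 drift_gate(50, 60)), "disjoint")
  expect_true(all(z$values == 0))
})

test_that("arithmetic interference subtraction zeroes unconverted wells exactly", {
  layout <- build_layout(1, 3)
  sim <- sim_ired_plate(layout, c(A1 = 0, A2 = 1, A3 = 0.5), seed = 1L,
                        instrument = quiet_instrument(),
                        responses = quiet_response())
  q <- quantify_ired(sim)
  env <- isotope_envelope(IRED_SUB, "M+H")
  q2 <- subtract_isotope_interference(q, env, sim$product$label,
                                      sim$substrate$label,
                                      product_mz = sim$product$target_mz)
  p <- function(qq, w) qq[qq$well == w & qq$channel == sim$product$label, ]
  # substrate-only well, noise 0: zero up to 32-bit storage rounding, flagged
  expect_lt(p(q2, "A1")$corrected, 1e-3)
  expect_true(p(q2, "A1")$isotope_false_positive)
  # zero substrate signal: product sum unchanged
  expect_equal(p(q2, "A2")$corrected, p(q, "A2")$corrected)
  expect_false(p(q2, "A2")$isotope_false_positive)
  # genuine converted well keeps most signal, no flag
  expect_false(p(q2, "A3")$isotope_false_positive)
  expect_gt(p(q2, "A3")$corrected, 0.9 * p(q, "A3")$corrected)
  # idempotent on its own output
  q3 <- subtract_isotope_interference(q2, env, sim$product$label,
                                      sim$substrate$label,
                                      product_mz = sim$product$target_mz)
  expect_identical(q3, q2)
  expect_error(subtract_isotope_interference(q, list(), sim$product$label,
                                             sim$substrate$label,
                                             product_mz = 208),
               "IsotopeEnvelope")
})
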