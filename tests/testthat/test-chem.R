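test_that("formula parsing follows element-count grammar and round-trips", {
  expect_equal(unclass(parse_formula("C12H15NO2"))[c("C", "H", "N", "O")],
               c(C = 12L, H = 15L, N = 1L, O = 2L))
  expect_equal(unclass(parse_formula("H2O"))[c("H", "O")], c(H = 2L, O = 1L))
  expect_equal(unclass(parse_formula("C6H12FO8P"))[c("C", "H", "F", "O", "P")],
               c(C = 6L, H = 12L, F = 1L, O = 8L, P = 1L))
  # Hill-order canonicalization round-trips
  for (f in c("C12H15NO2", "H2O", "C6H12FO8P", "CH4", "C2H6S", "CCl4")) {
    canon <- format_formula(parse_formula(f))
    expect_identical(format_formula(parse_formula(canon)), canon)
  }
  expect_identical(format_formula(parse_formula("O2H4C8")), "C8H4O2")
  expect_error(parse_formula("C6Xx2"), "Xx")
  expect_error(parse_formula(""), "non-empty")
  expect_error(parse_formula("C-1"), "grammar")
})

test_that("monoisotopic m/z reproduces the imine/amine ion pair", {
  expect_equal(round(monoisotopic_mz("C12H15NO2", "M+H"), 1), 206.1)
  expect_equal(monoisotopic_mz("C12H15NO2", "M+H"), 206.1176, tolerance = 1e-6)
  expect_equal(round(monoisotopic_mz("C12H17NO2", "M+H"), 1), 208.1)
  expect_equal(monoisotopic_mz("C12H17NO2", "M+H"), 208.1332, tolerance = 1e-6)
  expect_equal(monoisotopic_mz("H2O", "M+H"), 19.018, tolerance = 1e-3)
  # the deoxyfluorinated sugar phosphate computes to 261.02, not nominal 261.1
  expect_equal(monoisotopic_mz("C6H12FO8P", "M-H"), 261.018, tolerance = 1e-3)
  expect_error(monoisotopic_mz("H2O", "M"), "neutral")
})

test_that("protonation and deprotonation differ by two proton masses", {
  for (f in c("C12H15NO2", "H2O", "C6H13O9P", "C3H7NO2S")) {
    expect_equal(monoisotopic_mz(f, "M+H") - monoisotopic_mz(f, "M-H"),
                 2 * 1.007276466621, tolerance = 1e-9)
  }
  # adding 2 H (imine -> amine) shifts [M+H]+ by ~2.016 Da, within the
  # 0.2 Da channel window of a nominal +2 shift
  shift <- monoisotopic_mz("C12H17NO2", "M+H") -
    monoisotopic_mz("C12H15NO2", "M+H")
  expect_equal(shift, 2.0157, tolerance = 1e-3)
  expect_lt(abs(shift - 2), 0.2)
})

test_that("single-element envelopes equal the abundance table", {
  e1 <- isotope_envelope("C")
  expect_equal(e1$mass, c(12.0000, 13.00335), tolerance = 1e-4)
  expect_equal(e1$abundance, c(0.9893, 0.0107), tolerance = 1e-9)
  e2 <- isotope_envelope("C2")
  # binomial expansion by hand: M+1 = 2 * 0.9893 * 0.0107
  expect_equal(e2$abundance[[2]], 2 * 0.9893 * 0.0107, tolerance = 1e-9)
  expect_equal(e2$nominal_offset, c(0L, 1L, 2L))
})

test_that("envelopes are probability distributions with increasing masses", {
  for (f in c("C12H15NO2", "C12H17NO2", "C6H12FO8P", "H2O", "C3H7NO2S",
              "CCl4", "C2H5Br")) {
    for (a in c("M", "M+H")) {
      env <- isotope_envelope(f, a)
      expect_equal(sum(env$abundance), 1, tolerance = 1e-9)
      expect_true(all(diff(env$mass) > 0))
      expect_true(all(env$abundance > 0))
    }
  }
  expect_error(isotope_envelope("C", truncation = 0), "truncation")
  expect_error(isotope_envelope("C", truncation = 0.5), "truncation")
})

test_that("envelope convolution matches brute-force enumeration", {
  # small spot-check here; the full <= 40 atom sweep runs in the acceptance
  # suite
  env <- isotope_envelope("C12H15NO2", "M+H")
  oracle <- oracle_envelope(oracle_ion_counts("C12H15NO2", "M+H"),
                            polarity = 1L)
  expect_equal(length(env$abundance), length(oracle$abundance))
  expect_lt(max(abs(env$abundance - oracle$abundance)), 1e-9)
  expect_lt(max(abs(env$mass - oracle$mass)), 1e-6)
  # substrate M+2 is m/z-coincident with the product ion within the window
  prod_mz <- monoisotopic_mz("C12H17NO2", "M+H")
  expect_lt(abs(env$mass[[3]] - prod_mz), 0.2)
})

test_that("interference fraction quantifies M+2 leakage into the product channel", {
  env <- isotope_envelope("C12H15NO2", "M+H")
  prod_mz <- monoisotopic_mz("C12H17NO2", "M+H")
  f <- interference_fraction(env, prod_mz, 0.2)
  expect_equal(f, 0.0127, tolerance = 0.05)
  # brute-force check of the same number
  oracle <- oracle_envelope(oracle_ion_counts("C12H15NO2", "M+H"),
                            polarity = 1L)
  inwin <- abs(oracle$mass - prod_mz) <= 0.1
  expect_equal(f, sum(oracle$abundance[inwin]) / max(oracle$abundance),
               tolerance = 1e-9)
  expect_gte(interference_fraction(env, env$mass[[which.max(env$abundance)]],
                                   0.2), 1.0)
  expect_identical(interference_fraction(env, 300.0, 0.2), 0)
  expect_error(interference_fraction(list(), 208, 0.2), "envelope")
  expect_error(interference_fraction(env, 208, 0), "window")
})
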