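test_that("heat maps map channels to RGB planes deterministically", {
  layout <- build_layout(1, 2)
  sim <- sim_ired_plate(layout, c(A1 = 0, A2 = 1), seed = 1L,
                        instrument = quiet_instrument(),
                        responses = quiet_response())
  imgS <- extract_ion_image(sim$dataset, sim$substrate)  # red
  imgP <- extract_ion_image(sim$dataset, sim$product)    # green
  hm <- render_heatmap(list(imgS, imgP), layout, scale = 2,
                       draw_grid = FALSE, draw_labels = FALSE)
  # zero-conversion well renders red, full-conversion green
  at <- function(x_mm, y_mm) {
    r <- round(y_mm / 0.5) * 2; c <- round(x_mm / 0.5) * 2
    hm$rgb[r, c, ]
  }
  a1 <- at(2.5, 2.5); a2 <- at(7.5, 2.5)
  expect_gt(a1[[1]], 200); expect_lt(a1[[2]] / max(a1[[1]], 1), 0.05)
  expect_gt(a2[[2]], 200); expect_lt(a2[[1]] / max(a2[[2]], 1), 0.05)
  # uniform zero renders black
  zero <- imgS; zero$values[] <- 0
  black <- render_heatmap(zero, layout, scale = 1, draw_grid = FALSE,
                          draw_labels = FALSE)
  expect_true(all(black$rgb == 0))
  # single channel: per-channel and global normalization coincide
  g1 <- render_heatmap(imgP, layout, normalization = "per_channel")
  g2 <- render_heatmap(imgP, layout, normalization = "global")
  expect_identical(g1$rgb, g2$rgb)
  # deterministic byte-for-byte output
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  render_heatmap(list(imgS, imgP), layout, path = p1, scale = 3)
  render_heatmap(list(imgS, imgP), layout, path = p2, scale = 3)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_gt(file.size(p1), 100)
  expect_error(render_heatmap(list(imgS, imgP, imgS, imgP), layout), "1-3")
  expect_error(render_heatmap(list(imgS, imgS), layout), "distinct")
  # 16-bit grayscale export
  p3 <- withr::local_tempfile(fileext = ".png")
  write_ion_image_png(imgP, p3)
  expect_identical(readBin(p3, "raw", 8),
                   as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)))
})

test_that("hit calling separates true actives from blanks", {
  layout <- build_layout(2, 4)
  wells <- well_labels(layout)
  actives <- wells[c(2, 5, 7)]
  blanks <- setdiff(wells, actives)
  conv <- stats::setNames(rep(0.8, 3), actives)
  species <- ired_species(layout, actives)
  truth <- ground_truth(layout, species, conv)
  sim <- simulate_membrane(layout, species, truth, seed = 3L)
  ch <- ired_channels(species)
  img <- extract_ion_image(sim$dataset, ch$product)
  q <- quantify_wells(img, layout)
  hits <- call_hits(q, ch$product$label, mode = "threshold",
                    blank_wells = blanks)
  expect_setequal(hits$well, actives)
  expect_identical(hits$rank, seq_len(nrow(hits)))
  expect_false(is.unsorted(rev(hits$corrected)))
  # permutation invariance of the input rows
  qp <- q[sample(nrow(q)), ]
  class(qp) <- class(q)
  expect_equal(call_hits(qp, ch$product$label, "threshold",
                         blank_wells = blanks), hits)
  # isotope false positives are never called
  q2 <- q
  q2$isotope_false_positive[q2$well == actives[[1]]] <- TRUE
  hits2 <- call_hits(q2, ch$product$label, "threshold", blank_wells = blanks)
  expect_false(actives[[1]] %in% hits2$well)
  # top-k with k = plate size returns a total deterministic order
  topall <- call_hits(q, ch$product$label, "top_k", param = 8)
  expect_identical(nrow(topall), 8L)
  expect_identical(topall$rank, 1:8)
  expect_error(call_hits(q, ch$product$label, "threshold"), "top_k")
  expect_error(call_hits(q, ch$product$label, "top_k"), "k >= 1")
})

test_that("an all-blank plate yields an empty hit table", {
  layout <- build_layout(1, 4)
  q <- data.frame(well = well_labels(layout), channel = "prod",
                  raw = c(1, 1.2, 0.9, 1.1), background = 0,
                  corrected = c(1, 1.2, 0.9, 1.1), noise = 1, n_roi = 64L,
                  empty = TRUE, saturated = FALSE,
                  isotope_false_positive = FALSE, conversion = NA_real_)
  class(q) <- c("WellQuant", "data.frame")
  hits <- call_hits(q, "prod", "threshold", blank_wells = c("A1", "A2"))
  # remaining wells sit inside the blank band
  expect_identical(nrow(hits), 0L)
})

test_that("throughput arithmetic matches the raster geometry", {
  expect_equal(estimate_throughput(5, 500, 2000, 0), 25)
  expect_equal(estimate_throughput(5, 500, 2000, 1.9), 44)
  t1 <- estimate_throughput(5, 500, 1000, 0)
  expect_equal(estimate_throughput(5, 500, 2000, 0), t1 / 2)
  expect_equal(estimate_throughput(5, 600, 2000, 0), 9 * 2.5)
  expect_error(estimate_throughput(0, 500, 2000), "positive")
})

test_that("the packaged PAL panel drives threshold hit calling on printed conversions", {
  pal <- load_pal_panel()
  expect_identical(nrow(pal), 21L)
  expect_equal(pal$al11_pct[pal$substrate == "5o"], 92)
  expect_true(pal$pbpal_censored[pal$substrate == "5o"])
  # user-threshold screen: AL-11 actives above 50% conversion
  strong <- pal$substrate[pal$al11_pct > 50]
  expect_true(all(c("5a", "5o", "5q", "5s") %in% strong))
  expect_false("5c" %in% strong)
})

test_that("report bundling writes images and tables", {
  layout <- build_layout(1, 2)
  sim <- sim_ired_plate(layout, c(A1 = 0, A2 = 1), seed = 1L)
  img <- extract_ion_image(sim$dataset, sim$product)
  q <- quantify_wells(img, layout)
  hits <- call_hits(q, sim$product$label, "top_k", param = 2)
  dir <- withr::local_tempdir()
  write_report(dir, img, layout, q, hits, config = list(seed = 1))
  expect_true(all(file.exists(file.path(dir, c("heatmap.png",
                                               "well_quants.csv", "hits.csv",
                                               "hits.json", "config.json")))))
})
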