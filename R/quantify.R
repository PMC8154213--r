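# Core readout: m/z-channel ion images, grid registration, per-well ROI sums
# with local background subtraction, calibration linearity/LOD, and
# semiquantitative conversion estimates.

#' Extract an m/z-channel ion image
#'
#' Per pixel, sums the intensities of all centroids whose m/z lies in
#' `[target - window/2, target + window/2)` (half-open upper bound). When a
#' drift dimension is present all drift bins are summed unless a `gate`
#' restricts them (see [gate_image()]).
#'
#' @param ds `ImagingDataset`.
#' @param channel `ChannelSpec`.
#' @param gate Optional `DriftGate`; only bins whose centers fall inside the
#'   gate contribute.
#' @return An `IonImage`: list with `values` (ny x nx matrix), `channel`,
#'   `pixel_size`.
#' @export
extract_ion_image <- function(ds, channel, gate = NULL) {
  stopifnot(inherits(ds, "ImagingDataset"), inherits(channel, "ChannelSpec"))
  if (channel$polarity != 0L && ds$polarity != 0L &&
      channel$polarity != ds$polarity)
    stop("channel polarity (", channel$polarity,
         ") does not match dataset polarity (", ds$polarity, ")")
  lo <- channel$target_mz - channel$window / 2
  hi <- channel$target_mz + channel$window / 2
  bins <- NULL
  if (!is.null(gate)) {
    if (!has_drift(ds))
      stop("dataset has no drift dimension; cannot apply a drift gate")
    bins <- which(ds$drift_centers >= gate$lo & ds$drift_centers <= gate$hi)
    if (!length(bins)) {
      warning("drift gate [", gate$lo, ", ", gate$hi,
              "] ms is disjoint from the bin range; image is all zero")
    }
  }
  sum_frame <- function(fr) {
    if (!length(fr$mz)) return(0)
    sum(fr$intensity[fr$mz >= lo & fr$mz < hi])
  }
  vals <- vapply(seq_along(ds$spectra), function(i) {
    if (has_drift(ds)) {
      ks <- if (is.null(bins)) seq_along(ds$drift_centers) else bins
      s <- 0
      for (k in ks) s <- s + sum_frame(ds$spectra[[i]][[k]])
      s
    } else {
      sum_frame(ds$spectra[[i]])
    }
  }, numeric(1))
  structure(list(values = matrix(vals, nrow = ds$ny, ncol = ds$nx,
                                 byrow = TRUE),
                 channel = channel, pixel_size = ds$pixel_size),
            class = "IonImage")
}

#' Total ion current image
#'
#' Per-pixel sum over all centroids (and drift bins); used for spot detection
#' during grid registration.
#' @param ds `ImagingDataset`.
#' @return An `IonImage` with a pseudo-channel labelled `"TIC"`.
#' @export
total_ion_image <- function(ds) {
  vals <- vapply(seq_along(ds$spectra), function(i) {
    if (has_drift(ds)) {
      sum(vapply(ds$spectra[[i]], function(fr) sum(fr$intensity), numeric(1)))
    } else {
      sum(ds$spectra[[i]]$intensity)
    }
  }, numeric(1))
  ch <- channel_spec("TIC", target_mz = 1, window = 1,
                     polarity = ds$polarity)
  structure(list(values = matrix(vals, nrow = ds$ny, ncol = ds$nx,
                                 byrow = TRUE),
                 channel = ch, pixel_size = ds$pixel_size),
            class = "IonImage")
}

#' @export
print.IonImage <- function(x, ...) {
  cat(sprintf("<IonImage> %s: %d x %d px, max %.4g\n", x$channel$label,
              ncol(x$values), nrow(x$values), max(x$values)))
  invisible(x)
}

# 4-connected components above a threshold; returns an integer label matrix
label_components <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  labels <- matrix(0L, ny, nx)
  current <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue)) {
      i <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      r <- (i - 1L) %% ny + 1L
      cc <- (i - 1L) %/% ny + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[[1]]; cx <- cc + d[[2]]
        if (rr >= 1L && rr <= ny && cx >= 1L && cx <= nx) {
          jj <- (cx - 1L) * ny + rr
          if (mask[jj] && labels[jj] == 0L) {
            labels[jj] <- current
            queue <- c(queue, jj)
          }
        }
      }
    }
  }
  labels
}

# squared distance from each centroid to its nearest well center under a
# candidate translation; nearest center is analytic on the square lattice
nearest_well_dist2 <- function(cent, layout, dx, dy) {
  cell <- layout$cell_size
  colw <- pmin(pmax(round((cent[, "x"] - dx - layout$origin[[1]]) / cell + 0.5),
                    1), layout$n_cols)
  roww <- pmin(pmax(round((cent[, "y"] - dy - layout$origin[[2]]) / cell + 0.5),
                    1), layout$n_rows)
  wx <- layout$origin[[1]] + (colw - 0.5) * cell + dx
  wy <- layout$origin[[2]] + (roww - 0.5) * cell + dy
  cbind(d2 = (cent[, "x"] - wx)^2 + (cent[, "y"] - wy)^2,
        ex = cent[, "x"] - wx, ey = cent[, "y"] - wy,
        roww = roww, colw = colw)
}

# translation candidate score: truncated quadratic spot-to-well loss plus a
# penalty for on-membrane wells left without any matched spot (disambiguates
# translations aliased by a whole cell). The per-well penalty is cap/2: an
# unexplained bright spot (capped at `cap`) is stronger evidence against a
# candidate than an unmatched well, which may simply be blank.
candidate_score <- function(cent, layout, dx, dy, cap) {
  nd <- nearest_well_dist2(cent, layout, dx, dy)
  cell <- layout$cell_size
  matched <- unique(paste(nd[, "roww"], nd[, "colw"])[nd[, "d2"] < cap])
  wx <- layout$origin[[1]] + (seq_len(layout$n_cols) - 0.5) * cell + dx
  wy <- layout$origin[[2]] + (seq_len(layout$n_rows) - 0.5) * cell + dy
  on_x <- which(wx >= layout$origin[[1]] &
                wx <= layout$origin[[1]] + layout$n_cols * cell)
  on_y <- which(wy >= layout$origin[[2]] &
                wy <= layout$origin[[2]] + layout$n_rows * cell)
  n_on <- length(on_x) * length(on_y)
  n_missing <- n_on - sum(matched %in%
    as.vector(outer(on_y, on_x, function(r, cc) paste(r, cc))))
  sum(pmin(nd[, "d2"], cap)) + cap / 2 * n_missing
}

#' Register the plate grid against detected spots
#'
#' Detects bright spots in a TIC (or other) ion image as 4-connected
#' components above an automatic threshold and computes their
#' intensity-weighted centroids. The grid translation is found by a coarse
#' search (half-pixel steps over +/- `max_shift`, truncated quadratic loss to
#' tolerate clipped edge spots), then refined by least squares over the
#' centroids after trimming outliers (spots clipped at the membrane edge).
#'
#' @param tic `IonImage` (typically [total_ion_image()]).
#' @param layout `PlateLayout`.
#' @param max_shift Maximum |dx|, |dy| in mm (default one cell).
#' @param min_spot_pixels Minimum component size counted as a spot.
#' @return A `Registration`: list with `dx`, `dy` (mm), `residual` (mm RMS
#'   over the retained spot centroids), `n_spots_used`.
#' @export
register_grid <- function(tic, layout, max_shift = NULL,
                          min_spot_pixels = 3L) {
  stopifnot(inherits(tic, "IonImage"), inherits(layout, "PlateLayout"))
  if (is.null(max_shift)) max_shift <- layout$cell_size
  v <- tic$values
  bg <- stats::median(v)
  thr <- bg + 0.25 * (max(v) - bg)
  if (max(v) <= 0 || thr <= bg)
    stop("no spots detected above threshold; supply a manual offset")
  labels <- label_components(v > thr)
  n_comp <- max(labels)
  if (n_comp == 0L)
    stop("no spots detected above threshold; supply a manual offset")
  px <- tic$pixel_size / 1000
  cent <- do.call(rbind, lapply(seq_len(n_comp), function(k) {
    idx <- which(labels == k)
    if (length(idx) < min_spot_pixels) return(NULL)
    r <- (idx - 1L) %% nrow(v) + 1L
    cc <- (idx - 1L) %/% nrow(v) + 1L
    w <- v[idx]
    # spots touching the image border are clipped at the membrane edge and
    # carry biased centroids; they still help locate the grid coarsely but
    # are excluded from the least-squares refinement
    clipped <- any(r == 1L) || any(r == nrow(v)) ||
      any(cc == 1L) || any(cc == ncol(v))
    c(x = layout$origin[[1]] + (sum((cc - 0.5) * w) / sum(w)) * px,
      y = layout$origin[[2]] + (sum((r - 0.5) * w) / sum(w)) * px,
      clipped = as.numeric(clipped))
  }))
  if (is.null(cent) || nrow(cent) == 0L)
    stop("no spots detected above threshold; supply a manual offset")

  # coarse search over all spots; truncated loss + missing-well penalty
  # (clipped spots are the evidence that separates whole-cell aliases)
  step <- px / 2
  cand <- seq(-max_shift, max_shift, by = step)
  cap <- (layout$cell_size / 4)^2
  best <- c(0, 0); best_score <- Inf
  for (cdx in cand) for (cdy in cand) {
    score <- candidate_score(cent, layout, cdx, cdy, cap)
    # infinitesimal preference for the smaller shift: an exact score tie
    # between a translation and its whole-cell alias (possible when edge
    # wells are blank) resolves to the smaller correction
    score <- score + 1e-9 * (cdx^2 + cdy^2)
    if (score < best_score) {
      best_score <- score
      best <- c(cdx, cdy)
    }
  }
  dx <- best[[1]]; dy <- best[[2]]
  clean <- cent[cent[, "clipped"] == 0, , drop = FALSE]
  if (nrow(clean) == 0L) clean <- cent
  keep <- seq_len(nrow(clean))
  for (it in 1:3) {
    nd <- nearest_well_dist2(clean[keep, , drop = FALSE], layout, dx, dy)
    res_i <- sqrt(nd[, "d2"])
    tol <- max(px, 3 * stats::median(res_i))
    keep <- keep[res_i <= tol]
    if (!length(keep)) break
    nd <- nearest_well_dist2(clean[keep, , drop = FALSE], layout, dx, dy)
    dx <- max(min(dx + mean(nd[, "ex"]), max_shift), -max_shift)
    dy <- max(min(dy + mean(nd[, "ey"]), max_shift), -max_shift)
  }
  if (!length(keep)) keep <- seq_len(nrow(clean))
  nd <- nearest_well_dist2(clean[keep, , drop = FALSE], layout, dx, dy)
  res <- sqrt(mean(nd[, "d2"]))
  structure(list(dx = dx, dy = dy, residual = res,
                 n_spots_used = length(keep)),
            class = "Registration")
}

#' @export
print.Registration <- function(x, ...) {
  cat(sprintf("<Registration> dx %.3f mm, dy %.3f mm (RMS %.3f mm, %d spots)\n",
              x$dx, x$dy, x$residual, x$n_spots_used))
  invisible(x)
}

null_registration <- function() {
  structure(list(dx = 0, dy = 0, residual = 0, n_spots_used = 0L),
            class = "Registration")
}

roi_pixels <- function(layout, registration, img_dim, pixel_size, margin) {
  # per well: ROI = central square after trimming `margin` per side;
  # background frame = remaining border pixels of the same cell
  px <- pixel_size / 1000
  ny <- img_dim[[1]]; nx <- img_dim[[2]]
  wc <- well_centers(layout)
  cell <- layout$cell_size
  trim <- margin * cell
  lapply(seq_len(nrow(wc)), function(i) {
    x0 <- layout$origin[[1]] + (wc$col[[i]] - 1L) * cell + registration$dx
    y0 <- layout$origin[[2]] + (wc$row[[i]] - 1L) * cell + registration$dy
    in_rect <- function(ax0, ay0, ax1, ay1) {
      ixs <- max(0L, ceiling((ax0 - layout$origin[[1]]) / px - 0.5)):
             min(nx - 1L, ceiling((ax1 - layout$origin[[1]]) / px - 0.5) - 1L)
      iys <- max(0L, ceiling((ay0 - layout$origin[[2]]) / px - 0.5)):
             min(ny - 1L, ceiling((ay1 - layout$origin[[2]]) / px - 0.5) - 1L)
      if (ixs[[1]] > ixs[[length(ixs)]] || iys[[1]] > iys[[length(iys)]])
        return(integer(0))
      as.integer(outer(iys * nx, ixs, `+`)) + 1L
    }
    cell_px <- in_rect(x0, y0, x0 + cell, y0 + cell)
    roi <- in_rect(x0 + trim, y0 + trim, x0 + cell - trim, y0 + cell - trim)
    list(well = wc$well[[i]], roi = roi, border = setdiff(cell_px, roi))
  })
}

#' Per-well ROI quantification with background subtraction
#'
#' For every well and every supplied ion image: the raw sum over the
#' margin-trimmed central ROI; a background estimate as the median pixel
#' intensity of the trimmed-off border frame of the same cell (robust to
#' row/column drift); and the corrected sum
#' `max(raw - background * n_roi, 0)`. A well/channel is flagged `empty` when
#' its corrected sum is at most `3 * mad(border) * n_roi`.
#'
#' @param images List of `IonImage`s (must share dimensions).
#' @param layout `PlateLayout`.
#' @param registration Optional `Registration` (default: no shift). A
#'   residual above `cell_size / 2` is rejected as a grid mismatch.
#' @param margin Fraction of the cell edge trimmed per side (default 0.1).
#' @return A `WellQuant` data.frame: one row per well x channel with columns
#'   `well`, `channel`, `raw`, `background`, `corrected`, `noise`, `n_roi`,
#'   `empty`, `saturated`, `isotope_false_positive`, `conversion`.
#' @export
quantify_wells <- function(images, layout, registration = NULL,
                           margin = 0.1) {
  if (inherits(images, "IonImage")) images <- list(images)
  stopifnot(length(images) >= 1L, inherits(layout, "PlateLayout"))
  dims <- lapply(images, function(im) dim(im$values))
  if (!all(vapply(dims, identical, logical(1), y = dims[[1]])))
    stop("ion images must share dimensions")
  if (is.null(registration)) registration <- null_registration()
  if (registration$residual > layout$cell_size / 2)
    stop("registration residual (", signif(registration$residual, 3),
         " mm) exceeds half a cell: grid mismatch")
  rois <- roi_pixels(layout, registration, dims[[1]],
                     images[[1]]$pixel_size, margin)
  out <- do.call(rbind, lapply(images, function(im) {
    v <- im$values  # note: values matrix is [ny, nx] row-major pixel index
    vt <- as.numeric(t(v))  # index by 0-based pixel id + 1
    do.call(rbind, lapply(rois, function(r) {
      raw <- sum(vt[r$roi])
      bg <- if (length(r$border)) stats::median(vt[r$border]) else 0
      bmad <- if (length(r$border)) stats::mad(vt[r$border]) else 0
      corrected <- max(raw - bg * length(r$roi), 0)
      data.frame(well = r$well, channel = im$channel$label, raw = raw,
                 background = bg, corrected = corrected,
                 noise = bmad * length(r$roi), n_roi = length(r$roi),
                 empty = corrected <= 3 * bmad * length(r$roi),
                 saturated = FALSE, isotope_false_positive = FALSE,
                 conversion = NA_real_, stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  class(out) <- c("WellQuant", "data.frame")
  out
}

#' Fit a calibration line with saturation exclusion and LOD
#'
#' Ordinary least squares of summed ROI intensity versus concentration.
#' Saturation is detected against an initial line anchored on the three
#' lowest concentrations (the most linear end of the series; an all-point
#' initial fit would be dominated by the leverage of a saturated top point):
#' points falling more than 20% below that line's prediction are flagged
#' saturated and excluded from the final fit. `r_squared` is the squared
#' Pearson correlation of the retained points; the limit of detection is the
#' ICH-style `3.3 * sigma / slope` with `sigma` the SD of the final-fit
#' residuals.
#'
#' @param concs Concentrations (mM), length >= 3.
#' @param sums Summed ROI intensities, same length.
#' @return A `CalibrationResult`: `slope`, `intercept`, `r_squared`, `lod`
#'   (mM), `linear_range` (mM), `saturated_points` (indices into the input).
#' @export
fit_calibration <- function(concs, sums) {
  if (length(concs) != length(sums)) stop("concs and sums differ in length")
  if (length(concs) < 3L) stop("need at least 3 calibration points")
  anchor <- order(concs)[1:3]
  fit0 <- stats::lm(sums[anchor] ~ concs[anchor])
  pred <- stats::coef(fit0)[[1]] + stats::coef(fit0)[[2]] * concs
  saturated <- which(pred > 0 & (sums - pred) / pred < -0.2)
  keep <- setdiff(seq_along(concs), saturated)
  if (length(keep) < 3L)
    stop("fewer than 3 unsaturated calibration points")
  fit <- stats::lm(sums[keep] ~ concs[keep])
  slope <- unname(stats::coef(fit)[[2]])
  intercept <- unname(stats::coef(fit)[[1]])
  r2 <- stats::cor(concs[keep], sums[keep])^2
  sigma <- stats::sd(stats::residuals(fit))
  lod <- if (slope > 0) 3.3 * sigma / slope else Inf
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 lod = lod,
                 linear_range = range(concs[keep]),
                 saturated_points = saturated),
            class = "CalibrationResult")
}

#' @export
print.CalibrationResult <- function(x, ...) {
  cat(sprintf(paste0("<CalibrationResult> slope %.4g, R^2 %.5f, ",
                     "LOD %.3g mM, linear %g-%g mM, %d saturated point(s)\n"),
              x$slope, x$r_squared, x$lod, x$linear_range[[1]],
              x$linear_range[[2]], length(x$saturated_points)))
  invisible(x)
}

#' Semiquantitative conversion estimate per well
#'
#' Estimates conversion as `P / (P + r * S)` from corrected product (P) and
#' substrate (S) sums. `r` is the product/substrate response ratio (intensity
#' per mM); it defaults to 1, which assumes equal ionization efficiency and
#' membrane affinity of substrate and product -- treat cross-compound
#' comparisons under this default as semiquantitative at best. Wells whose
#' total `P + S` falls below the empty threshold are left undefined (NA,
#' `empty` flag).
#'
#' @param quants `WellQuant` containing both channels.
#' @param substrate_channel,product_channel Channel labels.
#' @param response_ratio r > 0.
#' @return The `WellQuant` with the `conversion` column filled on the product
#'   rows (NA where undefined).
#' @export
estimate_conversion <- function(quants, substrate_channel, product_channel,
                                response_ratio = 1) {
  stopifnot(inherits(quants, "WellQuant"))
  if (!is.numeric(response_ratio) || response_ratio <= 0)
    stop("response_ratio must be > 0")
  for (ch in c(substrate_channel, product_channel))
    if (!ch %in% quants$channel) stop("channel not quantified: ", ch)
  prows <- which(quants$channel == product_channel)
  for (i in prows) {
    w <- quants$well[[i]]
    j <- which(quants$well == w & quants$channel == substrate_channel)
    if (!length(j)) next
    P <- quants$corrected[[i]]
    S <- quants$corrected[[j[[1]]]]
    thr <- 3 * max(quants$noise[[i]], quants$noise[[j[[1]]]])
    if (P + S <= thr) {
      quants$conversion[[i]] <- NA_real_
      quants$empty[[i]] <- TRUE
    } else {
      quants$conversion[[i]] <- P / (P + response_ratio * S)
    }
  }
  quants
}

#' Export well quantifications as CSV
#' @param quants `WellQuant`.
#' @param path File path.
#' @export
write_quants_csv <- function(quants, path) {
  utils::write.csv(as.data.frame(quants), path, row.names = FALSE)
  invisible(path)
}
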