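# Drift-time gating and isotope-interference handling.
#
# An imine-to-amine reduction gives a product only two mass units above its
# substrate, so the substrate's M+2 isotopologue is m/z-coincident with the
# product ion and every substrate-containing well shows a low-intensity false
# positive in the product channel. With an ion-mobility dimension the false
# positive is removed by gating the product channel on the product's drift
# time; without one, the predicted envelope fraction of the substrate is
# subtracted arithmetically. When both are available, gating is applied first
# and subtraction second (residual leakage).

#' Drift gate
#' @param lo,hi Gate bounds in ms (`lo < hi`).
#' @return A `DriftGate`.
#' @export
drift_gate <- function(lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi)
    stop("drift gate requires lo < hi")
  structure(list(lo = lo, hi = hi), class = "DriftGate")
}

#' @export
print.DriftGate <- function(x, ...) {
  cat(sprintf("<DriftGate> [%.3g, %.3g] ms\n", x$lo, x$hi))
  invisible(x)
}

#' Summed drift-time profile of a channel over selected wells
#'
#' @param ds `ImagingDataset` with a drift dimension.
#' @param channel `ChannelSpec`.
#' @param layout `PlateLayout`.
#' @param wells Well labels to pool (default: all).
#' @param registration Optional `Registration`.
#' @param margin ROI margin fraction.
#' @return A `DriftProfile`: list with `centers` (ms), `intensity` (per-bin
#'   channel sum over the wells' ROIs), `channel`, `wells`.
#' @export
extract_drift_profile <- function(ds, channel, layout, wells = NULL,
                                  registration = NULL, margin = 0.1) {
  stopifnot(inherits(ds, "ImagingDataset"))
  if (!has_drift(ds))
    stop("dataset has no drift dimension; use subtract_isotope_interference()")
  if (is.null(registration)) registration <- null_registration()
  if (is.null(wells)) wells <- well_labels(layout)
  rois <- roi_pixels(layout, registration, c(ds$ny, ds$nx), ds$pixel_size,
                     margin)
  pix <- unlist(lapply(rois, function(r) if (r$well %in% wells) r$roi))
  lo <- channel$target_mz - channel$window / 2
  hi <- channel$target_mz + channel$window / 2
  intensity <- vapply(seq_along(ds$drift_centers), function(k) {
    s <- 0
    for (i in pix) {
      fr <- ds$spectra[[i]][[k]]
      if (length(fr$mz))
        s <- s + sum(fr$intensity[fr$mz >= lo & fr$mz < hi])
    }
    s
  }, numeric(1))
  structure(list(centers = ds$drift_centers, intensity = intensity,
                 channel = channel, wells = wells),
            class = "DriftProfile")
}

#' @export
print.DriftProfile <- function(x, ...) {
  cat(sprintf("<DriftProfile> %s over %d wells, %d bins (%.3g-%.3g ms)\n",
              x$channel$label, length(x$wells), length(x$centers),
              min(x$centers), max(x$centers)))
  invisible(x)
}

#' Export a drift profile as CSV
#' @param profile `DriftProfile`.
#' @param path File path.
#' @export
write_drift_profile_csv <- function(profile, path) {
  utils::write.csv(data.frame(drift_ms = profile$centers,
                              intensity = profile$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

# local maxima of a per-bin profile (plateaus keep the left-most bin)
profile_modes <- function(y) {
  n <- length(y)
  if (n == 1L) return(if (y > 0) 1L else integer(0))
  left <- c(-Inf, y[-n]); right <- c(y[-1], -Inf)
  which(y > 0 & y > left & y >= right)
}

#' Fit a drift gate around the mode nearest an expected center
#'
#' Finds the profile mode closest to `expected_center`, estimates the SD of
#' that mode by a single-Gaussian moment fit over its contiguous flank region,
#' and returns the gate `expected_center +/- width_sd * SD`. If another mode's
#' center would fall inside, the gate is tightened to the midpoint towards
#' that mode (with a warning).
#'
#' @param profile `DriftProfile`.
#' @param expected_center Expected drift time (ms); must lie within the
#'   observed bin range.
#' @param width_sd Half-width in fitted SDs (default 2, capturing ~95% of a
#'   Gaussian drift peak).
#' @return A `DriftGate`.
#' @export
fit_gate <- function(profile, expected_center, width_sd = 2) {
  y <- profile$intensity
  ctr <- profile$centers
  if (all(y <= 0) || max(y) == min(y))
    stop("drift profile is flat; cannot fit a gate")
  if (expected_center < min(ctr) || expected_center > max(ctr))
    stop("expected drift center ", expected_center,
         " ms lies outside the observed range [", min(ctr), ", ",
         max(ctr), "] ms")
  modes <- profile_modes(y)
  if (!length(modes)) stop("drift profile has no modes")
  m <- modes[[which.min(abs(ctr[modes] - expected_center))]]
  # contiguous region around the mode down to the nearest local minimum
  lo_i <- m
  while (lo_i > 1L && y[[lo_i - 1L]] < y[[lo_i]]) lo_i <- lo_i - 1L
  hi_i <- m
  while (hi_i < length(y) && y[[hi_i + 1L]] < y[[hi_i]]) hi_i <- hi_i + 1L
  idx <- lo_i:hi_i
  w <- y[idx]
  mu <- sum(ctr[idx] * w) / sum(w)
  sd_fit <- sqrt(sum((ctr[idx] - mu)^2 * w) / sum(w))
  bin_w <- if (length(ctr) > 1L) min(diff(ctr)) else 1
  sd_fit <- max(sd_fit, bin_w / 4)  # floor for single-bin peaks
  lo <- expected_center - width_sd * sd_fit
  hi <- expected_center + width_sd * sd_fit
  others <- setdiff(modes, m)
  for (o in others) {
    if (ctr[[o]] > lo && ctr[[o]] < expected_center) {
      lo <- (expected_center + ctr[[o]]) / 2
      warning("gate tightened to exclude mode at ", ctr[[o]], " ms")
    }
    if (ctr[[o]] < hi && ctr[[o]] > expected_center) {
      hi <- (expected_center + ctr[[o]]) / 2
      warning("gate tightened to exclude mode at ", ctr[[o]], " ms")
    }
  }
  drift_gate(lo, hi)
}

#' Drift-gated ion image
#'
#' As [extract_ion_image()] but summing only the drift bins whose centers lie
#' inside the gate. A gate covering every bin reproduces the ungated image
#' bit-exactly.
#'
#' @param ds `ImagingDataset` with drift dimension.
#' @param channel `ChannelSpec`.
#' @param gate `DriftGate`.
#' @return An `IonImage`.
#' @export
gate_image <- function(ds, channel, gate) {
  stopifnot(inherits(gate, "DriftGate"))
  if (!has_drift(ds)) stop("dataset has no drift dimension")
  extract_ion_image(ds, channel, gate = gate)
}

#' Arithmetic subtraction of predicted isotope interference
#'
#' Fallback for datasets without a mobility dimension: reduces each well's
#' corrected product sum by
#' `interference_fraction(substrate_envelope, product m/z, window) *`
#' the well's corrected substrate sum (floored at zero). Wells whose entire
#' product signal is explained by the predicted interference within 3x the
#' ROI noise estimate are flagged `isotope_false_positive`. The operation
#' records itself on the result and is idempotent: re-applying it to its own
#' output is a no-op.
#'
#' @param quants `WellQuant` with both channels quantified.
#' @param substrate_envelope `IsotopeEnvelope` of the substrate ion.
#' @param product_channel,substrate_channel Channel labels.
#' @param product_mz,window Product channel center/window; defaults are taken
#'   from attributes when `quants` rows carry them, otherwise must be given.
#' @return The corrected `WellQuant`.
#' @export
subtract_isotope_interference <- function(quants, substrate_envelope,
                                          product_channel, substrate_channel,
                                          product_mz, window = 0.2) {
  stopifnot(inherits(quants, "WellQuant"))
  if (!inherits(substrate_envelope, "IsotopeEnvelope"))
    stop("substrate_envelope must be an IsotopeEnvelope")
  for (ch in c(substrate_channel, product_channel))
    if (!ch %in% quants$channel) stop("channel not quantified: ", ch)
  key <- paste(product_channel, substrate_channel, sep = "|")
  done <- attr(quants, "isotope_corrected")
  if (!is.null(done) && key %in% done) return(quants)
  f <- interference_fraction(substrate_envelope, product_mz, window)
  prows <- which(quants$channel == product_channel)
  for (i in prows) {
    w <- quants$well[[i]]
    j <- which(quants$well == w & quants$channel == substrate_channel)
    if (!length(j)) next
    S <- quants$corrected[[j[[1]]]]
    P <- quants$corrected[[i]]
    quants$corrected[[i]] <- max(P - f * S, 0)
    if (P <= f * S + 3 * quants$noise[[i]] && S > 0)
      quants$isotope_false_positive[[i]] <- TRUE
  }
  attr(quants, "isotope_corrected") <- c(done, key)
  quants
}
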