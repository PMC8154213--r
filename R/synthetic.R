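# Synthetic DESI-membrane generator with ground-truth manifest.
#
# Emulates the statistical structure the analysis assumes: square reaction
# spots on a scored membrane grid, an isotropic Gaussian deposition profile
# truncated at the cell edge, a linear-then-saturating (Langmuir-type)
# intensity response I = rf*c/(1 + c/K) with K ~ 1 mM, natural-abundance
# isotopologue envelopes, species-specific drift times spread over drift bins,
# and signal-dependent Gaussian noise (a Poisson surrogate) with
# SD = noise_scale * sqrt(signal + baseline).
#
# Intensities are quantized to 32-bit float precision at generation time so
# that in-memory datasets round-trip bit-identically through imzML (whose
# intensity arrays are 32-bit).

snap_float32 <- function(x) {
  if (!length(x)) return(numeric(0))
  readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
          what = "double", n = length(x), size = 4L, endian = "little")
}

#' Per-compound intensity response model
#'
#' @param response_factor Intensity per mM in the linear regime (> 0).
#' @param saturation_level Langmuir constant K in mM; intensity is
#'   `rf * c / (1 + c / K)`, i.e. response saturates above ~K (default 1 mM).
#'   Use `Inf` for a purely linear response.
#' @param baseline Additive baseline intensity per recorded centroid.
#' @param noise_scale Noise SD multiplier (SD = `noise_scale * sqrt(I)`).
#' @return A `ResponseModel`.
#' @export
response_model <- function(response_factor = 2e4, saturation_level = 1.0,
                           baseline = 1.0, noise_scale = 0.05) {
  if (response_factor <= 0) stop("response_factor must be > 0")
  if (saturation_level <= 0) stop("saturation_level must be > 0")
  structure(list(response_factor = response_factor,
                 saturation_level = saturation_level,
                 baseline = baseline, noise_scale = noise_scale),
            class = "ResponseModel")
}

response_intensity <- function(rm, conc_mM) {
  if (is.infinite(rm$saturation_level)) return(rm$response_factor * conc_mM)
  rm$response_factor * conc_mM / (1 + conc_mM / rm$saturation_level)
}

#' Instrument / acquisition parameters for the generator
#'
#' @param pixel_size Pixel edge in micrometres (default 500).
#' @param stage_speed Stage raster speed in micrometres per second (default
#'   2000); recorded in the manifest and used by [estimate_throughput()].
#' @param spot_fwhm Full width at half maximum of the dried-spot Gaussian
#'   profile, mm (default 2).
#' @param mz_jitter_sd Per-centroid m/z jitter SD in Da (default 0.005,
#'   emulating finite resolution/rebinning).
#' @param drift_bins Number of drift-time bins; 0 disables the mobility
#'   dimension.
#' @param drift_start Center of the first drift bin, ms.
#' @param drift_resolution Drift bin width, ms.
#' @param drift_sd Per-species drift-peak SD, ms.
#' @return An `InstrumentParams`.
#' @export
instrument_params <- function(pixel_size = 500, stage_speed = 2000,
                              spot_fwhm = 2, mz_jitter_sd = 0.005,
                              drift_bins = 0L, drift_start = 3.0,
                              drift_resolution = 0.5, drift_sd = 0.5) {
  if (pixel_size <= 0 || stage_speed <= 0 || spot_fwhm <= 0)
    stop("pixel_size, stage_speed and spot_fwhm must be positive")
  structure(list(pixel_size = pixel_size, stage_speed = stage_speed,
                 spot_fwhm = spot_fwhm, mz_jitter_sd = mz_jitter_sd,
                 drift_bins = as.integer(drift_bins),
                 drift_start = drift_start,
                 drift_resolution = drift_resolution, drift_sd = drift_sd),
            class = "InstrumentParams")
}

drift_bin_centers <- function(instrument) {
  if (instrument$drift_bins <= 0L) return(NULL)
  instrument$drift_start +
    (seq_len(instrument$drift_bins) - 1L) * instrument$drift_resolution
}

#' Ground-truth manifest for a simulated plate
#'
#' Records, per well, the true conversion fraction and the resulting
#' substrate/product concentrations (conversion = product / (substrate +
#' product)), plus the per-compound response models. Wells of the layout
#' absent from `conversion` and carrying no species are blanks.
#'
#' @param layout `PlateLayout`.
#' @param species `SpeciesTable`; every well referenced must appear in
#'   `conversion` (or carry only role-`"other"` species).
#' @param conversion Named numeric vector (well -> true conversion in
#'   \[0, 1\]).
#' @param total_mM Total substrate+product concentration per well (default
#'   0.1 mM, inside the linear response range).
#' @param responses Named list formula -> `ResponseModel`; a single unnamed
#'   `ResponseModel` (or the default) applies to every compound.
#' @param seed Integer seed recorded for reproducibility.
#' @return A `GroundTruthManifest`.
#' @export
ground_truth <- function(layout, species, conversion, total_mM = 0.1,
                         responses = response_model(), seed = NA_integer_) {
  stopifnot(inherits(layout, "PlateLayout"), inherits(species, "SpeciesTable"))
  missing_lab <- setdiff(species$well, well_labels(layout))
  if (length(missing_lab))
    stop("species wells not in layout: ", paste(missing_lab, collapse = ", "))
  sp_wells <- unique(species$well[species$role %in% c("substrate", "product")])
  uncovered <- setdiff(sp_wells, names(conversion))
  if (length(uncovered))
    stop("wells lacking a true conversion: ",
         paste(uncovered, collapse = ", "))
  if (length(conversion) && (any(conversion < 0) || any(conversion > 1)))
    stop("conversions must lie in [0, 1]")
  wells <- data.frame(well = names(conversion),
                      conversion = as.numeric(conversion),
                      total_mM = rep_len(total_mM, length(conversion)),
                      stringsAsFactors = FALSE)
  wells$substrate_mM <- wells$total_mM * (1 - wells$conversion)
  wells$product_mM <- wells$total_mM * wells$conversion
  if (inherits(responses, "ResponseModel")) {
    forms <- unique(species$formula)
    responses <- stats::setNames(rep(list(responses), length(forms)), forms)
  }
  missing_rm <- setdiff(unique(species$formula), names(responses))
  if (length(missing_rm))
    stop("no response model for: ", paste(missing_rm, collapse = ", "))
  structure(list(wells = wells, responses = responses, seed = seed,
                 version = "1.0"),
            class = "GroundTruthManifest")
}

species_concentration <- function(truth, well, role, total_override = NULL) {
  w <- truth$wells[truth$wells$well == well, , drop = FALSE]
  if (nrow(w) == 0L) return(0)
  switch(role,
         substrate = w$substrate_mM[[1]],
         product = w$product_mM[[1]],
         other = w$total_mM[[1]])
}

#' Simulate a raster-scanned membrane bearing reaction spots
#'
#' Builds per-pixel centroid spectra: for each species in a pixel's well the
#' intensity is the Gaussian spot profile (FWHM = `spot_fwhm`, centered at the
#' well center, truncated at the cell edge) times the saturating concentration
#' response, distributed over the species' isotopologue envelope (masses
#' jittered by `mz_jitter_sd`), plus `baseline`; Gaussian noise with
#' SD = `noise_scale * sqrt(signal + baseline)` is added and negatives are
#' clipped to zero. With `drift_bins > 0` each species' intensity is spread
#' over drift bins as a Gaussian at the species' `drift_ms`. An identical seed
#' yields a bit-identical dataset.
#'
#' @param layout `PlateLayout`.
#' @param species `SpeciesTable` with a `drift_ms` per species when the drift
#'   dimension is enabled.
#' @param truth `GroundTruthManifest` covering every substrate/product well.
#' @param instrument `InstrumentParams`.
#' @param seed Integer RNG seed.
#' @param offset Length-2 mm translation applied to every spot (simulates
#'   stage misregistration; recovered by [register_grid()]).
#' @param path Optional output stem; when given, the dataset is written as
#'   imzML and the manifest as `<path>_manifest.json`.
#' @return List with `dataset` (`ImagingDataset`) and `manifest`.
#' @export
simulate_membrane <- function(layout, species, truth,
                              instrument = instrument_params(), seed = 1L,
                              offset = c(0, 0), path = NULL) {
  stopifnot(inherits(layout, "PlateLayout"), inherits(species, "SpeciesTable"),
            inherits(truth, "GroundTruthManifest"))
  sp_wells <- unique(species$well[species$role %in% c("substrate", "product")])
  uncovered <- setdiff(sp_wells, truth$wells$well)
  if (length(uncovered))
    stop("wells lacking ground truth: ", paste(uncovered, collapse = ", "))
  set.seed(as.integer(seed))

  px <- instrument$pixel_size / 1000  # mm
  cell <- layout$cell_size
  nx <- floor(layout$n_cols * cell / px + 1e-9)
  ny <- floor(layout$n_rows * cell / px + 1e-9)
  sigma <- instrument$spot_fwhm / (2 * sqrt(2 * log(2)))
  centers <- drift_bin_centers(instrument)
  n_bins <- if (is.null(centers)) 1L else length(centers)
  use_drift <- !is.null(centers)
  if (use_drift) {
    need_drift <- species$role %in% c("substrate", "product", "other")
    if (any(is.na(species$drift_ms[need_drift])))
      stop("drift dimension enabled but species table lacks drift_ms")
  }

  polarity <- adduct_spec(species$adduct[[1]])$polarity
  if (polarity == 0L) polarity <- 1L
  env_cache <- list()
  get_env <- function(formula, adduct) {
    key <- paste(formula, adduct)
    if (is.null(env_cache[[key]]))
      env_cache[[key]] <<- isotope_envelope(formula, adduct)
    env_cache[[key]]
  }

  # accumulator: per pixel, per bin, list of (mz, intensity) chunks
  acc <- vector("list", nx * ny)

  wc <- well_centers(layout)
  for (wi in seq_len(nrow(wc))) {
    lab <- wc$well[[wi]]
    rows <- which(species$well == lab)
    if (!length(rows)) next
    cx <- wc$x[[wi]] + offset[[1]]
    cy <- wc$y[[wi]] + offset[[2]]
    # footprint: the (shifted) cell rectangle, half-open
    x0 <- layout$origin[[1]] + (wc$col[[wi]] - 1L) * cell + offset[[1]]
    y0 <- layout$origin[[2]] + (wc$row[[wi]] - 1L) * cell + offset[[2]]
    ix_lo <- max(0L, ceiling((x0 - layout$origin[[1]]) / px - 0.5))
    ix_hi <- min(nx - 1L,
                 ceiling((x0 + cell - layout$origin[[1]]) / px - 0.5) - 1L)
    iy_lo <- max(0L, ceiling((y0 - layout$origin[[2]]) / px - 0.5))
    iy_hi <- min(ny - 1L,
                 ceiling((y0 + cell - layout$origin[[2]]) / px - 0.5) - 1L)
    if (ix_lo > ix_hi || iy_lo > iy_hi) next  # spot entirely off the membrane
    ix_range <- ix_lo:ix_hi
    iy_range <- iy_lo:iy_hi
    pcx <- layout$origin[[1]] + (ix_range + 0.5) * px
    pcy <- layout$origin[[2]] + (iy_range + 0.5) * px
    d2 <- outer((pcy - cy)^2, (pcx - cx)^2, `+`)  # [length(iy), length(ix)]
    profile <- as.numeric(exp(-d2 / (2 * sigma^2)))  # column-major
    pix_idx <- as.integer(outer(iy_range * nx, ix_range, `+`)) + 1L
    n_pix <- length(pix_idx)

    for (si in rows) {
      conc <- species_concentration(truth, lab, species$role[[si]])
      if (conc <= 0) next
      rm <- truth$responses[[species$formula[[si]]]]
      amp <- response_intensity(rm, conc)
      env <- get_env(species$formula[[si]], species$adduct[[si]])
      n_peaks <- length(env$mass)
      jitter <- if (instrument$mz_jitter_sd > 0)
        matrix(stats::rnorm(n_pix * n_peaks, sd = instrument$mz_jitter_sd),
               n_pix, n_peaks)
      else matrix(0, n_pix, n_peaks)
      mz_mat <- sweep(jitter, 2L, env$mass, `+`)
      base_int <- outer(profile * amp, env$abundance)  # [pix, peak]
      w <- if (use_drift) {
        dw <- stats::dnorm(centers, species$drift_ms[[si]], instrument$drift_sd)
        if (sum(dw) <= 0) dw[which.min(abs(centers - species$drift_ms[[si]]))] <- 1
        dw / sum(dw)
      } else 1
      for (k in seq_len(n_bins)) {
        det <- base_int * (if (use_drift) w[[k]] else 1) + rm$baseline
        val <- if (rm$noise_scale > 0)
          det + stats::rnorm(length(det), sd = rm$noise_scale * sqrt(det))
        else det
        val[val < 0] <- 0
        val <- matrix(snap_float32(val), n_pix, n_peaks)
        for (p in seq_len(n_pix)) {
          i <- pix_idx[[p]]
          if (is.null(acc[[i]])) acc[[i]] <- vector("list", n_bins)
          acc[[i]][[k]] <- c(acc[[i]][[k]],
                             list(list(mz = mz_mat[p, ], intensity = val[p, ])))
        }
      }
    }
  }

  assemble <- function(chunks) {
    if (is.null(chunks)) return(empty_spectrum())
    mz <- unlist(lapply(chunks, `[[`, "mz"))
    int <- unlist(lapply(chunks, `[[`, "intensity"))
    o <- order(mz)
    list(mz = mz[o], intensity = int[o])
  }
  spectra <- vector("list", nx * ny)
  for (i in seq_len(nx * ny)) {
    if (use_drift) {
      spectra[[i]] <- lapply(seq_len(n_bins), function(k)
        assemble(if (is.null(acc[[i]])) NULL else acc[[i]][[k]]))
    } else {
      spectra[[i]] <- assemble(if (is.null(acc[[i]])) NULL else acc[[i]][[1]])
    }
  }

  ds <- imaging_dataset(spectra, nx, ny, pixel_size = instrument$pixel_size,
                        polarity = polarity, drift_centers = centers,
                        metadata = list(simulated = TRUE, seed = seed))
  manifest <- truth
  manifest$seed <- as.integer(seed)
  manifest$instrument <- unclass(instrument)
  manifest$offset <- as.numeric(offset)
  manifest$layout <- list(n_rows = layout$n_rows, n_cols = layout$n_cols,
                          cell_size = layout$cell_size,
                          origin = layout$origin)
  if (!is.null(path)) {
    write_imzml(ds, path)
    write_manifest_json(manifest, paste0(sub("\\.imzML$", "", path),
                                         "_manifest.json"))
  }
  list(dataset = ds, manifest = manifest)
}

#' Write / read a ground-truth manifest as JSON
#' @param manifest `GroundTruthManifest`.
#' @param path File path.
#' @export
write_manifest_json <- function(manifest, path) {
  out <- unclass(manifest)
  out$responses <- lapply(out$responses, unclass)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_manifest_json
#' @export
read_manifest_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$wells <- as.data.frame(x$wells, stringsAsFactors = FALSE)
  x$responses <- lapply(x$responses, function(r) do.call(response_model, r))
  structure(x, class = "GroundTruthManifest")
}

#' Simulate a calibration dilution series
#'
#' One spot per concentration on a 1 x N grid, emulating a sugar-phosphate
#' dilution series. The default six concentrations span 5 to 100 uM
#' (0.005 to 0.1 mM).
#'
#' @param concentrations mM, positive and distinct (default
#'   `c(0.005, 0.010, 0.025, 0.050, 0.075, 0.100)`).
#' @param response `ResponseModel` for the analyte.
#' @param instrument `InstrumentParams`.
#' @param seed RNG seed.
#' @param formula,adduct Analyte identity (default galactose-1-phosphate,
#'   C6H13O9P, deprotonated).
#' @param cell_size Cell edge in mm.
#' @return List with `dataset`, `manifest`, and `wells` (well label per
#'   concentration, in input order).
#' @export
simulate_calibration_series <- function(concentrations = c(0.005, 0.010, 0.025,
                                                           0.050, 0.075, 0.100),
                                        response = response_model(),
                                        instrument = instrument_params(),
                                        seed = 1L, formula = "C6H13O9P",
                                        adduct = "M-H", cell_size = 5) {
  if (!length(concentrations)) stop("concentration list is empty")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (anyDuplicated(concentrations)) stop("concentrations must be distinct")
  n <- length(concentrations)
  layout <- build_layout(1L, n, cell_size = cell_size)
  labs <- well_labels(layout)
  species <- species_table(labs, rep("product", n), rep(formula, n),
                           rep(adduct, n), rep(5, n), layout = layout)
  truth <- ground_truth(layout, species,
                        conversion = stats::setNames(rep(1, n), labs),
                        total_mM = concentrations, responses = response,
                        seed = as.integer(seed))
  sim <- simulate_membrane(layout, species, truth, instrument, seed = seed)
  c(sim, list(wells = labs))
}

#' Noise scale achieving a target ROI signal-to-noise ratio
#'
#' Runs a noise-free simulation of the given plate, measures the raw ROI sum
#' of `channel` in `well`, and returns the `noise_scale` for which the summed
#' ROI noise SD (`noise_scale * sqrt(sum)`) gives the requested SNR.
#'
#' @param layout,species,truth,instrument As for [simulate_membrane()].
#' @param channel `ChannelSpec` to measure.
#' @param well Reference well label.
#' @param snr Target signal-to-noise ratio.
#' @param margin ROI margin fraction (default 0.1).
#' @return Numeric noise_scale.
#' @export
noise_scale_for_snr <- function(layout, species, truth, instrument, channel,
                                well, snr, margin = 0.1) {
  quiet <- truth
  quiet$responses <- lapply(quiet$responses, function(r) {
    r$noise_scale <- 0; r
  })
  inst0 <- instrument
  inst0$mz_jitter_sd <- 0
  sim <- simulate_membrane(layout, species, quiet, inst0, seed = 1L)
  img <- extract_ion_image(sim$dataset, channel)
  q <- quantify_wells(list(img), layout, margin = margin)
  s <- q$raw[q$well == well]
  if (!length(s) || s[[1]] <= 0) stop("reference well has no signal")
  sqrt(s[[1]]) / snr
}
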