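# In-memory container for raster-scanned MS imaging data.
#
# Spectra are stored as a list of length nx*ny in 0-based row-major pixel
# order (index = iy*nx + ix + 1). Without a drift dimension each element is a
# centroid spectrum list(mz=, intensity=); with a drift dimension each element
# is a list of such frames, one per drift bin (bin centers in $drift_centers).

#' Construct an imaging dataset
#'
#' @param spectra List of length `nx * ny` (row-major). Each element is either
#'   a centroid spectrum `list(mz=, intensity=)` or, when `drift_centers` is
#'   given, a list of one such frame per drift bin.
#' @param nx,ny Pixel counts along x (columns) and y (rows).
#' @param pixel_size Pixel edge in micrometres.
#' @param polarity +1 (positive mode) or -1 (negative mode).
#' @param drift_centers Optional numeric vector of drift-bin centers (ms).
#' @param metadata Free-form named list.
#' @return An `ImagingDataset`.
#' @export
imaging_dataset <- function(spectra, nx, ny, pixel_size = 500, polarity = 1L,
                            drift_centers = NULL, metadata = list()) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (length(spectra) != nx * ny)
    stop("need nx*ny = ", nx * ny, " spectra, got ", length(spectra))
  ds <- structure(list(nx = nx, ny = ny, pixel_size = as.numeric(pixel_size),
                       polarity = as.integer(polarity),
                       drift_centers = drift_centers,
                       spectra = spectra, metadata = metadata),
                  class = "ImagingDataset")
  validate_dataset(ds)
  ds
}

has_drift <- function(ds) !is.null(ds$drift_centers)

validate_dataset <- function(ds) {
  check_frame <- function(fr, where) {
    if (!is.list(fr) || !all(c("mz", "intensity") %in% names(fr)))
      stop("spectrum ", where, " is not a list(mz=, intensity=)")
    if (length(fr$mz) != length(fr$intensity))
      stop("spectrum ", where, ": mz/intensity length mismatch")
    if (is.unsorted(fr$mz)) stop("spectrum ", where, ": m/z not ascending")
    if (length(fr$intensity) && any(fr$intensity < 0))
      stop("spectrum ", where, ": negative intensity")
  }
  for (i in seq_along(ds$spectra)) {
    if (has_drift(ds)) {
      frames <- ds$spectra[[i]]
      if (length(frames) != length(ds$drift_centers))
        stop("pixel ", i, ": expected ", length(ds$drift_centers),
             " drift frames")
      for (k in seq_along(frames)) check_frame(frames[[k]], paste0(i, "/bin", k))
    } else {
      check_frame(ds$spectra[[i]], i)
    }
  }
  invisible(TRUE)
}

#' @export
print.ImagingDataset <- function(x, ...) {
  cat(sprintf("<ImagingDataset> %d x %d pixels, %g um, polarity %+d%s\n",
              x$nx, x$ny, x$pixel_size, x$polarity,
              if (has_drift(x)) sprintf(", %d drift bins", length(x$drift_centers))
              else ""))
  invisible(x)
}

#' Access one pixel's centroid spectrum
#'
#' @param ds `ImagingDataset`.
#' @param ix,iy 0-based pixel indices (column, row).
#' @param drift_bin Optional 1-based drift-bin index; default sums/returns all.
#' @return `list(mz=, intensity=)`. Without `drift_bin` on a drift dataset the
#'   frames are concatenated (sorted by m/z).
#' @export
pixel_spectrum <- function(ds, ix, iy, drift_bin = NULL) {
  i <- iy * ds$nx + ix + 1L
  if (!has_drift(ds)) return(ds$spectra[[i]])
  if (!is.null(drift_bin)) return(ds$spectra[[i]][[drift_bin]])
  mz <- unlist(lapply(ds$spectra[[i]], `[[`, "mz"))
  int <- unlist(lapply(ds$spectra[[i]], `[[`, "intensity"))
  o <- order(mz)
  list(mz = mz[o], intensity = int[o])
}

empty_spectrum <- function() list(mz = numeric(0), intensity = numeric(0))

#' Retain the top-N most intense centroids of a spectrum
#'
#' Emulates the vendor-style "top N peaks" processing step. The `n` highest
#' intensity centroids are kept and returned in ascending m/z order; if the
#' spectrum holds fewer than `n` peaks it is returned unchanged. Intensity
#' ties at the cutoff are broken in favour of the lower-m/z peak.
#'
#' @param x A centroid spectrum `list(mz=, intensity=)` or an
#'   `ImagingDataset` (applied to every frame of every pixel).
#' @param n Number of peaks to keep (>= 1).
#' @return Same shape as `x`.
#' @export
retain_top_n <- function(x, n) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  top1 <- function(sp) {
    if (length(sp$mz) <= n) return(sp)
    o <- order(-sp$intensity, sp$mz)[seq_len(n)]
    keep <- sort(o)
    list(mz = sp$mz[keep], intensity = sp$intensity[keep])
  }
  if (inherits(x, "ImagingDataset")) {
    x$spectra <- if (has_drift(x)) {
      lapply(x$spectra, function(frames) lapply(frames, top1))
    } else {
      lapply(x$spectra, top1)
    }
    return(x)
  }
  top1(x)
}
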