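# Heat-map rendering, hit calling/ranking, throughput arithmetic, and report
# bundling.

#' Render a single- or multi-channel heat map
#'
#' Up to three ion images are mapped onto RGB planes by their channels'
#' display colors (e.g. substrate = red, product = green, so full-conversion
#' wells render green and zero-conversion wells red). Each channel is min-max
#' normalized to its own maximum (`"per_channel"`) or to the common maximum
#' (`"global"`, comparable intensities). A single gray channel renders as a
#' grayscale ramp. The image is upscaled by nearest neighbour, and grid lines
#' and well labels are drawn from the layout. Output is deterministic
#' byte-for-byte.
#'
#' @param images One `IonImage` or a list of up to 3 with distinct display
#'   colors.
#' @param layout `PlateLayout`.
#' @param path Optional PNG output path (8-bit RGB).
#' @param normalization `"per_channel"` or `"global"`.
#' @param scale Integer nearest-neighbour upscaling factor (default 10).
#' @param draw_grid,draw_labels Draw cell boundaries / well labels.
#' @return Invisibly, a list with `rgb` (ny x nx x 3 array, 0-255) and
#'   `legend` (data.frame: channel, color, max_value).
#' @export
render_heatmap <- function(images, layout, path = NULL,
                           normalization = c("per_channel", "global"),
                           scale = 10L, draw_grid = TRUE,
                           draw_labels = TRUE) {
  normalization <- match.arg(normalization)
  if (inherits(images, "IonImage")) images <- list(images)
  if (length(images) < 1L || length(images) > 3L)
    stop("render_heatmap accepts 1-3 ion images")
  cols <- vapply(images, function(im) im$channel$display_color, character(1))
  if (length(images) > 1L && anyDuplicated(cols))
    stop("channels must have distinct display colors")
  dims <- lapply(images, function(im) dim(im$values))
  if (!all(vapply(dims, identical, logical(1), y = dims[[1]])))
    stop("ion images must share dimensions")
  ny <- dims[[1]][[1]]; nx <- dims[[1]][[2]]
  global_max <- max(vapply(images, function(im) max(im$values), numeric(1)))
  planes <- list(red = matrix(0, ny, nx), green = matrix(0, ny, nx),
                 blue = matrix(0, ny, nx))
  legend <- data.frame(channel = character(0), color = character(0),
                       max_value = numeric(0), stringsAsFactors = FALSE)
  for (im in images) {
    mx <- if (normalization == "global") global_max else max(im$values)
    norm <- if (mx > 0) im$values / mx else im$values * 0
    col <- im$channel$display_color
    if (col == "gray") {
      for (p in names(planes)) planes[[p]] <- pmax(planes[[p]], norm)
    } else {
      planes[[col]] <- pmax(planes[[col]], norm)
    }
    legend <- rbind(legend, data.frame(channel = im$channel$label,
                                       color = col, max_value = mx,
                                       stringsAsFactors = FALSE))
  }
  scale <- max(1L, as.integer(scale))
  up <- function(m) kronecker(m, matrix(1, scale, scale))
  planes <- lapply(planes, function(m) round(up(m) * 255))
  NY <- ny * scale; NX <- nx * scale

  if (draw_grid || draw_labels) {
    px_mm <- images[[1]]$pixel_size / 1000
    cell_px <- layout$cell_size / px_mm * scale
    if (draw_grid) {
      xs <- unique(pmin(pmax(round((0:layout$n_cols) * cell_px), 1), NX))
      ys <- unique(pmin(pmax(round((0:layout$n_rows) * cell_px), 1), NY))
      for (p in names(planes)) {
        planes[[p]][ys, ] <- pmax(planes[[p]][ys, ], 100)
        planes[[p]][, xs] <- pmax(planes[[p]][, xs], 100)
      }
    }
    if (draw_labels) {
      wc <- well_centers(layout)
      for (i in seq_len(nrow(wc))) {
        r0 <- round((wc$row[[i]] - 1L) * cell_px) + 3L
        c0 <- round((wc$col[[i]] - 1L) * cell_px) + 3L
        for (p in names(planes))
          planes[[p]] <- stamp_text(planes[[p]], wc$well[[i]], r0, c0, 255)
      }
    }
  }
  rgb <- array(0, dim = c(NY, NX, 3))
  rgb[, , 1] <- planes$red
  rgb[, , 2] <- planes$green
  rgb[, , 3] <- planes$blue
  if (!is.null(path)) write_png(rgb, path, bit_depth = 8)
  invisible(list(rgb = rgb, legend = legend))
}

#' Export an ion image as 16-bit grayscale PNG
#'
#' Intensities are scaled linearly so the image maximum maps to 65535.
#' @param image `IonImage`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ion_image_png <- function(image, path) {
  v <- image$values
  mx <- max(v)
  m <- if (mx > 0) v / mx * 65535 else v * 0
  write_png(m, path, bit_depth = 16)
}

# row-major well ordering key (A1, A2, ..., B1, ...) for deterministic ties
well_order_key <- function(labels) {
  letters_part <- sub("[0-9]+$", "", labels)
  num_part <- as.integer(sub("^[A-Za-z]+", "", labels))
  order(nchar(letters_part), letters_part, num_part)
}

#' Call and rank hits from well quantifications
#'
#' `"threshold"` mode keeps wells whose corrected sum exceeds
#' `mean(blanks) + 3 * sd(blanks)` over the declared blank wells and that are
#' not flagged as isotope false positives. `"top_k"` keeps the `k` highest.
#' Ranking is by corrected sum, descending; ties break by well label in
#' row-major plate order. Blank wells themselves are never called.
#'
#' @param quants `WellQuant`.
#' @param channel Channel label to rank on.
#' @param mode `"threshold"` or `"top_k"`.
#' @param param For `"top_k"`: k. Ignored in threshold mode.
#' @param blank_wells Character vector of declared blank/control wells
#'   (required in threshold mode; blanks are declared, not inferred).
#' @return A `HitTable` data.frame: `rank`, `well`, `channel`, `corrected`,
#'   `conversion`, `empty`, `isotope_false_positive`.
#' @export
call_hits <- function(quants, channel, mode = c("threshold", "top_k"),
                      param = NULL, blank_wells = NULL) {
  stopifnot(inherits(quants, "WellQuant"))
  mode <- match.arg(mode)
  q <- quants[quants$channel == channel, , drop = FALSE]
  if (nrow(q) == 0L) stop("channel not quantified: ", channel)
  if (mode == "threshold") {
    blanks <- q[q$well %in% blank_wells, , drop = FALSE]
    if (is.null(blank_wells) || nrow(blanks) == 0L)
      stop("threshold mode needs declared blank wells; use top_k instead")
    thr <- mean(blanks$corrected) +
      3 * (if (nrow(blanks) > 1L) stats::sd(blanks$corrected) else 0)
    q <- q[!q$well %in% blank_wells & q$corrected > thr &
             !q$isotope_false_positive, , drop = FALSE]
  } else {
    if (is.null(param) || param < 1) stop("top_k mode needs param = k >= 1")
    q <- q[!q$well %in% blank_wells, , drop = FALSE]
  }
  # convert the row-major permutation into a sortable key for tie-breaking
  key <- integer(nrow(q))
  key[well_order_key(q$well)] <- seq_len(nrow(q))
  ord <- order(-q$corrected, key)
  q <- q[ord, , drop = FALSE]
  if (mode == "top_k") q <- utils::head(q, as.integer(param))
  out <- data.frame(rank = seq_len(nrow(q)), well = q$well,
                    channel = q$channel, corrected = q$corrected,
                    conversion = q$conversion, empty = q$empty,
                    isotope_false_positive = q$isotope_false_positive,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("HitTable", "data.frame")
  out
}

#' Raster throughput per sample
#'
#' Time to image one grid cell:
#' `lines_per_cell = ceiling(cell_size / pixel_size)` raster lines, each
#' taking `cell_size / stage_speed` plus a per-line overhead (turnaround,
#' inter-line moves). With 5 mm cells, 500 um pixels and 2000 um/s this gives
#' 25 s/sample at zero overhead; a ~1.9 s/line overhead brings it to the
#' ~44 s/sample regime typical of optimized acquisitions. The overhead is an
#' explicit parameter and is never defaulted silently.
#'
#' @param cell_size Cell edge, mm.
#' @param pixel_size Pixel edge, um.
#' @param stage_speed Stage speed, um/s.
#' @param per_line_overhead Seconds per raster line.
#' @return Seconds per sample.
#' @export
estimate_throughput <- function(cell_size = 5, pixel_size = 500,
                                stage_speed = 2000, per_line_overhead = 0) {
  if (cell_size <= 0 || pixel_size <= 0 || stage_speed <= 0 ||
      per_line_overhead < 0)
    stop("parameters must be positive (overhead non-negative)")
  cell_um <- cell_size * 1000
  lines <- ceiling(cell_um / pixel_size)
  lines * (cell_um / stage_speed + per_line_overhead)
}

#' Load the packaged PAL variant conversion panel
#'
#' A small packaged table of HPLC-measured conversion percentages for two
#' phenylalanine ammonia lyase enzymes across 21 methoxy/alkyl-substituted
#' cinnamic acid substrates, useful for demonstrating [call_hits()] on real
#' printed numbers. Censored entries ("<1") are parsed as 0.5 with
#' `censored = TRUE`.
#'
#' @return data.frame: `substrate`, `ar_substituents`, `pbpal_pct`,
#'   `al11_pct`, `pbpal_censored`, `al11_censored`.
#' @export
load_pal_panel <- function() {
  path <- system.file("extdata", "pal_panel_conversions_hplc.csv",
                      package = "desiscreen", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  parse_pct <- function(x) {
    out <- rep(0.5, length(x))
    plain <- x != "<1"
    out[plain] <- as.numeric(x[plain])
    out
  }
  data.frame(substrate = tab$substrate,
             ar_substituents = tab$ar_substituents,
             pbpal_pct = parse_pct(tab$pbpal_conversion_pct),
             al11_pct = parse_pct(tab$al11_conversion_pct),
             pbpal_censored = tab$pbpal_conversion_pct == "<1",
             al11_censored = tab$al11_conversion_pct == "<1",
             stringsAsFactors = FALSE)
}

#' Bundle a screening report into a directory
#'
#' Writes the heat map (PNG), the well quantification table (CSV), the hit
#' table (CSV + JSON) and the run configuration (JSON) into `dir`.
#'
#' @param dir Output directory (created if needed).
#' @param images Ion image(s) for the heat map.
#' @param layout `PlateLayout`.
#' @param quants `WellQuant`.
#' @param hits `HitTable`.
#' @param config Named list recorded as `config.json`.
#' @return Invisibly, `dir`.
#' @export
write_report <- function(dir, images, layout, quants, hits,
                         config = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  render_heatmap(images, layout, path = file.path(dir, "heatmap.png"))
  write_quants_csv(quants, file.path(dir, "well_quants.csv"))
  utils::write.csv(as.data.frame(hits), file.path(dir, "hits.csv"),
                   row.names = FALSE)
  jsonlite::write_json(as.data.frame(hits), file.path(dir, "hits.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
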