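# Grid geometry of spotted membranes and assignment of wells to m/z channels.
#
# Coordinate convention: millimetres, origin at the membrane top-left,
# x to the right, y down. Pixel indices are 0-based row-major; a pixel belongs
# to the cell containing its center (half-open cell intervals).

row_letters <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  extra <- as.vector(outer(LETTERS, LETTERS, function(a, b) paste0(a, b)))
  c(LETTERS, extra)[seq_len(n)]
}

#' Build a plate/grid layout
#'
#' Describes the square-cell grid scored onto the membrane. Wells are labelled
#' A1-style, row-major (A1 is top-left). Well centers sit at
#' `origin + (col - 0.5, row - 0.5) * cell_size`.
#'
#' @param n_rows,n_cols Grid dimensions (e.g. 8 x 12 for a 96-well format).
#' @param cell_size Cell edge in mm (default 5, i.e. a 25 mm^2 area per
#'   sample).
#' @param origin Length-2 mm offset of the top-left cell corner.
#' @return A `PlateLayout`.
#' @examples
#' build_layout(8, 12)           # 96-well
#' build_layout(16, 24)          # 384-well
#' @export
build_layout <- function(n_rows, n_cols, cell_size = 5, origin = c(0, 0)) {
  if (!is.numeric(n_rows) || !is.numeric(n_cols) || n_rows < 1 || n_cols < 1)
    stop("n_rows and n_cols must be positive")
  if (!is.numeric(cell_size) || cell_size <= 0)
    stop("cell_size must be positive")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  format_tag <- if (n_rows == 8L && n_cols == 12L) "96"
                else if (n_rows == 16L && n_cols == 24L) "384"
                else "custom"
  structure(list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
                 origin = as.numeric(origin), format_tag = format_tag),
            class = "PlateLayout")
}

#' @export
print.PlateLayout <- function(x, ...) {
  cat(sprintf("<PlateLayout> %d x %d (%s-format), %.3g mm cells, origin (%g, %g) mm\n",
              x$n_rows, x$n_cols, x$format_tag, x$cell_size,
              x$origin[[1]], x$origin[[2]]))
  invisible(x)
}

#' Well labels and center coordinates of a layout
#'
#' @param layout `PlateLayout`.
#' @return data.frame with columns `well`, `row`, `col` (1-based) and
#'   `x`, `y` (mm center coordinates), in row-major order.
#' @export
well_centers <- function(layout) {
  stopifnot(inherits(layout, "PlateLayout"))
  rows <- rep(seq_len(layout$n_rows), each = layout$n_cols)
  cols <- rep(seq_len(layout$n_cols), times = layout$n_rows)
  data.frame(
    well = paste0(row_letters(layout$n_rows)[rows], cols),
    row = rows, col = cols,
    x = layout$origin[[1]] + (cols - 0.5) * layout$cell_size,
    y = layout$origin[[2]] + (rows - 0.5) * layout$cell_size,
    stringsAsFactors = FALSE
  )
}

#' All well labels of a layout (row-major)
#' @param layout `PlateLayout`.
#' @return Character vector.
#' @export
well_labels <- function(layout) well_centers(layout)$well

#' Detection channel specification
#'
#' A narrow m/z window in which centroid intensities are summed to form an
#' ion image.
#'
#' @param label Channel name.
#' @param target_mz Window center (Da).
#' @param window Full window width in Da (default 0.2).
#' @param polarity +1 or -1.
#' @param display_color One of `"red"`, `"green"`, `"blue"`, `"gray"`.
#' @param species_role `"substrate"`, `"product"` or `"other"`.
#' @return A `ChannelSpec`.
#' @export
channel_spec <- function(label, target_mz, window = 0.2, polarity = 1L,
                         display_color = c("gray", "red", "green", "blue"),
                         species_role = c("other", "substrate", "product")) {
  if (!is.numeric(target_mz) || target_mz <= 0) stop("target_mz must be > 0")
  if (!is.numeric(window) || window <= 0) stop("window must be > 0")
  structure(list(label = label, target_mz = target_mz, window = window,
                 polarity = as.integer(polarity),
                 display_color = match.arg(display_color),
                 species_role = match.arg(species_role)),
            class = "ChannelSpec")
}

#' @export
print.ChannelSpec <- function(x, ...) {
  cat(sprintf("<ChannelSpec> %s: m/z %.4f +/- %.3g (%s, %s)\n", x$label,
              x$target_mz, x$window / 2, x$species_role, x$display_color))
  invisible(x)
}

#' Species table: which molecular species sits in which well
#'
#' @param well Character vector of well labels.
#' @param role `"substrate"`, `"product"` or `"other"` per row.
#' @param formula Molecular formula string per row.
#' @param adduct Adduct kind per row (`"M+H"` / `"M-H"`).
#' @param drift_ms Optional expected drift time (ms); NA when unknown.
#' @param layout Optional `PlateLayout` to validate well labels against.
#' @return A `SpeciesTable` data.frame.
#' @export
species_table <- function(well, role, formula, adduct = "M+H",
                          drift_ms = NA_real_, layout = NULL) {
  tab <- data.frame(well = as.character(well), role = as.character(role),
                    formula = as.character(formula),
                    adduct = as.character(adduct),
                    drift_ms = as.numeric(drift_ms),
                    stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("species table is empty")
  ok <- tab$role %in% c("substrate", "product", "other")
  if (any(!ok)) stop("invalid species role: ", tab$role[!ok][[1]])
  if (!is.null(layout)) {
    missing <- setdiff(tab$well, well_labels(layout))
    if (length(missing))
      stop("wells not present in layout: ", paste(missing, collapse = ", "))
  }
  class(tab) <- c("SpeciesTable", "data.frame")
  tab
}

#' Read / write a species table as CSV
#'
#' CSV columns: `well,role,formula,adduct,drift_ms`.
#' @param path File path.
#' @param layout Optional layout for validation.
#' @return A `SpeciesTable`.
#' @export
read_species_csv <- function(path, layout = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "role", "formula", "adduct")
  if (!all(need %in% names(tab)))
    stop("species CSV must have columns: ", paste(need, collapse = ", "))
  if (!"drift_ms" %in% names(tab)) tab$drift_ms <- NA_real_
  species_table(tab$well, tab$role, tab$formula, tab$adduct, tab$drift_ms,
                layout = layout)
}

#' @rdname read_species_csv
#' @param species `SpeciesTable` to write.
#' @export
write_species_csv <- function(species, path) {
  utils::write.csv(as.data.frame(species), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write / read a plate layout as JSON
#' @param layout `PlateLayout`.
#' @param path File path.
#' @export
write_layout_json <- function(layout, path) {
  jsonlite::write_json(unclass(layout), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout_json
#' @export
read_layout_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_layout(x$n_rows, x$n_cols, x$cell_size, x$origin)
}

#' Assign wells to m/z detection channels
#'
#' Computes each species' m/z and greedily merges species whose m/z fall
#' within one `window` of each other (ascending m/z) onto shared channels.
#' Isomeric substrates/products therefore multiplex onto a single channel: a
#' kinase screen of 11 enzymes x 8 isomeric substrates yields one product
#' channel covering all 88 wells. Potential isotope interference between
#' channels (an envelope peak of one channel's species falling inside another
#' channel's window) is reported in `$overlaps`.
#'
#' @param species `SpeciesTable`.
#' @param window Channel window width in Da (default 0.2).
#' @return A `ChannelAssignment`: list with `channels` (data.frame: label,
#'   target_mz, window, polarity, display_color, species_role), `wells`
#'   (named list channel label -> well labels), and `overlaps` (data.frame of
#'   predicted isotope interference fractions between channels).
#' @export
assign_channels <- function(species, window = 0.2) {
  if (!inherits(species, "SpeciesTable")) stop("species must be a SpeciesTable")
  if (nrow(species) == 0L) stop("species table is empty")
  sp <- as.data.frame(species)
  sp$mz <- mapply(function(f, a) monoisotopic_mz(f, a),
                  sp$formula, sp$adduct)
  sp$polarity <- vapply(sp$adduct, function(a) adduct_spec(a)$polarity,
                        integer(1))
  # order-invariant: sort by m/z then well then role
  sp <- sp[order(sp$mz, sp$well, sp$role), , drop = FALSE]
  grp <- integer(nrow(sp))
  g <- 0L; anchor <- -Inf
  for (i in seq_len(nrow(sp))) {
    if (sp$mz[[i]] - anchor > window) {
      g <- g + 1L
      anchor <- sp$mz[[i]]
    }
    grp[[i]] <- g
  }
  palette <- c(substrate = "red", product = "green", other = "blue")
  channels <- do.call(rbind, lapply(split(sp, grp), function(d) {
    role <- names(sort(table(d$role), decreasing = TRUE))[[1]]
    data.frame(label = sprintf("mz%.1f_%s", mean(d$mz), role),
               target_mz = mean(d$mz), window = window,
               polarity = d$polarity[[1]], display_color = palette[[role]],
               species_role = role, n_wells = length(unique(d$well)),
               stringsAsFactors = FALSE)
  }))
  rownames(channels) <- NULL
  wells <- lapply(split(sp, grp), function(d) sort(unique(d$well)))
  names(wells) <- channels$label
  # predicted isotope interference between distinct channels
  overlaps <- list()
  key <- unique(sp[c("formula", "adduct")])
  envs <- lapply(seq_len(nrow(key)), function(i)
    isotope_envelope(key$formula[[i]], key$adduct[[i]]))
  names(envs) <- paste(key$formula, key$adduct)
  for (i in seq_len(nrow(sp))) {
    env <- envs[[paste(sp$formula[[i]], sp$adduct[[i]])]]
    for (j in seq_len(nrow(channels))) {
      if (grp[[i]] == j) next
      f <- interference_fraction(env, channels$target_mz[[j]], window)
      if (f > 0)
        overlaps[[length(overlaps) + 1L]] <- data.frame(
          formula = sp$formula[[i]], from = channels$label[[grp[[i]]]],
          onto = channels$label[[j]], fraction = f,
          stringsAsFactors = FALSE)
    }
  }
  overlaps <- if (length(overlaps)) unique(do.call(rbind, overlaps))
              else data.frame(formula = character(), from = character(),
                              onto = character(), fraction = numeric())
  rownames(overlaps) <- NULL
  structure(list(channels = channels, wells = wells, overlaps = overlaps),
            class = "ChannelAssignment")
}

#' @export
print.ChannelAssignment <- function(x, ...) {
  cat("<ChannelAssignment> ", nrow(x$channels), " channel(s)\n", sep = "")
  print(x$channels)
  if (nrow(x$overlaps)) {
    cat("isotope overlaps:\n")
    print(x$overlaps)
  }
  invisible(x)
}

#' Build a ChannelSpec from one row of a ChannelAssignment
#' @param assignment `ChannelAssignment`.
#' @param label Channel label (or index).
#' @return `ChannelSpec`.
#' @export
get_channel <- function(assignment, label) {
  ch <- assignment$channels
  i <- if (is.numeric(label)) label else match(label, ch$label)
  if (is.na(i)) stop("no such channel: ", label)
  channel_spec(ch$label[[i]], ch$target_mz[[i]], ch$window[[i]],
               ch$polarity[[i]], ch$display_color[[i]], ch$species_role[[i]])
}
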