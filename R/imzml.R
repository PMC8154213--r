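# imzML 1.1 reader/writer (XML metadata + external .ibd binary).
#
# Drift-time dialect: imzML has no standard ion-mobility axis, so a dataset
# with drift bins is written as one spectrum per (pixel, drift bin), each scan
# tagged with userParams `drift_bin` (1-based index) and `drift_time_ms`
# (bin center). The full bin-center vector is repeated in scanSettings as
# userParam `drift_bin_centers_ms` (comma-separated). Standard viewers see a
# plain multi-spectrum-per-coordinate file.
#
# Integrity: an MD5 checksum of the .ibd file is stored in fileContent
# (cv accession IMS:1000090) and verified on read; the 16-byte ibd UUID is
# derived deterministically from the MD5 of the binary payload so identical
# datasets produce byte-identical files.

ibd_serialize <- function(sp) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(as.numeric(sp$mz), con, size = 8L, endian = "little")
  writeBin(as.numeric(sp$intensity), con, size = 4L, endian = "little")
  rawConnectionValue(con)
}

md5_of_raw <- function(bytes) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(bytes, tmp)
  unname(tools::md5sum(tmp))
}

uuid_format <- function(bytes16) {
  h <- paste(sprintf("%02x", as.integer(bytes16)), collapse = "")
  paste(substring(h, c(1, 9, 13, 17, 21), c(8, 12, 16, 20, 32)),
        collapse = "-")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write an imaging dataset as imzML
#'
#' Writes an `.imzML`/`.ibd` pair in processed mode (per-spectrum m/z axes):
#' 64-bit float m/z, 32-bit float intensities, little-endian, no compression.
#' `mode = "continuous"` additionally marks spectra as profile data (used to
#' exercise profile-to-centroid conversion on read) and requires every
#' spectrum to share one m/z axis, which is stored once.
#'
#' @param ds `ImagingDataset`.
#' @param path Output path; a trailing `.imzML` is optional. The `.ibd` is
#'   written alongside.
#' @param mode `"processed"` (default) or `"continuous"`.
#' @return Invisibly, the `.imzML` path.
#' @export
write_imzml <- function(ds, path, mode = c("processed", "continuous")) {
  stopifnot(inherits(ds, "ImagingDataset"))
  mode <- match.arg(mode)
  validate_dataset(ds)
  stem <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  xml_path <- paste0(stem, ".imzML")
  ibd_path <- paste0(stem, ".ibd")

  # flatten to (pixel, bin) spectrum records in row-major pixel order
  recs <- list()
  for (iy in seq_len(ds$ny) - 1L) for (ix in seq_len(ds$nx) - 1L) {
    i <- iy * ds$nx + ix + 1L
    if (has_drift(ds)) {
      for (k in seq_along(ds$drift_centers)) {
        recs[[length(recs) + 1L]] <- list(ix = ix, iy = iy, bin = k,
                                          sp = ds$spectra[[i]][[k]])
      }
    } else {
      recs[[length(recs) + 1L]] <- list(ix = ix, iy = iy, bin = NA_integer_,
                                        sp = ds$spectra[[i]])
    }
  }

  if (mode == "continuous") {
    axes <- lapply(recs, function(r) r$sp$mz)
    if (!all(vapply(axes, identical, logical(1), y = axes[[1]])))
      stop("continuous mode requires all spectra to share one m/z axis")
  }

  # binary payload + offsets (offsets are relative to ibd start, i.e. after
  # the 16-byte UUID which is prepended below)
  chunks <- vector("list", length(recs))
  offset <- 16L
  shared_mz <- NULL
  for (j in seq_along(recs)) {
    sp <- recs[[j]]$sp
    n <- length(sp$mz)
    if (mode == "continuous" && j > 1L) {
      mz_off <- shared_mz$offset; mz_len <- shared_mz$len
      con <- rawConnection(raw(0), "wb")
      writeBin(as.numeric(sp$intensity), con, size = 4L, endian = "little")
      bytes <- rawConnectionValue(con); close(con)
      int_off <- offset
      chunks[[j]] <- bytes
      recs[[j]]$arr <- list(n = n, mz_offset = mz_off, mz_bytes = mz_len,
                            int_offset = int_off, int_bytes = 4L * n)
      offset <- offset + length(bytes)
    } else {
      bytes <- ibd_serialize(sp)
      mz_off <- offset; int_off <- offset + 8L * n
      chunks[[j]] <- bytes
      recs[[j]]$arr <- list(n = n, mz_offset = mz_off, mz_bytes = 8L * n,
                            int_offset = int_off, int_bytes = 4L * n)
      offset <- offset + length(bytes)
      if (j == 1L) shared_mz <- list(offset = mz_off, len = 8L * n)
    }
  }
  payload <- do.call(c, c(chunks, list(raw(0))))
  uuid_bytes <- md5_of_raw(payload)
  uuid_raw <- as.raw(strtoi(substring(uuid_bytes,
                                      seq(1, 31, 2), seq(2, 32, 2)), 16L))
  writeBin(c(uuid_raw, payload), ibd_path)
  md5 <- unname(tools::md5sum(ibd_path))

  pol_cv <- if (ds$polarity >= 0)
    '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan"/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000129" name="negative scan"/>'
  spec_type_cv <- if (mode == "continuous")
    '<cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum"/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/>'
  bin_mode_cv <- if (mode == "continuous")
    '<cvParam cvRef="IMS" accession="IMS:1000030" name="continuous"/>'
  else
    '<cvParam cvRef="IMS" accession="IMS:1000031" name="processed"/>'

  spectra_xml <- vapply(seq_along(recs), function(j) {
    r <- recs[[j]]; a <- r$arr
    drift_xml <- if (!is.na(r$bin)) sprintf(
      '<userParam name="drift_bin" value="%d"/><userParam name="drift_time_ms" value="%.10g"/>',
      r$bin, ds$drift_centers[[r$bin]]) else ""
    sprintf(paste0(
      '<spectrum id="spectrum=%d" index="%d" defaultArrayLength="%d">',
      spec_type_cv, pol_cv,
      '<scanList count="1"><scan>',
      '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>',
      '%s</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0"><referenceableParamGroupRef ref="mzArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>',
      '<binary/></binaryDataArray>',
      '<binaryDataArray encodedLength="0"><referenceableParamGroupRef ref="intensityArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>',
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'),
      j, j - 1L, a$n, r$ix + 1L, r$iy + 1L, drift_xml,
      a$n, a$mz_offset, a$mz_bytes, a$n, a$int_offset, a$int_bytes)
  }, character(1))

  drift_meta <- if (has_drift(ds)) sprintf(
    '<userParam name="drift_bin_centers_ms" value="%s"/>',
    paste(sprintf("%.10g", ds$drift_centers), collapse = ",")) else ""

  header <- sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>',
    '</cvList>\n',
    '<fileDescription><fileContent>',
    spec_type_cv, bin_mode_cv,
    '<cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000090" name="ibd MD5" value="%s"/>',
    '</fileContent></fileDescription>\n',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
    '<cvParam cvRef="MS" accession="MS:1000521" name="32-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>\n',
    '<softwareList count="1"><software id="desiscreen" version="0.1.0"/></softwareList>\n',
    '<scanSettingsList count="1"><scanSettings id="scanSettings1">',
    '<cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size (x)" value="%.10g" unitCvRef="UO" unitAccession="UO:0000017" unitName="micrometer"/>',
    '<userParam name="polarity" value="%d"/>%s',
    '</scanSettings></scanSettingsList>\n',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"/></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="dp1">',
    '<processingMethod order="1" softwareRef="desiscreen"/>',
    '</dataProcessing></dataProcessingList>\n',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
    '<spectrumList count="%d" defaultDataProcessingRef="dp1">\n'),
    uuid_format(uuid_raw), md5, ds$nx, ds$ny, ds$pixel_size, ds$polarity,
    drift_meta, length(recs))

  con <- file(xml_path, "wb")
  writeLines(c(header, spectra_xml,
               "</spectrumList>\n</run>\n</mzML>"), con, sep = "\n")
  close(con)
  invisible(xml_path)
}

cv_value <- function(params, accession) {
  v <- params$value[params$accession == accession]
  if (length(v)) v[[1]] else NA_character_
}

# local-maximum centroid picking for profile spectra; plateaus keep the
# left-most point
pick_centroids <- function(mz, int) {
  n <- length(int)
  if (n == 0L) return(empty_spectrum())
  if (n == 1L) {
    keep <- int > 0
    return(list(mz = mz[keep], intensity = int[keep]))
  }
  left <- c(Inf, int[-n])    # strictly greater than left neighbour
  right <- c(int[-1], -Inf)  # at least the right neighbour
  is_max <- int > 0 & int > left & int >= right
  is_max[1] <- int[1] > 0 & int[1] >= int[2]
  list(mz = mz[is_max], intensity = int[is_max])
}

#' Read an imzML imaging dataset
#'
#' Reads processed- or continuous-mode imzML written by [write_imzml()] (and
#' minimal standard-compliant files using the same conventions). Profile
#' spectra are converted to centroid lists by local-maximum picking. The ibd
#' MD5 checksum, when present, is verified. Coordinates are mapped to a
#' 0-based row-major grid; coordinates missing from the file are filled with
#' empty spectra (one warning reporting the gap count).
#'
#' @param path Path to the `.imzML` file (or stem).
#' @return An `ImagingDataset`.
#' @export
read_imzml <- function(path) {
  stem <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  xml_path <- if (file.exists(path) && !dir.exists(path)) path
              else paste0(stem, ".imzML")
  ibd_path <- paste0(stem, ".ibd")
  if (!file.exists(xml_path)) stop("no such imzML file: ", xml_path)
  if (!file.exists(ibd_path)) stop("missing ibd file: ", ibd_path)

  doc <- xml2::read_xml(xml_path)
  xml2::xml_ns_strip(doc)

  fc <- xml2::xml_find_all(doc, "//fileDescription/fileContent/cvParam")
  fc_acc <- xml2::xml_attr(fc, "accession")
  fc_val <- xml2::xml_attr(fc, "value")
  md5_stated <- fc_val[fc_acc == "IMS:1000090"]
  if (length(md5_stated)) {
    md5_actual <- unname(tools::md5sum(ibd_path))
    if (!identical(tolower(md5_stated[[1]]), tolower(md5_actual)))
      stop("ibd MD5 checksum mismatch: file may be corrupt")
  }
  profile_default <- "MS:1000128" %in% fc_acc

  # referenceable param groups: id -> (which array, encoding)
  groups <- list()
  for (g in xml2::xml_find_all(doc, "//referenceableParamGroup")) {
    acc <- xml2::xml_attr(xml2::xml_find_all(g, "./cvParam"), "accession")
    groups[[xml2::xml_attr(g, "id")]] <- list(
      kind = if ("MS:1000514" %in% acc) "mz"
             else if ("MS:1000515" %in% acc) "intensity" else NA,
      size = if ("MS:1000523" %in% acc) 8L
             else if ("MS:1000521" %in% acc) 4L else 8L)
  }

  ss <- xml2::xml_find_all(doc, "//scanSettings/cvParam")
  ss_acc <- xml2::xml_attr(ss, "accession")
  ss_val <- xml2::xml_attr(ss, "value")
  nx_stated <- suppressWarnings(as.integer(cv_value(
    data.frame(accession = ss_acc, value = ss_val,
               stringsAsFactors = FALSE), "IMS:1000042")))
  ny_stated <- suppressWarnings(as.integer(cv_value(
    data.frame(accession = ss_acc, value = ss_val,
               stringsAsFactors = FALSE), "IMS:1000043")))
  px <- suppressWarnings(as.numeric(cv_value(
    data.frame(accession = ss_acc, value = ss_val,
               stringsAsFactors = FALSE), "IMS:1000046")))
  if (is.na(px)) px <- 500
  up <- xml2::xml_find_all(doc, "//scanSettings/userParam")
  up_names <- xml2::xml_attr(up, "name")
  up_vals <- xml2::xml_attr(up, "value")
  polarity_meta <- if ("polarity" %in% up_names)
    as.integer(up_vals[up_names == "polarity"][[1]]) else NA_integer_
  drift_centers <- if ("drift_bin_centers_ms" %in% up_names)
    as.numeric(strsplit(up_vals[up_names == "drift_bin_centers_ms"][[1]],
                        ",")[[1]]) else NULL

  ibd_size <- file.size(ibd_path)
  ibd <- file(ibd_path, "rb")
  on.exit(close(ibd))

  nodes <- xml2::xml_find_all(doc, "//spectrumList/spectrum")
  n_spec <- length(nodes)
  recs <- vector("list", n_spec)
  polarity <- polarity_meta
  for (j in seq_len(n_spec)) {
    node <- nodes[[j]]
    cvs <- xml2::xml_find_all(node, ".//cvParam")
    acc <- xml2::xml_attr(cvs, "accession")
    val <- xml2::xml_attr(cvs, "value")
    if (is.na(polarity)) {
      if ("MS:1000130" %in% acc) polarity <- 1L
      if ("MS:1000129" %in% acc) polarity <- -1L
    }
    profile <- if ("MS:1000128" %in% acc) TRUE
               else if ("MS:1000127" %in% acc) FALSE else profile_default
    pos_x <- as.integer(val[acc == "IMS:1000050"][[1]])
    pos_y <- as.integer(val[acc == "IMS:1000051"][[1]])
    ups <- xml2::xml_find_all(node, ".//scan/userParam")
    un <- xml2::xml_attr(ups, "name"); uv <- xml2::xml_attr(ups, "value")
    bin <- if ("drift_bin" %in% un) as.integer(uv[un == "drift_bin"][[1]])
           else NA_integer_
    drift_ms <- if ("drift_time_ms" %in% un)
      as.numeric(uv[un == "drift_time_ms"][[1]]) else NA_real_

    arrays <- list()
    for (bda in xml2::xml_find_all(node, ".//binaryDataArray")) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(bda, "./referenceableParamGroupRef"), "ref")
      bacc <- xml2::xml_attr(xml2::xml_find_all(bda, "./cvParam"), "accession")
      bval <- xml2::xml_attr(xml2::xml_find_all(bda, "./cvParam"), "value")
      kind <- NA; size <- NA
      if (!is.na(ref) && !is.null(groups[[ref]])) {
        kind <- groups[[ref]]$kind; size <- groups[[ref]]$size
      }
      if (is.na(kind))
        kind <- if ("MS:1000514" %in% bacc) "mz"
                else if ("MS:1000515" %in% bacc) "intensity" else NA
      if (is.na(size))
        size <- if ("MS:1000523" %in% bacc) 8L
                else if ("MS:1000521" %in% bacc) 4L else 8L
      len <- as.numeric(bval[bacc == "IMS:1000103"][[1]])
      off <- as.numeric(bval[bacc == "IMS:1000102"][[1]])
      enc <- as.numeric(bval[bacc == "IMS:1000104"][[1]])
      if (is.na(kind))
        stop("spectrum ", j, ": binary array of unknown type")
      if (off + enc > ibd_size || enc != len * size)
        stop("spectrum ", j, ": binary length mismatch in ibd")
      arrays[[kind]] <- list(offset = off, n = len, size = size)
    }
    if (is.null(arrays$mz) || is.null(arrays$intensity))
      stop("spectrum ", j, ": missing m/z or intensity array")
    read_arr <- function(a) {
      seek(ibd, where = a$offset, origin = "start")
      readBin(ibd, what = "double", n = a$n, size = a$size,
              endian = "little")
    }
    mz <- read_arr(arrays$mz)
    int <- read_arr(arrays$intensity)
    sp <- if (profile) pick_centroids(mz, int)
          else list(mz = mz, intensity = int)
    recs[[j]] <- list(ix = pos_x - 1L, iy = pos_y - 1L, bin = bin,
                      drift_ms = drift_ms, sp = sp)
  }
  if (n_spec == 0L) stop("imzML contains no spectra")
  if (is.na(polarity)) polarity <- 1L

  nx <- max(vapply(recs, `[[`, integer(1), "ix")) + 1L
  ny <- max(vapply(recs, `[[`, integer(1), "iy")) + 1L
  if (!is.na(nx_stated)) nx <- max(nx, nx_stated)
  if (!is.na(ny_stated)) ny <- max(ny, ny_stated)

  bins <- vapply(recs, `[[`, integer(1), "bin")
  with_drift <- any(!is.na(bins))
  if (with_drift && is.null(drift_centers)) {
    bd <- unique(data.frame(bin = bins,
                            ms = vapply(recs, `[[`, numeric(1), "drift_ms")))
    bd <- bd[order(bd$bin), ]
    drift_centers <- bd$ms
  }
  n_bins <- if (with_drift) length(drift_centers) else 1L

  spectra <- vector("list", nx * ny)
  filled <- matrix(FALSE, nrow = n_bins, ncol = nx * ny)
  if (with_drift) {
    for (i in seq_len(nx * ny))
      spectra[[i]] <- replicate(n_bins, empty_spectrum(), simplify = FALSE)
  } else {
    for (i in seq_len(nx * ny)) spectra[[i]] <- empty_spectrum()
  }
  for (r in recs) {
    i <- r$iy * nx + r$ix + 1L
    if (with_drift) {
      spectra[[i]][[r$bin]] <- r$sp
      filled[r$bin, i] <- TRUE
    } else {
      spectra[[i]] <- r$sp
      filled[1L, i] <- TRUE
    }
  }
  n_gaps <- sum(!filled)
  if (n_gaps > 0L)
    warning(n_gaps, " missing pixel spectra filled as empty")

  imaging_dataset(spectra, nx, ny, pixel_size = px, polarity = polarity,
                  drift_centers = drift_centers,
                  metadata = list(source = xml_path))
}
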