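## Readers/writers and coordinate conventions.
##
## Convention used throughout the package: pixel coordinates are 0-based,
## x = column, y = row, with the centre of the top-left pixel at (0, 0).
## Internally images are stored as H x W (rows x cols) arrays indexed
## [y + 1, x + 1].

NUCLEUS_TABLE_COLS <- c(
  "tile_id", "core_id", "case_id", "nucleus_id",
  "centroid_x_px", "centroid_y_px",
  "area_um2", "length_um", "width_um", "ratio", "qc_flag",
  "mean_dab_od", "dab_pos_px", "granule_count", "node_count", "ng_label"
)

QC_LEVELS <- c("OK", "OVERLAP", "BLUR", "WEAK", "EDGE")
NG_LEVELS <- c("NEGATIVE", "NG1", "NG2", "NG3_4", "MITOSIS")

#' Construct a calibrated RGB tile
#'
#' @param pixels H x W x 3 array of integer intensities in \[0, 255\].
#' @param pixel_size isotropic pixel size in micrometres per pixel.
#' @param tile_id,core_id identifiers carried through the pipeline.
#' @return an object of class `rgb_tile`.
#' @export
rgb_tile <- function(pixels, pixel_size, tile_id = "tile", core_id = NA_character_) {
  if (length(dim(pixels)) == 2L) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("pixel_size must be a positive scalar (um/px)")
  }
  if (any(pixels < 0) || any(pixels > 255)) {
    stop("tile intensities must lie in [0, 255]")
  }
  structure(
    list(pixels = round(pixels), pixel_size = pixel_size,
         tile_id = tile_id, core_id = core_id),
    class = "rgb_tile"
  )
}

#' @export
print.rgb_tile <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_tile '%s'> %d x %d px @ %.4g um/px\n",
              x$tile_id, d[1], d[2], x$pixel_size))
  invisible(x)
}

#' @export
dim.rgb_tile <- function(x) dim(x$pixels)

#' Read an image tile from PNG or TIFF
#'
#' Reads an 8-bit raster and attaches the pixel calibration. Grayscale
#' rasters are promoted to three identical channels; an alpha channel, if
#' present, is dropped.
#'
#' @param path file path (`.png`, `.tif`, `.tiff`).
#' @param pixel_size micrometres per pixel (must be supplied: brightfield
#'   rasters rarely embed a trustworthy calibration).
#' @param tile_id,core_id identifiers; `tile_id` defaults to the file stem.
#' @return an [rgb_tile()].
#' @export
read_tile <- function(path, pixel_size, tile_id = NULL, core_id = NA_character_) {
  if (!file.exists(path)) stop("cannot read tile: file not found: ", path)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("pixel_size must be a positive scalar (um/px)")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported tile format: .", ext, " (use PNG or TIFF)")
  )
  if (length(dim(raw)) == 3L && dim(raw)[3] >= 3L) {
    raw <- raw[, , 1:3, drop = FALSE]
  } else {
    if (length(dim(raw)) == 3L) raw <- raw[, , 1]
    raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  }
  if (is.null(tile_id)) tile_id <- tools::file_path_sans_ext(basename(path))
  rgb_tile(round(raw * 255), pixel_size, tile_id = tile_id, core_id = core_id)
}

#' Write an image tile to PNG or TIFF
#'
#' Lossless 8-bit output; `write_tile()` followed by [read_tile()] is
#' pixel-identical.
#'
#' @param tile an [rgb_tile()].
#' @param path output path; the extension selects the format.
#' @export
write_tile <- function(tile, path) {
  stopifnot(inherits(tile, "rgb_tile"))
  img <- tile$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(img, path),
    tif  = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L, compression = "none"),
    stop("unsupported tile format: .", ext)
  )
  invisible(path)
}

#' Validate a per-nucleus results table
#'
#' Checks the fixed column set and the row-level invariants (unique
#' `nucleus_id` within a tile, `ratio` in (0, 1\], non-negative pixel
#' counts, known QC flags and NG labels).
#'
#' @param table data.frame with the nucleus-table columns.
#' @return the table, invisibly, with columns in canonical order.
#' @export
validate_nucleus_table <- function(table) {
  missing <- setdiff(NUCLEUS_TABLE_COLS, names(table))
  if (length(missing)) stop("nucleus table missing columns: ",
                            paste(missing, collapse = ", "))
  table <- table[, NUCLEUS_TABLE_COLS, drop = FALSE]
  if (nrow(table)) {
    key <- paste(table$tile_id, table$nucleus_id)
    if (anyDuplicated(key)) stop("duplicate nucleus_id within tile")
    ok <- is.na(table$ratio) | (table$ratio > 0 & table$ratio <= 1)
    if (!all(ok)) stop("ratio must lie in (0, 1]")
    if (any(table$dab_pos_px < 0, na.rm = TRUE)) stop("dab_pos_px must be >= 0")
    if (!all(table$qc_flag %in% QC_LEVELS)) stop("unknown qc_flag value")
    if (!all(is.na(table$ng_label) | table$ng_label %in% NG_LEVELS)) {
      stop("unknown ng_label value")
    }
  }
  invisible(table)
}

#' Write / read the per-nucleus table as CSV
#'
#' Comma-separated, UTF-8, `.` decimal, fixed documented header. Reals are
#' written with full precision; integer columns round-trip bit-exactly.
#'
#' @param table a valid nucleus table (see [validate_nucleus_table()]).
#' @param path CSV path.
#' @export
write_nucleus_table <- function(table, path) {
  table <- validate_nucleus_table(table)
  write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_nucleus_table
#' @export
read_nucleus_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                  colClasses = c(tile_id = "character", core_id = "character",
                                 case_id = "character"))
  validate_nucleus_table(tab)
  tab
}

#' Read a TMA core map
#'
#' CSV with columns `core_id, case_id, grid_row, grid_col`; every core must
#' be unique and map to exactly one case.
#'
#' @param path CSV path.
#' @return data.frame of core-to-case assignments.
#' @export
read_tma_map <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("core_id", "case_id", "grid_row", "grid_col")
  missing <- setdiff(need, names(m))
  if (length(missing)) stop("TMA map missing columns: ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(m$core_id)) stop("TMA map: core_id must be unique")
  m
}

#' Export nucleus boundary polygons as GeoJSON
#'
#' Writes a FeatureCollection with one polygon feature per nucleus, in
#' pixel coordinates (0-based, x = column). Each feature carries the
#' nucleus id, NG label and QC flag as properties, for import into
#' interactive slide viewers.
#'
#' @param nuclei list of nucleus objects as returned by [segment_nuclei()]
#'   (each with `polygon`, an n x 2 matrix; the ring is closed on output).
#' @param path output `.geojson` path.
#' @export
export_polygons <- function(nuclei, path) {
  features <- lapply(nuclei, function(nuc) {
    poly <- nuc$polygon
    if (is.null(poly) || nrow(poly) < 3L) {
      stop("nucleus ", nuc$nucleus_id, ": boundary polygon missing or degenerate")
    }
    if (!all(poly[1, ] == poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
    if (polygon_self_intersects(poly)) {
      stop("nucleus ", nuc$nucleus_id, ": self-intersecting boundary polygon")
    }
    list(
      type = "Feature",
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(poly)),
                                  function(i) unname(poly[i, ])))
      ),
      properties = list(
        nucleus_id = nuc$nucleus_id,
        ng_label = if (is.null(nuc$ng_label)) NA else nuc$ng_label,
        qc_flag = if (is.null(nuc$qc_flag)) NA else nuc$qc_flag
      )
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

## O(n^2) proper-crossing test on the closed ring; shared edges/vertices of
## adjacent segments are skipped.
polygon_self_intersects <- function(ring) {
  n <- nrow(ring) - 1L
  if (n < 4L) return(FALSE)
  seg <- function(i) rbind(ring[i, ], ring[i + 1L, ])
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (segments_cross(seg(i), seg(j))) return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(s1, s2) {
  d <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  d1 <- d(s2[1, ], s2[2, ], s1[1, ]); d2 <- d(s2[1, ], s2[2, ], s1[2, ])
  d3 <- d(s1[1, ], s1[2, ], s2[1, ]); d4 <- d(s1[1, ], s1[2, ], s2[2, ])
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

#' Assemble a per-nucleus results table from scored nuclei
#'
#' @param nuclei list of nucleus objects after QC and NG scoring.
#' @param tile the source [rgb_tile()].
#' @param case_id case identifier for the tile's core.
#' @return a validated nucleus table (data.frame).
#' @export
nuclei_to_table <- function(nuclei, tile, case_id = NA_character_) {
  if (!length(nuclei)) {
    tab <- as.data.frame(setNames(
      rep(list(character(0)), length(NUCLEUS_TABLE_COLS)), NUCLEUS_TABLE_COLS))
    return(tab)
  }
  rows <- lapply(nuclei, function(nuc) {
    m <- nuc$morphometry
    f <- nuc$features
    data.frame(
      tile_id = tile$tile_id, core_id = tile$core_id, case_id = case_id,
      nucleus_id = nuc$nucleus_id,
      centroid_x_px = nuc$centroid[1], centroid_y_px = nuc$centroid[2],
      area_um2 = if (is.null(m)) NA_real_ else m$area,
      length_um = if (is.null(m)) NA_real_ else m$length,
      width_um = if (is.null(m)) NA_real_ else m$width,
      ratio = if (is.null(m)) NA_real_ else m$ratio,
      qc_flag = nuc$qc_flag,
      mean_dab_od = if (is.null(f)) NA_real_ else f$mean_dab_od,
      dab_pos_px = if (is.null(f)) NA_integer_ else f$dab_pos_px,
      granule_count = if (is.null(f)) NA_integer_ else f$granule_count,
      node_count = if (is.null(f)) NA_integer_ else f$node_count,
      ng_label = if (is.null(nuc$ng_label)) NA_character_ else nuc$ng_label,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  validate_nucleus_table(tab)
  tab
}
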