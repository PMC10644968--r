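## Tissue detection, tumour gating, nucleus segmentation on the
## hematoxylin channel, and per-nucleus / per-core quality control.
##
## Matrices are indexed [row = y, col = x]; EBImage sees the transposed
## interpretation but all operations used here are orientation-agnostic.

#' Detect tissue on a tile
#'
#' Background (glass) pixels are those whose total optical density falls
#' below `stains$background_od_cutoff`; the background mask is smoothed by
#' morphological closing and tissue is its complement.
#'
#' @param tile an [rgb_tile()].
#' @param config pipeline configuration, see [ki67_config()].
#' @return list with logical matrix `mask` (TRUE = tissue) and scalar
#'   `tissue_fraction`.
#' @export
detect_tissue <- function(tile, config = ki67_config()) {
  od <- rgb_to_od(tile)$values
  tot <- od[, , 1] + od[, , 2] + od[, , 3]
  bg <- tot < config$stains$background_od_cutoff
  brush <- EBImage::makeBrush(5L, shape = "disc")
  bg <- EBImage::closing(bg * 1, brush) > 0.5
  tissue <- !bg
  list(mask = tissue, tissue_fraction = mean(tissue))
}

#' Gate the tumour region of a core
#'
#' Density-based heuristic standing in for the expert-assisted
#' tumour/non-tumour separation: pixels where the locally smoothed density
#' of nuclear (hematoxylin-high) signal and the mean hematoxylin OD both
#' exceed configurable cutoffs are called tumour. A user-supplied mask
#' (expert annotation) overrides the heuristic and is returned verbatim
#' with provenance `"user"`.
#'
#' @param tile an [rgb_tile()].
#' @param tissue_mask logical matrix from [detect_tissue()].
#' @param user_mask optional logical matrix of the same size; overrides.
#' @param config pipeline configuration.
#' @param model stain model used to extract the hematoxylin channel.
#' @return list with `mask`, `tumor_fraction` (of tile area) and
#'   `provenance` (`"heuristic"` or `"user"`).
#' @export
segment_tumor_region <- function(tile, tissue_mask, user_mask = NULL,
                                 config = ki67_config(), model = stain_model()) {
  if (!is.null(user_mask)) {
    stopifnot(all(dim(user_mask) == dim(tissue_mask)))
    return(list(mask = user_mask, tumor_fraction = mean(user_mask),
                provenance = "user"))
  }
  ps <- tile$pixel_size
  hema <- deconvolve(rgb_to_od(tile), model)$hema
  sm <- as.matrix(EBImage::gblur(hema, sigma = max(1, config$seg$sigma_um / ps)))
  nuc <- (sm > config$seg$min_thr) & tissue_mask
  sig <- min(config$tumor$density_sigma_um / ps, floor(min(dim(tissue_mask)) / 9))
  dens <- as.matrix(EBImage::gblur(nuc * 1, sigma = max(1, sig)))
  ## density cutoff is relative to the tile's peak density, so the gate is
  ## insensitive to overall cellularity
  cut <- config$tumor$min_density * max(dens)
  mask <- dens > cut & sm > config$tumor$min_hema_od & tissue_mask
  if (max(dens) == 0) mask[] <- FALSE
  list(mask = mask, tumor_fraction = mean(mask), provenance = "heuristic")
}

#' Segment nuclei on the hematoxylin channel
#'
#' Gaussian smoothing (sigma in um) -> global threshold (Otsu computed over
#' the region of interest, floored at `seg$min_thr` OD) -> hole filling ->
#' watershed split on the distance transform -> size filter. Objects
#' touching the tile border are flagged `EDGE` immediately (the flag is
#' re-derived identically by [qc_nucleus()]).
#'
#' @param hema_map H x W hematoxylin concentration matrix from
#'   [deconvolve()].
#' @param pixel_size um per pixel.
#' @param config pipeline configuration.
#' @param region optional logical matrix restricting segmentation (e.g. the
#'   tumour mask); also the support on which the Otsu threshold is fitted.
#' @return list of `nucleus` objects: each has `nucleus_id`, `idx` (linear
#'   pixel indices), `dim`, `centroid` (0-based, x = column), `bbox`
#'   (0-based x0,y0,x1,y1), `polygon` (boundary ring, 0-based px), and a
#'   provisional `qc_flag` of `EDGE` or `NA`.
#' @export
segment_nuclei <- function(hema_map, pixel_size, config = ki67_config(),
                           region = NULL) {
  ps <- pixel_size
  H <- nrow(hema_map); W <- ncol(hema_map)
  sm <- as.matrix(EBImage::gblur(hema_map, sigma = max(0.5, config$seg$sigma_um / ps)))
  roi <- if (is.null(region)) rep(TRUE, length(sm)) else as.vector(region)
  vals <- sm[roi]
  thr <- config$seg$min_thr
  if (length(vals) && max(vals) > 0) {
    vmax <- max(vals)
    ot <- EBImage::otsu(EBImage::Image(vals / vmax, dim = c(length(vals), 1L)),
                        range = c(0, 1), levels = 256L) * vmax
    ## with a dominant background class Otsu sits above the half-height
    ## boundary and undersizes nuclei; iterate to the midpoint of the class
    ## means (Ridler-Calvard), which recovers the half-height edge
    for (i in 1:20) {
      mid <- (mean(vals[vals <= ot]) + mean(vals[vals > ot])) / 2
      if (!is.finite(mid) || abs(mid - ot) < 1e-4) break
      ot <- mid
    }
    thr <- max(ot, config$seg$min_thr)
  }
  bin <- sm > thr
  if (!is.null(region)) bin <- bin & region
  if (!any(bin)) return(list())
  bin <- EBImage::fillHull(bin * 1) > 0.5
  dm <- EBImage::distmap(bin)
  lab <- EBImage::watershed(dm, tolerance = config$seg$ws_tolerance, ext = 1L)
  lab <- as.matrix(EBImage::imageData(lab))
  make_nuclei_from_labels(lab, ps, config)
}

## Shared label-matrix -> nucleus-object builder (also used on ground-truth
## label images). Applies the area filter and the EDGE pre-flag.
make_nuclei_from_labels <- function(lab, pixel_size, config = ki67_config(),
                                    filter_area = TRUE) {
  H <- nrow(lab); W <- ncol(lab)
  n <- max(lab)
  if (n == 0L) return(list())
  idx_by_lab <- split(seq_along(lab), factor(lab, levels = 1:n))
  min_px <- config$seg$min_area_um2 / pixel_size^2
  max_px <- config$seg$max_area_um2 / pixel_size^2
  out <- list()
  k <- 0L
  for (i in seq_len(n)) {
    idx <- idx_by_lab[[i]]
    npx <- length(idx)
    if (npx == 0L) next
    if (filter_area && (npx < min_px || npx > max_px)) next
    rows <- ((idx - 1L) %% H) + 1L
    cols <- ((idx - 1L) %/% H) + 1L
    k <- k + 1L
    sub <- matrix(FALSE, max(rows) - min(rows) + 1L, max(cols) - min(cols) + 1L)
    sub[cbind(rows - min(rows) + 1L, cols - min(cols) + 1L)] <- TRUE
    poly <- mask_contour(sub, offset = c(min(cols) - 1L, min(rows) - 1L))
    edge <- min(rows) == 1L || min(cols) == 1L || max(rows) == H || max(cols) == W
    out[[k]] <- structure(list(
      nucleus_id = k,
      idx = idx, dim = c(H, W),
      centroid = c(mean(cols) - 1, mean(rows) - 1),
      bbox = c(min(cols) - 1L, min(rows) - 1L, max(cols) - 1L, max(rows) - 1L),
      polygon = poly,
      qc_flag = if (edge) "EDGE" else NA_character_,
      morphometry = NULL, features = NULL, ng_label = NULL
    ), class = "nucleus")
  }
  out
}

## Boundary ring of a connected submask, as 0-based (x, y) pixel coords.
mask_contour <- function(sub, offset = c(0, 0)) {
  oc <- tryCatch(EBImage::ocontour(EBImage::Image(sub * 1)),
                 error = function(e) NULL)
  if (is.null(oc) || !length(oc)) {
    ## degenerate 1-px-wide object: fall back to its pixel list
    w <- which(sub, arr.ind = TRUE)
    return(cbind(x = w[, 2] - 1 + offset[1], y = w[, 1] - 1 + offset[2]))
  }
  cc <- oc[[1]]
  ## matrix fed as [y, x]: EBImage's first index runs over our rows
  cbind(x = cc[, 2] + offset[1], y = cc[, 1] + offset[2])
}

## Per-nucleus logical submask + bbox row/col ranges, from linear indices.
nucleus_submask <- function(nucleus) {
  H <- nucleus$dim[1]
  rows <- ((nucleus$idx - 1L) %% H) + 1L
  cols <- ((nucleus$idx - 1L) %/% H) + 1L
  rr <- range(rows); cr <- range(cols)
  sub <- matrix(FALSE, rr[2] - rr[1] + 1L, cr[2] - cr[1] + 1L)
  sub[cbind(rows - rr[1] + 1L, cols - cr[1] + 1L)] <- TRUE
  list(sub = sub, rows = rr[1]:rr[2], cols = cr[1]:cr[2])
}

#' Per-nucleus quality control
#'
#' Checks run in a fixed order and the first failure wins:
#' `EDGE` (border contact) -> `OVERLAP` (solidity below `qc$min_solidity`)
#' -> `BLUR` (variance of the Laplacian of the grayscale bounding-box patch
#' below `qc$min_focus`) -> `WEAK` (mean DAB OD inside the mask below
#' `qc$weak_od`) -> `OK`.
#'
#' @param nucleus a nucleus object from [segment_nuclei()].
#' @param tile the source [rgb_tile()] (for the focus metric).
#' @param dab_map DAB concentration matrix from [deconvolve()].
#' @param config pipeline configuration.
#' @return the nucleus with `qc_flag` set.
#' @export
qc_nucleus <- function(nucleus, tile, dab_map, config = ki67_config()) {
  sm <- nucleus_submask(nucleus)
  H <- nucleus$dim[1]; W <- nucleus$dim[2]
  flag <- NA_character_
  if (min(sm$rows) == 1L || min(sm$cols) == 1L ||
      max(sm$rows) == H || max(sm$cols) == W) {
    flag <- "EDGE"
  } else if (mask_solidity(sm$sub) < config$qc$min_solidity) {
    flag <- "OVERLAP"
  } else {
    gray <- (tile$pixels[sm$rows, sm$cols, 1] +
             tile$pixels[sm$rows, sm$cols, 2] +
             tile$pixels[sm$rows, sm$cols, 3]) / (3 * 255)
    if (laplacian_variance(gray) < config$qc$min_focus) {
      flag <- "BLUR"
    } else if (mean(dab_map[nucleus$idx]) < config$qc$weak_od) {
      flag <- "WEAK"
    } else {
      flag <- "OK"
    }
  }
  nucleus$qc_flag <- flag
  nucleus
}

## Solidity = mask pixel count / pixel count of the convex hull. The hull
## pixel count is estimated from the hull polygon through pixel centres as
## shoelace area + perimeter/2 + 1 (Pick-style lattice-point count).
mask_solidity <- function(sub) {
  w <- which(sub, arr.ind = TRUE)
  if (nrow(w) < 3L) return(1)
  pts <- cbind(w[, 2], w[, 1])                     # (x, y)
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  if (nrow(hull) < 3L) return(1)
  x <- hull[, 1]; y <- hull[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  area <- abs(sum(x * yn - xn * y)) / 2
  perim <- sum(sqrt((xn - x)^2 + (yn - y)^2))
  min(1, sum(sub) / (area + perim / 2 + 1))
}

#' Variance of the Laplacian focus metric
#'
#' 4-neighbour Laplacian on a grayscale patch in \[0, 1\]; low variance
#' indicates a blurred (out-of-focus) patch.
#'
#' @param gray numeric matrix in \[0, 1\].
#' @return scalar focus score, >= 0.
#' @export
laplacian_variance <- function(gray) {
  H <- nrow(gray); W <- ncol(gray)
  if (H < 3L || W < 3L) return(0)
  core <- gray[2:(H - 1), 2:(W - 1)]
  lap <- gray[1:(H - 2), 2:(W - 1)] + gray[3:H, 2:(W - 1)] +
    gray[2:(H - 1), 1:(W - 2)] + gray[2:(H - 1), 3:W] - 4 * core
  var(as.vector(lap))
}

#' Core-level quality control
#'
#' A core is valid iff its tumour fraction is at least
#' `qc$min_tumor_fraction` (boundary inclusive: exactly 10% tumour is
#' valid) and the fraction of its nuclei flagged `BLUR` does not exceed
#' `qc$max_blur_fraction` (an artifact proxy).
#'
#' @param nuclei list of QC'd nucleus objects for the core.
#' @param tumor_fraction scalar in \[0, 1\].
#' @param core_id,case_id identifiers.
#' @param config pipeline configuration.
#' @return one-row data.frame: `core_id, case_id, tumor_fraction, valid,
#'   n_nuclei, invalid_reason`.
#' @export
qc_core <- function(nuclei, tumor_fraction, core_id = NA_character_,
                    case_id = NA_character_, config = ki67_config()) {
  flags <- vapply(nuclei, function(nuc) nuc$qc_flag, character(1))
  blur_frac <- if (length(flags)) mean(flags == "BLUR") else 0
  reason <- "none"
  if (tumor_fraction < config$qc$min_tumor_fraction) {
    reason <- "low_tumor"
  } else if (blur_frac > config$qc$max_blur_fraction) {
    reason <- "artifact"
  }
  data.frame(
    core_id = core_id, case_id = case_id,
    tumor_fraction = tumor_fraction,
    valid = reason == "none",
    n_nuclei = length(nuclei),
    invalid_reason = reason,
    stringsAsFactors = FALSE
  )
}
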