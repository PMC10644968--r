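## Beer-Lambert absorbance transform and H-DAB colour deconvolution.
##
## Stains absorb light approximately linearly in optical-density (OD)
## space: od = -log10(I / I0). A pixel's OD vector is modelled as a
## non-negative combination of per-stain unit absorbance vectors, so
## unmixing is a 3x3 linear solve per pixel.

#' Convert an RGB tile to optical density (absorbance)
#'
#' Per channel, `OD = -log10(max(I, 1) / I0)`. Saturated (zero-intensity)
#' pixels are clamped at intensity 1 so the OD stays finite; a blank white
#' pixel maps to zero OD in every channel.
#'
#' @param tile an [rgb_tile()].
#' @param I0 incident (background) intensity, 255 for 8-bit input.
#' @return object of class `od_image`: list with `values` (H x W x 3
#'   non-negative array) and `tile_id`.
#' @export
rgb_to_od <- function(tile, I0 = 255) {
  stopifnot(inherits(tile, "rgb_tile"), I0 > 0)
  od <- -log10(pmax(tile$pixels, 1) / I0)
  od[od < 0] <- 0
  structure(list(values = od, tile_id = tile$tile_id), class = "od_image")
}

#' Render an optical-density image back to 8-bit RGB
#'
#' Inverse of [rgb_to_od()]: `I = I0 * 10^(-OD)` rounded to integers.
#' Used by the synthetic generator so that the analysis inverts exactly the
#' model that produced the image.
#'
#' @param od H x W x 3 OD array (or `od_image`).
#' @inheritParams rgb_to_od
#' @return H x W x 3 integer intensity array.
#' @export
od_to_rgb <- function(od, I0 = 255) {
  if (inherits(od, "od_image")) od <- od$values
  pmin(pmax(round(I0 * 10^(-od)), 0), 255)
}

#' Construct a stain model
#'
#' @param matrix 3x3 matrix, rows = (hematoxylin, DAB, residual) OD unit
#'   vectors. Rows are re-normalised to unit Euclidean norm.
#' @param provenance `"default"` or `"estimated"`.
#' @return object of class `stain_model`.
#' @export
stain_model <- function(matrix = default_stain_matrix(), provenance = "default") {
  stopifnot(is.matrix(matrix), all(dim(matrix) == c(3L, 3L)))
  nrm <- sqrt(rowSums(matrix^2))
  if (any(nrm < 1e-12)) stop("stain model: zero-norm stain vector")
  m <- matrix / nrm
  ## non-degenerate basis: pairwise angles above 1 degree
  ang <- function(a, b) acos(pmin(1, abs(sum(a * b)))) * 180 / pi
  angs <- c(ang(m[1, ], m[2, ]), ang(m[1, ], m[3, ]), ang(m[2, ], m[3, ]))
  if (any(angs <= 1)) stop("stain model: degenerate basis (pairwise angle <= 1 degree)")
  rownames(m) <- c("hema", "dab", "residual")
  structure(list(matrix = m, provenance = provenance), class = "stain_model")
}

#' Deconvolve an OD image into stain concentration maps
#'
#' Solves `od = t(M) %*% c` per pixel where the rows of `M` are the stain
#' OD vectors, then clips negative concentrations to zero. The unclipped
#' solution reconstructs the OD exactly (to numerical precision).
#'
#' @param od an `od_image` from [rgb_to_od()] or an H x W x 3 array.
#' @param model a [stain_model()].
#' @param clip clip negative concentrations to zero (default TRUE).
#' @return list with H x W matrices `hema`, `dab`, `residual`.
#' @export
deconvolve <- function(od, model = stain_model(), clip = TRUE) {
  if (inherits(od, "od_image")) od <- od$values
  stopifnot(inherits(model, "stain_model"), length(dim(od)) == 3L)
  d <- dim(od)
  flat <- matrix(od, ncol = 3L)              # pixels x channels
  conc <- flat %*% solve(model$matrix)       # solve c M = od  =>  c = od M^-1
  if (clip) conc[conc < 0] <- 0
  list(
    hema = matrix(conc[, 1], d[1], d[2]),
    dab = matrix(conc[, 2], d[1], d[2]),
    residual = matrix(conc[, 3], d[1], d[2])
  )
}

#' Compose concentration maps into an OD image
#'
#' Linear forward model `od = c_h v_h + c_d v_d + c_r v_r`; the inverse of
#' [deconvolve()] (pre-clipping).
#'
#' @param hema,dab,residual H x W concentration matrices (`residual` may be
#'   omitted).
#' @param model a [stain_model()].
#' @return H x W x 3 OD array.
#' @export
compose_od <- function(hema, dab, residual = NULL, model = stain_model()) {
  d <- dim(hema)
  if (is.null(residual)) residual <- matrix(0, d[1], d[2])
  conc <- cbind(as.vector(hema), as.vector(dab), as.vector(residual))
  od <- conc %*% model$matrix
  array(od, dim = c(d, 3L))
}

#' Estimate H-DAB stain vectors from a tile
#'
#' Selects confidently stained pixels (total OD above a cutoff), projects
#' their OD vectors onto the plane spanned by the two principal absorbance
#' directions, and takes the extreme-angle directions in that plane as the
#' two stain vectors (Macenko-style extreme-angle selection). The vector
#' whose red-channel OD share is larger is assigned to hematoxylin (blue
#' stains absorb red light); the other to DAB. The residual is the
#' normalised cross product. Falls back to the default H-DAB matrix when
#' too few stained pixels are available or the estimate is degenerate.
#'
#' @param tile an [rgb_tile()].
#' @param min_od total-OD cutoff for pixel selection.
#' @param min_pixels minimum number of stained pixels required.
#' @param alpha robust percentile for the extreme angles.
#' @return a [stain_model()] with provenance `"estimated"` (or `"default"`
#'   on fallback; partial fallback for a single estimated stain is
#'   `"estimated"` with a `fallback` attribute naming the defaulted stain).
#' @export
estimate_stain_vectors <- function(tile, min_od = 0.15, min_pixels = 200,
                                   alpha = 1) {
  od <- rgb_to_od(tile)$values
  flat <- matrix(od, ncol = 3L)
  tot <- rowSums(flat)
  sel <- flat[tot > min_od, , drop = FALSE]
  if (nrow(sel) < min_pixels) {
    return(stain_model(default_stain_matrix(), provenance = "default"))
  }
  eig <- eigen(crossprod(sel), symmetric = TRUE)
  basis <- eig$vectors[, 1:2]                       # dominant OD plane
  proj <- sel %*% basis
  phi <- atan2(proj[, 2], proj[, 1])
  lo <- quantile(phi, alpha / 100)
  hi <- quantile(phi, 1 - alpha / 100)
  v1 <- basis %*% c(cos(lo), sin(lo))
  v2 <- basis %*% c(cos(hi), sin(hi))
  fix <- function(v) {
    v <- as.vector(v); if (sum(v) < 0) v <- -v
    v[v < 0] <- 0
    n <- sqrt(sum(v^2)); if (n < 1e-9) return(NULL)
    v / n
  }
  v1 <- fix(v1); v2 <- fix(v2)
  def <- default_stain_matrix()
  if (is.null(v1) && is.null(v2)) {
    return(stain_model(def, provenance = "default"))
  }
  ## angular spread too small => effectively a single stain present:
  ## keep the estimated direction for the stain it resembles, default the other
  single <- !is.null(v1) && !is.null(v2) &&
    acos(pmin(1, sum(v1 * v2))) * 180 / pi < 8
  red_share <- function(v) v[1] / sum(v)
  fallback <- NULL
  if (single || is.null(v1) || is.null(v2)) {
    v <- if (is.null(v1)) v2 else v1
    if (abs(red_share(v) - red_share(def["hema", ])) <
        abs(red_share(v) - red_share(def["dab", ]))) {
      v_h <- v; v_d <- def["dab", ]; fallback <- "dab"
    } else {
      v_d <- v; v_h <- def["hema", ]; fallback <- "hema"
    }
  } else if (red_share(v1) > red_share(v2)) {
    v_h <- v1; v_d <- v2
  } else {
    v_h <- v2; v_d <- v1
  }
  v_r <- pracma_cross(v_h, v_d)
  n <- sqrt(sum(v_r^2))
  if (n < 1e-9) return(stain_model(def, provenance = "default"))
  m <- rbind(v_h, v_d, v_r / n)
  out <- tryCatch(stain_model(m, provenance = "estimated"),
                  error = function(e) stain_model(def, provenance = "default"))
  if (!is.null(fallback) && out$provenance == "estimated") {
    attr(out, "fallback") <- fallback
  }
  out
}

#' Threshold a DAB concentration map into a positivity mask
#'
#' A pixel is DAB-positive iff its DAB concentration strictly exceeds the
#' absorbance threshold `theta` (a pixel exactly at the threshold is
#' negative, so counts are bit-reproducible).
#'
#' @param dab_map H x W DAB concentration matrix.
#' @param theta absorbance threshold (OD units), >= 0.
#' @return object of class `positivity_mask`: list with logical `mask`,
#'   `theta`, and `positive_pixel_count`.
#' @export
absorbance_threshold <- function(dab_map, theta) {
  stopifnot(is.numeric(theta), length(theta) == 1L, theta >= 0)
  mask <- dab_map > theta
  structure(
    list(mask = mask, theta = theta, positive_pixel_count = sum(mask)),
    class = "positivity_mask"
  )
}
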