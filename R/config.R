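#' Default pipeline configuration
#'
#' Returns the full nested configuration used by every stage of the
#' pipeline. All spatial parameters are denominated in micrometres so that
#' results are independent of scan resolution; the pixel calibration
#' (`pixel_size`, um/px) converts them to pixels at run time.
#'
#' Sections:
#' \describe{
#'   \item{stains}{`theta` — DAB absorbance threshold in OD units (a pixel is
#'     DAB-positive iff its DAB concentration strictly exceeds `theta`);
#'     `default_matrix` — 3x3 H-DAB stain matrix (rows: hematoxylin, DAB,
#'     residual unit OD vectors); `estimate` — estimate stain vectors from the
#'     tile instead of using the default matrix; `background_od_cutoff` —
#'     total-OD level below which a pixel counts as glass/background.}
#'   \item{seg}{`sigma_um` — Gaussian smoothing applied to the hematoxylin
#'     map before thresholding; `min_thr` — floor on the Otsu threshold (OD);
#'     `min_area_um2`/`max_area_um2` — admissible nucleus area;
#'     `ws_tolerance` — watershed merge tolerance (px of distance map).}
#'   \item{qc}{`min_solidity` — below this a nucleus is flagged OVERLAP;
#'     `min_focus` — minimum variance of the Laplacian of the grayscale
#'     patch, below which a nucleus is flagged BLUR; `weak_od` — mean DAB OD
#'     below which a nucleus is weakly/not stained; `max_blur_fraction` —
#'     core-level artifact gate; `min_tumor_fraction` — cores with less
#'     tumour than this are invalid.}
#'   \item{tumor}{density gate for the tumour-region heuristic:
#'     `density_sigma_um` (smoothing scale of the nucleus-density field),
#'     `min_density` (relative density cutoff), `min_hema_od`.}
#'   \item{ng}{feature-extraction scales — `granule_um`/`node_um` are the
#'     admissible blob equivalent-diameter bands (um) for granules and
#'     perinucleolar nodes; `rim_um` — width of the membrane band;
#'     `center_frac` — central-disc radius as a fraction of the equivalent
#'     radius — and classification cutpoints `fill_high`, `void_min`,
#'     `mitosis_rim_min`, `mitosis_area_z`, `granule_min`, `rim_min`.}
#'   \item{sample}{`n` — number of positive nuclei sampled per run (the
#'     protocol samples 1000); `seed`.}
#' }
#'
#' @param overrides optional named list (possibly nested) merged over the
#'   defaults, or a path to a YAML file with the same structure.
#' @return nested list of configuration values.
#' @export
#' @examples
#' cfg <- ki67_config()
#' cfg$stains$theta
#' cfg2 <- ki67_config(list(stains = list(theta = 0.2)))
ki67_config <- function(overrides = NULL) {
  cfg <- list(
    pixel_size = 0.25,
    stains = list(
      theta = 0.15,
      default_matrix = default_stain_matrix(),
      estimate = FALSE,
      background_od_cutoff = 0.10
    ),
    seg = list(
      sigma_um = 0.4,
      min_thr = 0.15,
      min_area_um2 = 5,
      max_area_um2 = 400,
      ws_tolerance = 1.5
    ),
    qc = list(
      min_solidity = 0.85,
      min_focus = 0.005,
      weak_od = 0.10,
      max_blur_fraction = 0.5,
      min_tumor_fraction = 0.10
    ),
    tumor = list(
      density_sigma_um = 12,
      min_density = 0.15,
      min_hema_od = 0.05
    ),
    ng = list(
      granule_um = c(0.3, 1.2),
      node_um = c(1.5, 4.0),
      rim_um = 0.5,
      center_frac = 0.4,
      fill_high = 0.7,
      void_min = 0.6,
      mitosis_rim_min = 0.4,
      mitosis_area_z = -1.0,
      granule_min = 3,
      rim_min = 0.3
    ),
    sample = list(n = 1000, seed = 42L)
  )
  if (!is.null(overrides)) {
    if (is.character(overrides) && length(overrides) == 1L) {
      overrides <- yaml::read_yaml(overrides)
    }
    cfg <- modify_list_deep(cfg, overrides)
  }
  cfg
}

## recursive version of modifyList that keeps unnamed leaves intact
modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(new[[nm]]))) {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

#' Standard H-DAB stain matrix
#'
#' The published hematoxylin/DAB absorbance unit vectors widely used for
#' brightfield colour deconvolution, with the residual vector completed as
#' the normalised cross product. Rows are stains (hematoxylin, DAB,
#' residual), columns are the R, G, B optical-density components.
#'
#' @return 3x3 numeric matrix with unit-norm rows.
#' @export
default_stain_matrix <- function() {
  v_h <- c(0.650, 0.704, 0.286)
  v_d <- c(0.268, 0.570, 0.776)
  v_h <- v_h / sqrt(sum(v_h^2))
  v_d <- v_d / sqrt(sum(v_d^2))
  v_r <- pracma_cross(v_h, v_d)
  v_r <- v_r / sqrt(sum(v_r^2))
  m <- rbind(hema = v_h, dab = v_d, residual = v_r)
  colnames(m) <- c("R", "G", "B")
  m
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
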