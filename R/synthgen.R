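## Ground-truth synthesis: H-DAB tiles with planted nuclei realising the
## four positive nuclear-gradient staining patterns, and a survival-cohort
## simulator for the statistics layer.
##
## Textures are painted in stain-concentration space and rendered to RGB
## through the same Beer-Lambert model the analysis inverts, so stain-model
## error is isolated to the estimation tests rather than the classifier
## tests.

#' Specification for a synthetic H-DAB tile
#'
#' Defaults define the package's reference test conditions: a 1024 px
#' square tile at 0.25 um/px holding 420 non-overlapping nuclei (200
#' negative, 60 NG1, 60 NG2, 60 NG3/4, 40 mitoses) with lognormal areas
#' around 30 um^2 and mild sensor noise.
#'
#' Per-class DAB patterns: NG1 paints fine granules (diameter
#' `granule_d_um`) scattered through the nucleoplasm, scaling in number
#' with nuclear area; NG2 paints 1-2 perinucleolar nodes (`node_d_um`);
#' NG3/4 paints a homogeneous intense fill over a 1.3x enlarged nucleus;
#' MITOSIS paints a near-continuous peripheral ring of granules around an
#' empty centre (prometaphase-like ring figure; set
#' `mitosis_style = "bar"` for a condensed chromosome-mass variant).
#'
#' @param tile_px tile side length in pixels.
#' @param pixel_size um per pixel.
#' @param counts named integer vector over
#'   `NEGATIVE, NG1, NG2, NG3_4, MITOSIS`.
#' @param area_mean_um2,area_cv lognormal nucleus-area distribution.
#' @param ratio_range range of the width/length axis ratio.
#' @param hema_od hematoxylin concentration inside nuclei (OD units).
#' @param granule_d_um,node_d_um,granule_od,node_od,fill_od pattern
#'   parameters (diameters in um, concentrations in OD).
#' @param noise_sd Gaussian sensor noise (8-bit intensity units).
#' @param blur_sigma_px optional Gaussian blur of the rendered image
#'   (degradation knob; 0 = crisp).
#' @param mitosis_style `"ring"` or `"bar"`.
#' @param theta_ref DAB threshold at which planted positive-pixel counts
#'   are recorded in the ground truth.
#' @param seed integer; fixes the tile bit-exactly.
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(tile_px = 1024L, pixel_size = 0.25,
                       counts = c(NEGATIVE = 200L, NG1 = 60L, NG2 = 60L,
                                  NG3_4 = 60L, MITOSIS = 40L),
                       area_mean_um2 = 30, area_cv = 0.25,
                       ratio_range = c(0.60, 0.90),
                       hema_od = 0.60,
                       granule_d_um = 0.9, node_d_um = 2.5,
                       granule_od = 1.0, node_od = 0.9, fill_od = 0.75,
                       noise_sd = 2, blur_sigma_px = 0,
                       mitosis_style = "ring",
                       theta_ref = 0.15, seed = 1L) {
  cls <- c("NEGATIVE", "NG1", "NG2", "NG3_4", "MITOSIS")
  full <- setNames(rep(0L, 5L), cls)
  full[names(counts)] <- as.integer(counts)
  stopifnot(all(full >= 0L), area_mean_um2 > 0, area_cv >= 0,
            tile_px >= 64L, pixel_size > 0)
  structure(list(
    tile_px = as.integer(tile_px), pixel_size = pixel_size, counts = full,
    area_mean_um2 = area_mean_um2, area_cv = area_cv,
    ratio_range = ratio_range, hema_od = hema_od,
    granule_d_um = granule_d_um, node_d_um = node_d_um,
    granule_od = granule_od, node_od = node_od, fill_od = fill_od,
    noise_sd = noise_sd, blur_sigma_px = blur_sigma_px,
    mitosis_style = mitosis_style, theta_ref = theta_ref,
    seed = as.integer(seed)
  ), class = "synth_spec")
}

#' Tumour-type presets for the synthetic generator
#'
#' Encapsulate the three study conditions the generator emulates, with the
#' published cohort morphometry and proliferation index as calibration:
#' pulmonary typical carcinoid (`PTC`: mean nuclear area 24.38 um^2, PI
#' 0.40%, positive compartment dominated by NG1), pulmonary adenocarcinoma
#' (`PAD`: 49.66 um^2, PI 4.31%, NG3/4-dominant) and breast ductal
#' carcinoma (`BDC`: 33.36 um^2, PI 3.42%, NG2/NG3_4-leaning). Positive
#' nuclei per tile are `round(n * PI/100)` (at least 1), apportioned across
#' the positive classes by largest remainder.
#'
#' @param tumor_type one of `"PTC"`, `"PAD"`, `"BDC"`.
#' @param n_nuclei total nuclei per tile.
#' @param tile_px,seed passed through to [synth_spec()].
#' @return a `synth_spec`; attributes `pi_percent`, `mix` and `tumor_type`
#'   record the preset calibration.
#' @export
synth_preset <- function(tumor_type, n_nuclei = NULL, tile_px = 1024L, seed = 1L) {
  par <- switch(tumor_type,
    PTC = list(area = 24.38, cv = 8.35 / 24.38, ratio = c(0.59, 0.89),
               pi = 0.40, mix = c(NG1 = 0.88, NG2 = 0.06, NG3_4 = 0.04,
                                  MITOSIS = 0.02), n = 350L),
    PAD = list(area = 49.66, cv = 3.40 / 49.66, ratio = c(0.50, 0.66),
               pi = 4.31, mix = c(NG1 = 0.25, NG2 = 0.15, NG3_4 = 0.55,
                                  MITOSIS = 0.05), n = 160L),
    BDC = list(area = 33.36, cv = 8.41 / 33.36, ratio = c(0.42, 0.46),
               pi = 3.42, mix = c(NG1 = 0.25, NG2 = 0.25, NG3_4 = 0.45,
                                  MITOSIS = 0.05), n = 220L),
    stop("unknown tumor_type: ", tumor_type, " (use PTC, PAD or BDC)")
  )
  n <- if (is.null(n_nuclei)) par$n else as.integer(n_nuclei)
  n_pos <- max(1L, round(n * par$pi / 100))
  pos <- apportion(n_pos, par$mix)
  counts <- c(NEGATIVE = n - n_pos, pos)
  spec <- synth_spec(tile_px = tile_px, counts = counts,
                     area_mean_um2 = par$area, area_cv = par$cv,
                     ratio_range = par$ratio, seed = seed)
  attr(spec, "pi_percent") <- par$pi
  attr(spec, "mix") <- par$mix
  attr(spec, "tumor_type") <- tumor_type
  spec
}

## largest-remainder apportionment of n among weights (deterministic)
apportion <- function(n, weights) {
  q <- n * weights / sum(weights)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(weights))
}

#' Generate a synthetic H-DAB tile with ground truth
#'
#' Plants non-overlapping elliptical nuclei (rejection-sampled positions),
#' paints per-class hematoxylin and DAB concentration fields, renders to
#' 8-bit RGB through the Beer-Lambert model with the default H-DAB stain
#' matrix, and adds Gaussian sensor noise. Identical specs (including
#' seed) reproduce the tile bit-exactly.
#'
#' @param spec a [synth_spec()].
#' @return list with `tile` (an [rgb_tile()]) and `truth`: `label` (H x W
#'   nucleus-id matrix), `nuclei` (data.frame: `nucleus_id, class, cx, cy,
#'   area_px, a_px, b_px, planted_granules, planted_nodes,
#'   planted_dab_px`), and the `spec`.
#' @export
generate_tile <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_local_seed(spec$seed, generate_tile_impl(spec))
}

generate_tile_impl <- function(spec) {
  ps <- spec$pixel_size
  Hd <- spec$tile_px; Wd <- spec$tile_px
  classes <- rep(names(spec$counts), times = spec$counts)
  n <- length(classes)
  hema <- matrix(0.08, Hd, Wd)          # faint cytoplasm/stroma counterstain
  dab <- matrix(0, Hd, Wd)
  label <- matrix(0L, Hd, Wd)
  truth <- list()
  if (n > 0L) {
    classes <- sample(classes)          # shuffle spatial placement order
    ## sample geometry first, then place largest-first (easier packing)
    sdlog <- sqrt(log(1 + spec$area_cv^2))
    areas_um <- rlnorm(n, log(spec$area_mean_um2) - sdlog^2 / 2, sdlog)
    scale_cls <- c(NEGATIVE = 1, NG1 = 1, NG2 = 1, NG3_4 = 1.3, MITOSIS = 0.9)
    areas_um <- areas_um * scale_cls[classes]
    ratios <- runif(n, spec$ratio_range[1], spec$ratio_range[2])
    a_px <- sqrt(areas_um / ps^2 / (pi * ratios))
    b_px <- a_px * ratios
    phis <- runif(n, 0, pi)
    ord <- order(a_px, decreasing = TRUE)
    centers <- place_nuclei(a_px[ord], Hd, Wd)
    if (is.null(centers)) {
      stop("infeasible packing: ", n, " nuclei of mean area ",
           signif(spec$area_mean_um2, 4), " um^2 exceed the density limit of a ",
           Hd, " px tile")
    }
    inv <- integer(n); inv[ord] <- seq_len(n)
    centers <- centers[inv, , drop = FALSE]
    for (i in seq_len(n)) {
      nuc <- paint_nucleus(hema, dab, label, i, classes[i],
                           centers[i, 1], centers[i, 2],
                           a_px[i], b_px[i], phis[i], spec)
      hema <- nuc$hema; dab <- nuc$dab; label <- nuc$label
      truth[[i]] <- nuc$row
    }
  }
  od <- compose_od(hema, dab)
  rgb <- od_to_rgb(od)
  if (spec$blur_sigma_px > 0) {
    for (ch in 1:3) {
      rgb[, , ch] <- as.matrix(EBImage::gblur(rgb[, , ch], spec$blur_sigma_px))
    }
  }
  if (spec$noise_sd > 0) {
    rgb <- rgb + array(rnorm(length(rgb), 0, spec$noise_sd), dim = dim(rgb))
  }
  rgb <- pmin(pmax(round(rgb), 0), 255)
  tile <- rgb_tile(rgb, ps, tile_id = sprintf("synth_seed%d", spec$seed))
  nuclei <- if (length(truth)) do.call(rbind, truth) else
    data.frame(nucleus_id = integer(0), class = character(0), cx = numeric(0),
               cy = numeric(0), area_px = integer(0), a_px = numeric(0),
               b_px = numeric(0), planted_granules = integer(0),
               planted_nodes = integer(0), planted_dab_px = integer(0))
  list(tile = tile, truth = list(label = label, nuclei = nuclei, spec = spec))
}

## rejection-sample non-overlapping centres (bounding-circle test);
## NULL on failure after bounded attempts
place_nuclei <- function(radii, Hd, Wd, margin = 3, max_attempts = 400L) {
  n <- length(radii)
  cx <- numeric(n); cy <- numeric(n)
  for (i in seq_len(n)) {
    r <- radii[i]
    lo <- r + margin + 1
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      x <- runif(1, lo, Wd - lo); y <- runif(1, lo, Hd - lo)
      if (i == 1L ||
          all((cx[seq_len(i - 1)] - x)^2 + (cy[seq_len(i - 1)] - y)^2 >
              (radii[seq_len(i - 1)] + r + margin)^2)) {
        ok <- TRUE; break
      }
    }
    if (!ok) return(NULL)
    cx[i] <- x; cy[i] <- y
  }
  cbind(cx, cy)
}

## paint one nucleus into the concentration fields; returns updated fields
## and its ground-truth row
paint_nucleus <- function(hema, dab, label, id, class, cx, cy, a, b, phi, spec) {
  Hd <- nrow(hema); Wd <- ncol(hema)
  ps <- spec$pixel_size
  r_out <- ceiling(a) + 2L
  rows <- max(1L, floor(cy - r_out)):min(Hd, ceiling(cy + r_out))
  cols <- max(1L, floor(cx - r_out)):min(Wd, ceiling(cx + r_out))
  gx <- matrix(rep(cols, each = length(rows)), length(rows))
  gy <- matrix(rep(rows, times = length(cols)), length(rows))
  dx <- gx - cx; dy <- gy - cy
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  sel <- cbind(as.vector(gy)[inside], as.vector(gx)[inside])
  hema[sel] <- spec$hema_od * (1 + rnorm(nrow(sel), 0, 0.05))
  label[sel] <- id
  area_px <- nrow(sel)

  ## class-specific DAB texture, painted as discs in concentration space
  g_r <- spec$granule_d_um / 2 / ps
  n_r <- spec$node_d_um / 2 / ps
  granules <- 0L; nodes <- 0L
  disc_at <- function(dab, px, py, r, od) {
    rr <- max(1L, floor(py - r - 1)):min(Hd, ceiling(py + r + 1))
    cc <- max(1L, floor(px - r - 1)):min(Wd, ceiling(px + r + 1))
    ggx <- matrix(rep(cc, each = length(rr)), length(rr))
    ggy <- matrix(rep(rr, times = length(cc)), length(rr))
    hit <- (ggx - px)^2 + (ggy - py)^2 <= r^2
    pts <- cbind(as.vector(ggy)[hit], as.vector(ggx)[hit])
    dab[pts] <- pmax(dab[pts], od)
    dab
  }
  ## rejection-sample puncta centres inside the scaled ellipse, min separation
  sample_puncta <- function(k, rho_max, min_sep, rho_min = 0) {
    pts <- matrix(numeric(0), 0, 2)
    for (j in seq_len(k)) {
      for (a2 in 1:80) {
        rho <- sqrt(runif(1, rho_min^2, rho_max^2)); th <- runif(1, 0, 2 * pi)
        uu <- rho * a * cos(th); vv <- rho * b * sin(th)
        px <- cx + uu * cos(phi) - vv * sin(phi)
        py <- cy + uu * sin(phi) + vv * cos(phi)
        if (!nrow(pts) ||
            all((pts[, 1] - px)^2 + (pts[, 2] - py)^2 > min_sep^2)) {
          pts <- rbind(pts, c(px, py)); break
        }
      }
    }
    pts
  }
  if (class == "NG1") {
    k <- max(5L, min(14L, round(area_px / 40)))
    pts <- sample_puncta(k, rho_max = 0.80, min_sep = 2 * g_r + 1.5)
    for (j in seq_len(nrow(pts))) {
      dab <- disc_at(dab, pts[j, 1], pts[j, 2], g_r, spec$granule_od)
    }
    granules <- nrow(pts)
  } else if (class == "NG2") {
    k <- sample(1:2, 1)
    pts <- sample_puncta(k, rho_max = 0.45, min_sep = 2 * n_r + 2)
    for (j in seq_len(nrow(pts))) {
      dab <- disc_at(dab, pts[j, 1], pts[j, 2], n_r, spec$node_od)
    }
    nodes <- nrow(pts)
  } else if (class == "NG3_4") {
    dab[sel] <- pmax(dab[sel], spec$fill_od * (1 + rnorm(nrow(sel), 0, 0.05)))
  } else if (class == "MITOSIS") {
    if (spec$mitosis_style == "bar") {
      ## condensed chromosome mass: central bar of intense DAB
      bar <- abs(v[inside]) <= 0.45 * b
      pts <- sel[bar, , drop = FALSE]
      dab[pts] <- pmax(dab[pts], spec$granule_od)
    } else {
      ## ring of coarse peripheral granules hugging the membrane, empty
      ## centre; discs overlap into a near-continuous prometaphase ring
      m_r <- 1.1 / 2 / ps
      circ <- pi * (a + b)                    # ellipse perimeter approx
      k <- max(8L, round(circ / (1.8 * m_r)))
      ths <- seq(0, 2 * pi, length.out = k + 1L)[-1L] + runif(1, 0, pi / 8)
      for (th in ths) {
        uu <- 0.90 * a * cos(th); vv <- 0.90 * b * sin(th)
        px <- cx + uu * cos(phi) - vv * sin(phi)
        py <- cy + uu * sin(phi) + vv * cos(phi)
        dab <- disc_at(dab, px, py, m_r, spec$granule_od)
      }
      granules <- k
    }
  }
  ## planted positive pixels: painted DAB above the reference threshold,
  ## within this nucleus's mask
  planted <- sum(dab[sel] > spec$theta_ref)
  list(hema = hema, dab = dab, label = label,
       row = data.frame(nucleus_id = id, class = class, cx = cx - 1, cy = cy - 1,
                        area_px = area_px, a_px = a, b_px = b,
                        planted_granules = granules, planted_nodes = nodes,
                        planted_dab_px = planted, stringsAsFactors = FALSE))
}

#' Simulate a clinical cohort with survival outcomes
#'
#' Draws case-level covariates (age, sex, stage, tumour size, positive
#' lymph nodes, NG pixel scores, proliferation index) from documented
#' distributions and event times from a Weibull proportional-hazards model
#' with user-supplied log hazard ratios. Censoring is independent uniform
#' on `(0, tau)` with `tau` solved so the expected censored fraction
#' matches the request.
#'
#' @param n number of cases.
#' @param effects named numeric vector of log hazard ratios; names must be
#'   numeric columns of the generated table (e.g. `c(sex_male = log(2))`,
#'   or `ng1_px`, `age`). Default: no effects (null model).
#' @param censoring target censored fraction in \[0, 1).
#' @param seed integer seed; fixes the cohort bit-exactly.
#' @param baseline Weibull baseline: list with `shape` and `scale`
#'   (months).
#' @return data.frame of case records: `case_id, tumor_type, age, sex,
#'   sex_male, stage, tumor_size, ln_positive, pi_percent, ng1_px, ng2_px,
#'   ng34_px, pfd_months, event`.
#' @export
generate_cohort <- function(n, effects = NULL, censoring = 0.3, seed = 1L,
                            baseline = list(shape = 1.2, scale = 60)) {
  stopifnot(n >= 1, censoring >= 0, censoring < 1)
  with_local_seed(seed, {
    df <- data.frame(
      case_id = sprintf("case%04d", seq_len(n)),
      tumor_type = "PTC",
      age = round(rnorm(n, 46, 12), 1),
      stringsAsFactors = FALSE
    )
    df$sex_male <- rbinom(n, 1L, 0.52)
    df$sex <- ifelse(df$sex_male == 1L, "male", "female")
    df$stage <- sample(c("I", "II", "IIIA"), n, replace = TRUE,
                       prob = c(0.75, 0.125, 0.125))
    df$tumor_size <- round(rlnorm(n, log(2.0), 0.4), 2)
    df$ln_positive <- rpois(n, 0.4)
    df$pi_percent <- round(pmin(100, rlnorm(n, log(0.4), 0.6)), 3)
    df$ng1_px <- round(rlnorm(n, log(16.7), 0.4), 2)
    df$ng2_px <- round(rlnorm(n, log(2.5), 0.4), 2)
    df$ng34_px <- round(rlnorm(n, log(2.8), 0.4), 2)

    lp <- rep(0, n)
    if (!is.null(effects) && length(effects)) {
      for (nm in names(effects)) {
        if (!nm %in% names(df)) stop("effect on unknown covariate: ", nm)
        x <- df[[nm]]
        if (!is.numeric(x)) stop("effects must target numeric covariates: ", nm)
        lp <- lp + effects[[nm]] * x
      }
    }
    stopifnot(all(is.finite(lp)))
    k <- baseline$shape
    t_event <- ((-log(runif(n)) / exp(lp))^(1 / k)) * baseline$scale
    if (censoring > 0) {
      f <- function(tau) mean(pmin(t_event / tau, 1)) - censoring
      tau <- uniroot(f, c(1e-6, max(t_event) * 1e3), tol = 1e-8)$root
      t_cens <- runif(n, 0, tau)
    } else {
      t_cens <- rep(Inf, n)
    }
    df$pfd_months <- round(pmin(t_event, t_cens), 3)
    df$event <- t_event <= t_cens
    df
  })
}
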