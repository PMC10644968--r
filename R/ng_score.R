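## Nuclear morphometry, Ki-67 gradient feature extraction, rule-based
## nuclear-gradient (NG) classification, positive-nucleus sampling, the
## proliferation index, and "NG in pixels" aggregation.

#' Nuclear morphometry from a pixel mask
#'
#' Area is the pixel count scaled by the pixel area; length and width are
#' the major and minor axes of the ellipse with the same second central
#' moments as the mask (a 1/12 px^2 term accounts for the finite pixel
#' extent), scaled to micrometres.
#'
#' @param nucleus a nucleus object.
#' @param pixel_size um per pixel.
#' @return list with `area` (um^2), `length`, `width` (um) and `ratio`
#'   (width/length, in (0, 1]).
#' @export
compute_morphometry <- function(nucleus, pixel_size) {
  if (!length(nucleus$idx)) stop("empty nucleus mask")
  H <- nucleus$dim[1]
  y <- ((nucleus$idx - 1L) %% H)
  x <- ((nucleus$idx - 1L) %/% H)
  n <- length(x)
  mu20 <- mean(x^2) - mean(x)^2 + 1 / 12
  mu02 <- mean(y^2) - mean(y)^2 + 1 / 12
  mu11 <- mean(x * y) - mean(x) * mean(y)
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 1e-12)
  len <- 4 * sqrt(l1) * pixel_size
  wid <- 4 * sqrt(l2) * pixel_size
  list(area = n * pixel_size^2, length = len, width = wid,
       ratio = min(1, wid / len))
}

#' Extract Ki-67 gradient features for one nucleus
#'
#' Operationalises the staining-pattern criteria: DAB-positive blobs inside
#' the mask are sized by equivalent diameter and counted as *granules*
#' (fine puncta, diameter within `ng$granule_um`) or *nodes* (perinucleolar
#' blobs, diameter within `ng$node_um`); the *rim* is a boundary band of
#' width `ng$rim_um` (membrane positivity); the *central void* compares
#' positivity in a central disc (radius `ng$center_frac` of the equivalent
#' radius) against the rim band — mitotic rings are positive at the rim and
#' empty in the centre.
#'
#' @param nucleus a nucleus object.
#' @param dab_map DAB concentration matrix (full tile).
#' @param theta DAB absorbance threshold (OD), >= 0.
#' @param pixel_size um per pixel.
#' @param config pipeline configuration.
#' @param area_stats optional list `(median, sd)` of nucleus areas on the
#'   tile, used for the `area_z` feature; defaults to `area_z = 0`.
#' @return list of features: `mean_dab_od`, `dab_pos_px`, `fill_fraction`,
#'   `granule_count`, `node_count`, `rim_fraction`, `center_void`, `od_cv`,
#'   `area_z`.
#' @export
extract_ng_features <- function(nucleus, dab_map, theta, pixel_size,
                                config = ki67_config(), area_stats = NULL) {
  if (theta < 0) stop("theta must be >= 0")
  ps <- pixel_size
  sm <- nucleus_submask(nucleus)
  sub <- sm$sub
  dab <- dab_map[sm$rows, sm$cols, drop = FALSE]
  vals <- dab[sub]
  pos_sub <- (dab > theta) & sub
  npx <- sum(sub)
  dab_pos_px <- sum(pos_sub)
  mean_od <- mean(vals)
  od_cv <- if (mean_od > 0) sd(vals) / mean_od else 0

  ## blob census: connected DAB-positive components, sized in um
  granules <- 0L; nodes <- 0L
  if (dab_pos_px > 0L) {
    lab <- EBImage::bwlabel(pos_sub * 1)
    sizes <- tabulate(as.integer(lab)[as.integer(lab) > 0])
    d_um <- 2 * sqrt(sizes / pi) * ps
    gb <- config$ng$granule_um; nb <- config$ng$node_um
    granules <- sum(d_um >= gb[1] & d_um <= gb[2])
    nodes <- sum(d_um >= nb[1] & d_um <= nb[2])
  }

  ## rim band: mask minus erosion by the rim width
  rim_px <- max(1L, round(config$ng$rim_um / ps))
  brush <- EBImage::makeBrush(2L * rim_px + 1L, shape = "disc")
  er <- pad_erode(sub, brush)
  band <- sub & !er
  rim_fraction <- if (any(band)) mean(pos_sub[band]) else 0

  ## central disc vs rim band
  r_eq <- sqrt(npx / pi)
  cy <- mean(((nucleus$idx - 1L) %% nucleus$dim[1]) + 1L) - sm$rows[1] + 1L
  cx <- mean(((nucleus$idx - 1L) %/% nucleus$dim[1]) + 1L) - sm$cols[1] + 1L
  gx <- matrix(rep(seq_len(ncol(sub)), each = nrow(sub)), nrow(sub))
  gy <- matrix(rep(seq_len(nrow(sub)), times = ncol(sub)), nrow(sub))
  disc <- ((gx - cx)^2 + (gy - cy)^2 <= (config$ng$center_frac * r_eq)^2) & sub
  center_pos <- if (any(disc)) mean(pos_sub[disc]) else 0
  center_void <- if (rim_fraction > 0) {
    min(1, max(0, 1 - center_pos / rim_fraction))
  } else 0

  area_z <- 0
  if (!is.null(area_stats) && is.finite(area_stats$sd) && area_stats$sd > 0) {
    area_z <- (npx * ps^2 - area_stats$median) / area_stats$sd
  }

  list(mean_dab_od = mean_od, dab_pos_px = dab_pos_px,
       fill_fraction = dab_pos_px / npx,
       granule_count = granules, node_count = nodes,
       rim_fraction = rim_fraction, center_void = center_void,
       od_cv = od_cv, area_z = area_z)
}

## erosion with zero padding so border-touching masks erode correctly
pad_erode <- function(sub, brush) {
  p <- (dim(brush)[1] - 1L) / 2L
  big <- matrix(0, nrow(sub) + 2L * p, ncol(sub) + 2L * p)
  big[(p + 1L):(p + nrow(sub)), (p + 1L):(p + ncol(sub))] <- sub * 1
  er <- EBImage::erode(big, brush)
  er[(p + 1L):(p + nrow(sub)), (p + 1L):(p + ncol(sub))] > 0.5
}

#' Classify the Ki-67 nuclear gradient of one nucleus
#'
#' Ordered decision list; the first matching rule wins. Specific patterns
#' pre-empt generic ones because mitoses and homogeneously filled nuclei
#' also contain granule-scale blobs:
#' \enumerate{
#'   \item mean DAB OD below `qc$weak_od` -> `NEGATIVE` (resting, G0/NA);
#'   \item mitosis: an empty central area with peripheral positivity
#'     (`center_void >= ng$void_min` and `rim_fraction >= ng$mitosis_rim_min`),
#'     *or* a condensed strongly positive mass (`fill_fraction >= 0.5` with
#'     `area_z <= ng$mitosis_area_z`) -> `MITOSIS` (M);
#'   \item homogeneous intense fill (`fill_fraction >= ng$fill_high`) ->
#'     `NG3_4` (S/G2);
#'   \item one or two perinucleolar nodes (`node_count` 1-2 without high
#'     fill) -> `NG2` (late G1/S);
#'   \item granular or membrane positivity (`granule_count >=
#'     ng$granule_min` or `rim_fraction >= ng$rim_min`) -> `NG1` (G1);
#'   \item otherwise `NG1` (weakest positive pattern, default assignment).
#' }
#'
#' @param features feature list from [extract_ng_features()].
#' @param config pipeline configuration.
#' @return list with `value` (one of NEGATIVE, NG1, NG2, NG3_4, MITOSIS),
#'   `cycle_phase` annotation, and `default_assigned` (TRUE when rule 6
#'   fired).
#' @export
classify_ng <- function(features, config = ki67_config()) {
  f <- features
  ng <- config$ng
  stopifnot(all(is.finite(c(f$mean_dab_od, f$fill_fraction, f$granule_count,
                            f$node_count, f$rim_fraction, f$center_void))))
  out <- function(value, phase, default_assigned = FALSE) {
    list(value = value, cycle_phase = phase, default_assigned = default_assigned)
  }
  if (f$mean_dab_od < config$qc$weak_od) return(out("NEGATIVE", "G0"))
  if ((f$center_void >= ng$void_min && f$rim_fraction >= ng$mitosis_rim_min) ||
      (f$fill_fraction >= 0.5 && f$area_z <= ng$mitosis_area_z)) {
    return(out("MITOSIS", "M"))
  }
  if (f$fill_fraction >= ng$fill_high) return(out("NG3_4", "S/G2"))
  if (f$node_count %in% c(1L, 2L)) return(out("NG2", "late G1/S"))
  if (f$granule_count >= ng$granule_min || f$rim_fraction >= ng$rim_min) {
    return(out("NG1", "G1"))
  }
  out("NG1", "G1", default_assigned = TRUE)
}

#' Sample positive nuclei for scoring
#'
#' Uniform sampling without replacement of `n` nuclei from the supplied
#' (QC-passed, Ki-67-positive) set, deterministic for a given seed; when
#' fewer than `n` are available all are returned and the shortfall is
#' recorded. The scoring protocol samples 1000 nuclei per run.
#'
#' @param nuclei a nucleus table (data.frame) or list of nucleus objects,
#'   already filtered to QC `OK` and non-`NEGATIVE` labels.
#' @param n number to sample (>= 1).
#' @param seed integer RNG seed; the caller's RNG state is untouched.
#' @return subset of `nuclei` (same type); attribute `shortfall` gives
#'   `max(0, n - available)`.
#' @export
sample_positive <- function(nuclei, n, seed = 42L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be >= 1")
  avail <- if (is.data.frame(nuclei)) nrow(nuclei) else length(nuclei)
  take <- min(n, avail)
  pick <- with_local_seed(seed, sample.int(avail, take))
  pick <- sort(pick)
  out <- if (is.data.frame(nuclei)) nuclei[pick, , drop = FALSE] else nuclei[pick]
  attr(out, "shortfall") <- max(0L, as.integer(n) - avail)
  out
}

## run expr under a fixed seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Ki-67 proliferation index
#'
#' Percentage of countable tumour nuclei that are Ki-67 positive. The
#' denominator is every nucleus that survived morphological QC (flags `OK`
#' or `WEAK` — weakly/un-stained nuclei are countable negatives, unlike
#' overlapping, blurred or edge-cut nuclei, which are excluded from both
#' numerator and denominator); the numerator is the QC-`OK` nuclei whose NG
#' label is not `NEGATIVE`.
#'
#' @param table a nucleus table with `qc_flag` and `ng_label` columns.
#' @return percentage in \[0, 100\], or `NA` when no countable nuclei.
#' @export
proliferation_index <- function(table) {
  countable <- table$qc_flag %in% c("OK", "WEAK")
  if (!any(countable)) return(NA_real_)
  pos <- table$qc_flag == "OK" & !is.na(table$ng_label) &
    table$ng_label != "NEGATIVE"
  100 * sum(pos) / sum(countable)
}

#' Ki-67 NG in pixels: per-class aggregation
#'
#' For each positive NG class, sums the DAB-positive pixel counts
#' (`dab_pos_px`, computed at the fixed absorbance threshold) of the
#' sampled nuclei and reports totals and per-nucleus means. The
#' aggregation hierarchy is nucleus -> core -> case: the case-level value
#' of a class is the mean of its per-core mean over valid cores.
#'
#' @param table sampled, classified nucleus table.
#' @param valid_cores optional character vector of valid `core_id`s; when
#'   supplied, case-level aggregation uses only those cores.
#' @return list of data.frames: `per_class` (class, count, total_px,
#'   mean_px), `per_core`, `per_case`.
#' @export
ng_pixel_scores <- function(table, valid_cores = NULL) {
  classes <- c("NG1", "NG2", "NG3_4", "MITOSIS")
  t_pos <- table[!is.na(table$ng_label) & table$ng_label %in% classes, ,
                 drop = FALSE]
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    px <- t_pos$dab_pos_px[t_pos$ng_label == cl]
    data.frame(ng_class = cl, count = length(px),
               total_px = if (length(px)) sum(px) else 0,
               mean_px = if (length(px)) mean(px) else 0,
               stringsAsFactors = FALSE)
  }))
  agg_by <- function(key) {
    keys <- unique(t_pos[[key]])
    keys <- keys[!is.na(keys)]
    do.call(rbind, lapply(keys, function(k) {
      sub <- t_pos[t_pos[[key]] %in% k, , drop = FALSE]
      do.call(rbind, lapply(classes, function(cl) {
        px <- sub$dab_pos_px[sub$ng_label == cl]
        data.frame(id = k, ng_class = cl, count = length(px),
                   total_px = if (length(px)) sum(px) else 0,
                   mean_px = if (length(px)) mean(px) else 0,
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  per_core <- agg_by("core_id")
  t_case <- t_pos
  if (!is.null(valid_cores)) {
    t_case <- t_case[t_case$core_id %in% valid_cores, , drop = FALSE]
  }
  per_case <- NULL
  cases <- unique(t_case$case_id); cases <- cases[!is.na(cases)]
  if (length(cases)) {
    pc <- if (!is.null(valid_cores)) {
      pcv <- agg_by("core_id")
      pcv[pcv$id %in% valid_cores, , drop = FALSE]
    } else per_core
    core_case <- unique(t_case[, c("core_id", "case_id")])
    per_case <- do.call(rbind, lapply(cases, function(cs) {
      cores <- core_case$core_id[core_case$case_id == cs]
      sub <- pc[pc$id %in% cores, , drop = FALSE]
      do.call(rbind, lapply(classes, function(cl) {
        v <- sub[sub$ng_class == cl, , drop = FALSE]
        data.frame(case_id = cs, ng_class = cl,
                   count = sum(v$count),
                   total_px = sum(v$total_px),
                   mean_px = if (nrow(v)) mean(v$mean_px) else 0,
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  list(per_class = per_class, per_core = per_core, per_case = per_case)
}
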