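## End-to-end tile scoring and ground-truth evaluation helpers.

#' Score a tile end to end
#'
#' Runs the full pipeline on one tile: tissue detection, stain model
#' (default matrix or per-tile estimation), colour deconvolution, tumour
#' gating, nucleus segmentation on the hematoxylin channel, per-nucleus QC,
#' morphometry, NG feature extraction and classification, and assembly of
#' the per-nucleus table plus the core QC record.
#'
#' @param tile an [rgb_tile()].
#' @param config pipeline configuration, see [ki67_config()].
#' @param case_id case identifier attached to the output rows.
#' @param tumor_mask optional expert tumour mask overriding the heuristic.
#' @return list: `table` (nucleus table), `nuclei` (scored nucleus
#'   objects), `core` (core QC record), `tissue`, `tumor`, `model`,
#'   `maps` (hema/dab concentration matrices).
#' @export
score_tile <- function(tile, config = ki67_config(), case_id = NA_character_,
                       tumor_mask = NULL) {
  stopifnot(inherits(tile, "rgb_tile"))
  ps <- tile$pixel_size
  tissue <- detect_tissue(tile, config)
  model <- if (isTRUE(config$stains$estimate)) {
    estimate_stain_vectors(tile)
  } else {
    stain_model(config$stains$default_matrix, provenance = "default")
  }
  maps <- deconvolve(rgb_to_od(tile), model)
  tumor <- segment_tumor_region(tile, tissue$mask, user_mask = tumor_mask,
                                config = config, model = model)
  nuclei <- segment_nuclei(maps$hema, ps, config, region = tissue$mask)
  nuclei <- lapply(nuclei, qc_nucleus, tile = tile, dab_map = maps$dab,
                   config = config)
  areas <- vapply(nuclei, function(nuc) length(nuc$idx) * ps^2, numeric(1))
  area_stats <- list(median = median(areas), sd = sd(areas))
  theta <- config$stains$theta
  nuclei <- lapply(nuclei, function(nuc) {
    nuc$morphometry <- compute_morphometry(nuc, ps)
    nuc$features <- extract_ng_features(nuc, maps$dab, theta, ps, config,
                                        area_stats = area_stats)
    cls <- classify_ng(nuc$features, config)
    nuc$ng_label <- cls$value
    nuc$cycle_phase <- cls$cycle_phase
    nuc
  })
  core <- qc_core(nuclei, tumor$tumor_fraction, core_id = tile$core_id,
                  case_id = case_id, config = config)
  list(table = nuclei_to_table(nuclei, tile, case_id = case_id),
       nuclei = nuclei, core = core, tissue = tissue, tumor = tumor,
       model = model, maps = maps)
}

#' Match detected nuclei to ground truth and evaluate recovery
#'
#' Greedy nearest-centroid matching (closest pairs first, each nucleus and
#' each ground-truth entry used at most once, maximum distance
#' `max_dist_px`), then per-class precision and recall of the NG labels.
#' Edge-flagged detections and edge-adjacent truths are excluded from
#' scoring, as the protocol excludes border-cut nuclei.
#'
#' @param table scored nucleus table from [score_tile()].
#' @param truth ground truth from [generate_tile()].
#' @param max_dist_px matching radius in pixels.
#' @return list: `matches` (data.frame of matched pairs with detected and
#'   true labels), `per_class` (data.frame: class, n_true, n_pred, tp,
#'   precision, recall), `detection_recall`.
#' @export
evaluate_recovery <- function(table, truth, max_dist_px = 6) {
  tr <- truth$nuclei
  det <- table
  if (nrow(det)) det <- det[det$qc_flag != "EDGE", , drop = FALSE]
  if (!nrow(tr) || !nrow(det)) {
    return(list(matches = NULL, per_class = NULL, detection_recall = 0))
  }
  d2 <- outer(det$centroid_x_px, tr$cx, "-")^2 +
    outer(det$centroid_y_px, tr$cy, "-")^2
  cand <- which(d2 <= max_dist_px^2, arr.ind = TRUE)
  if (nrow(cand)) {
    cand <- cand[order(d2[cand]), , drop = FALSE]
    used_d <- logical(nrow(det)); used_t <- logical(nrow(tr))
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      di <- cand[i, 1]; ti <- cand[i, 2]
      if (!used_d[di] && !used_t[ti]) {
        keep[i] <- TRUE; used_d[di] <- TRUE; used_t[ti] <- TRUE
      }
    }
    cand <- cand[keep, , drop = FALSE]
  }
  matches <- data.frame(
    det_row = cand[, 1], true_row = cand[, 2],
    pred = det$ng_label[cand[, 1]],
    truth = tr$class[cand[, 2]],
    qc_flag = det$qc_flag[cand[, 1]],
    stringsAsFactors = FALSE
  )
  classes <- c("NEGATIVE", "NG1", "NG2", "NG3_4", "MITOSIS")
  ## recall counts missed detections against each true class; precision
  ## counts every (non-edge) detection carrying the label, matched or not
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(matches$pred == cl & matches$truth == cl, na.rm = TRUE)
    n_pred <- sum(det$ng_label == cl, na.rm = TRUE)
    n_true <- sum(tr$class == cl)
    data.frame(ng_class = cl, n_true = n_true, n_pred = n_pred, tp = tp,
               precision = if (n_pred) tp / n_pred else NA_real_,
               recall = if (n_true) tp / n_true else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(matches = matches, per_class = per_class,
       detection_recall = nrow(matches) / nrow(tr))
}
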