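# Shared fixtures, built in code.

# small reference tile specs (512 px, ~55 nuclei) used across module tests
small_counts <- c(NEGATIVE = 20L, NG1 = 10L, NG2 = 10L, NG3_4 = 10L, MITOSIS = 5L)

small_spec <- function(seed = 5L, ...) {
  synth_spec(tile_px = 512L, counts = small_counts, seed = seed, ...)
}

# cache expensive fixtures for the session
.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

small_tile <- function() cached("small_tile", generate_tile(small_spec()))

small_scored <- function() cached("small_scored", score_tile(small_tile()$tile))

# binary mask of a digital disk / axis-aligned ellipse, as a nucleus object
mask_to_nucleus <- function(mask, id = 1L) {
  idx <- which(mask)
  structure(list(
    nucleus_id = id, idx = idx, dim = dim(mask),
    centroid = c(mean((idx - 1L) %/% nrow(mask)), mean((idx - 1L) %% nrow(mask))),
    bbox = NULL, polygon = NULL, qc_flag = NA_character_,
    morphometry = NULL, features = NULL, ng_label = NULL
  ), class = "nucleus")
}

ellipse_mask <- function(H, W, cy, cx, a, b) {
  gy <- matrix(rep(seq_len(H), times = W), H)
  gx <- matrix(rep(seq_len(W), each = H), H)
  ((gx - cx) / a)^2 + ((gy - cy) / b)^2 <= 1
}

disk_mask <- function(H, W, cy, cx, r) ellipse_mask(H, W, cy, cx, r, r)

# paint dab discs into a matrix at given centres
paint_discs <- function(dab, centers, r, od) {
  for (i in seq_len(nrow(centers))) {
    hit <- disk_mask(nrow(dab), ncol(dab), centers[i, 1], centers[i, 2], r)
    dab[hit] <- pmax(dab[hit], od)
  }
  dab
}

# tiny 3-row nucleus table satisfying all invariants
tiny_nucleus_table <- function() {
  data.frame(
    tile_id = "t1", core_id = "c1", case_id = "p1",
    nucleus_id = 1:3,
    centroid_x_px = c(10.5, 20, 30.25), centroid_y_px = c(5, 15.5, 25),
    area_um2 = c(24.4, 30.1, 18.9), length_um = c(8.3, 9.1, 7.2),
    width_um = c(6.1, 7.0, 5.5), ratio = c(0.73, 0.77, 0.76),
    qc_flag = c("OK", "OVERLAP", "OK"),
    mean_dab_od = c(0.42, 0.05, 0.31), dab_pos_px = c(120L, 0L, 85L),
    granule_count = c(7L, 0L, 4L), node_count = c(0L, 0L, 1L),
    ng_label = c("NG1", "NEGATIVE", "NG2"),
    stringsAsFactors = FALSE
  )
}
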