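test_that("morphometry matches analytic circle and ellipse", {
  disk <- mask_to_nucleus(disk_mask(64, 64, 32, 32, 10))
  m <- compute_morphometry(disk, 0.25)
  expect_equal(m$area, pi * 2.5^2, tolerance = 0.05 * pi * 2.5^2)
  expect_equal(m$ratio, 1, tolerance = 0.02)

  ell <- mask_to_nucleus(ellipse_mask(96, 96, 48, 48, 20, 10))
  me <- compute_morphometry(ell, 0.25)
  expect_equal(me$ratio, 0.5, tolerance = 0.03)
  expect_equal(me$length, 2 * 20 * 0.25, tolerance = 0.05 * 10)
  expect_error(compute_morphometry(mask_to_nucleus(matrix(FALSE, 4, 4)), 0.25),
               "empty")
})

test_that("generator morphometry calibration is recovered by measurement", {
  # nuclei drawn with the carcinoid-like area calibration, measured on
  # ground-truth masks
  areas <- c()
  for (s in 1:3) {
    gt <- generate_tile(synth_preset("PTC", n_nuclei = 180L, tile_px = 768L,
                                     seed = s))
    nucs <- ki67ng:::make_nuclei_from_labels(gt$truth$label, 0.25,
                                             filter_area = FALSE)
    areas <- c(areas, vapply(nucs, function(n) compute_morphometry(n, 0.25)$area,
                             numeric(1)))
  }
  se <- sd(areas) / sqrt(length(areas))
  expect_lt(abs(mean(areas) - 24.38), 2 * se + 0.5)
})

test_that("NG features respond to painted patterns", {
  H <- 64; W <- 64
  mask <- disk_mask(H, W, 32, 32, 12)          # r = 12 px = 3 um
  nuc <- mask_to_nucleus(mask)

  # zero DAB -> all-zero features
  f0 <- extract_ng_features(nuc, matrix(0, H, W), 0.15, 0.25)
  expect_equal(f0$dab_pos_px, 0L)
  expect_equal(f0$granule_count, 0L)
  expect_equal(f0$node_count, 0L)
  expect_equal(f0$rim_fraction, 0)
  expect_equal(f0$fill_fraction, 0)

  # 7 puncta of diameter 0.6 um (r ~ 1.2 px)
  set.seed(2)
  ctr <- cbind(c(25, 25, 32, 39, 39, 32, 28), c(26, 38, 22, 27, 37, 42, 32))
  dab <- paint_discs(matrix(0, H, W), ctr, 1.2, 0.8)
  f7 <- extract_ng_features(nuc, dab, 0.15, 0.25)
  expect_true(f7$granule_count %in% 6:8)
  expect_equal(f7$node_count, 0L)

  # 2 nodes of 2.5 um (r = 5 px)
  dabn <- paint_discs(matrix(0, H, W), cbind(c(28, 36), c(28, 37)), 5, 0.9)
  f2 <- extract_ng_features(nuc, dabn, 0.15, 0.25)
  expect_equal(f2$node_count, 2L)
  expect_lte(f2$granule_count, 2L)

  expect_error(extract_ng_features(nuc, dab, -0.1, 0.25), "theta")
})

test_that("classification follows the ordered decision list", {
  base <- list(mean_dab_od = 0.4, dab_pos_px = 100L, fill_fraction = 0.2,
               granule_count = 0L, node_count = 0L, rim_fraction = 0,
               center_void = 0, od_cv = 0.5, area_z = 0)
  cls <- function(over) {
    classify_ng(modifyList(base, over))$value
  }
  # weak staining wins first
  expect_equal(cls(list(mean_dab_od = 0.02)), "NEGATIVE")
  # intense homogeneous fill
  expect_equal(cls(list(fill_fraction = 0.9, node_count = 2L,
                        mean_dab_od = 0.8, center_void = 0.1)), "NG3_4")
  # one or two perinucleolar nodes without high fill
  expect_equal(cls(list(node_count = 2L, fill_fraction = 0.2,
                        granule_count = 1L)), "NG2")
  # granular pattern
  expect_equal(cls(list(granule_count = 8L, fill_fraction = 0.15,
                        mean_dab_od = 0.3, center_void = 0.2)), "NG1")
  # empty centre + peripheral positivity = mitosis
  expect_equal(cls(list(center_void = 0.8, rim_fraction = 0.6,
                        mean_dab_od = 0.5)), "MITOSIS")
  # condensed chromosome-mass branch
  expect_equal(cls(list(fill_fraction = 0.6, area_z = -1.5)), "MITOSIS")
  # fallthrough: weakest positive pattern, flagged as default-assigned
  out <- classify_ng(base)
  expect_equal(out$value, "NG1")
  expect_true(out$default_assigned)
  # phase annotations
  expect_equal(classify_ng(modifyList(base, list(fill_fraction = 0.9)))$cycle_phase,
               "S/G2")
})

test_that("every QC-OK nucleus gets exactly one label and labels respect intensity", {
  res <- small_scored()
  ok <- res$table[res$table$qc_flag == "OK", ]
  expect_true(all(ok$ng_label %in% c("NEGATIVE", "NG1", "NG2", "NG3_4", "MITOSIS")))
  expect_false(any(is.na(ok$ng_label)))

  # monotonicity: scaling all DAB up never demotes NG3_4 to NEGATIVE
  base <- list(mean_dab_od = 0.5, dab_pos_px = 300L, fill_fraction = 0.8,
               granule_count = 2L, node_count = 0L, rim_fraction = 0.2,
               center_void = 0, od_cv = 0.3, area_z = 0)
  expect_equal(classify_ng(base)$value, "NG3_4")
  up <- modifyList(base, list(mean_dab_od = 1.2, fill_fraction = 1.0))
  expect_false(classify_ng(up)$value == "NEGATIVE")
})

test_that("positive-nucleus sampling is deterministic, exhaustive on shortfall, and uniform", {
  tab <- tiny_nucleus_table()
  # shortfall: all rows returned, shortfall recorded
  s <- sample_positive(tab, 1000, seed = 1)
  expect_equal(nrow(s), 3L)
  expect_equal(attr(s, "shortfall"), 997L)

  # identical seeds give identical subsets; RNG state untouched
  big <- data.frame(nucleus_id = 1:5000)
  set.seed(99); before <- runif(1)
  a <- sample_positive(big, 100, seed = 7)
  b <- sample_positive(big, 100, seed = 7)
  expect_identical(a, b)
  set.seed(99); expect_identical(runif(1), before)
  expect_error(sample_positive(big, 0), "n must be")

  # inclusion-frequency uniformity (chi-squared GOF)
  n_pop <- 2000L; n_draw <- 200L; reps <- 400L
  inc <- integer(n_pop)
  for (r in seq_len(reps)) {
    pick <- sample_positive(big[seq_len(n_pop), , drop = FALSE], n_draw,
                            seed = 1000L + r)
    inc[pick$nucleus_id] <- inc[pick$nucleus_id] + 1L
  }
  expected <- reps * n_draw / n_pop
  chi <- sum((inc - expected)^2 / expected)
  p <- pchisq(chi, df = n_pop - 1L, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("proliferation index arithmetic and binomial recovery", {
  mk <- function(n_pos, n_neg) {
    data.frame(qc_flag = c(rep("OK", n_pos), rep("WEAK", n_neg)),
               ng_label = c(rep("NG1", n_pos), rep("NEGATIVE", n_neg)))
  }
  expect_equal(proliferation_index(mk(0, 500)), 0)
  expect_equal(proliferation_index(mk(4, 996)), 0.4)
  expect_true(is.na(proliferation_index(
    data.frame(qc_flag = "EDGE", ng_label = NA))))

  # planted positive fraction recovered within 3 binomial SE on a tile
  res <- small_scored()
  pi_hat <- proliferation_index(res$table)
  planted <- 100 * 35 / 55
  se <- 100 * sqrt((35 / 55) * (20 / 55) / 55)
  expect_lt(abs(pi_hat - planted), 3 * se + 1e-9)
})

test_that("NG pixel scores: totals, additivity, and empty classes", {
  tab <- data.frame(
    tile_id = "t", core_id = rep(c("c1", "c2"), each = 4),
    case_id = "p", nucleus_id = 1:8,
    qc_flag = "OK",
    ng_label = c("NG1", "NG1", "NG3_4", "MITOSIS", "NG1", "NG3_4", "NG3_4", "MITOSIS"),
    dab_pos_px = c(10L, 20L, 300L, 50L, 15L, 280L, 310L, 60L)
  )
  sc <- ng_pixel_scores(tab)
  # brute-force totals
  expect_equal(sc$per_class$total_px[sc$per_class$ng_class == "NG1"], 45)
  expect_equal(sc$per_class$total_px[sc$per_class$ng_class == "NG3_4"], 890)
  expect_equal(sc$per_class$total_px[sc$per_class$ng_class == "NG2"], 0)
  expect_equal(sc$per_class$count[sc$per_class$ng_class == "NG2"], 0)
  expect_equal(sc$per_class$mean_px[sc$per_class$ng_class == "NG2"], 0)

  # additivity: batch split and merge gives identical totals
  sc1 <- ng_pixel_scores(tab[1:4, ])
  sc2 <- ng_pixel_scores(tab[5:8, ])
  expect_equal(sc$per_class$total_px,
               sc1$per_class$total_px + sc2$per_class$total_px)

  # case level = mean over valid cores
  pc <- sc$per_case
  ng34_core_means <- c(300, mean(c(280, 310)))
  expect_equal(pc$mean_px[pc$ng_class == "NG3_4"], mean(ng34_core_means))

  # restricting to valid cores drops the other core's nuclei
  sv <- ng_pixel_scores(tab, valid_cores = "c1")
  expect_equal(sv$per_case$count[sv$per_case$ng_class == "NG3_4"], 1L)
})
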