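test_that("Spearman matches a rank-then-Pearson oracle and bands correctly", {
  # perfect monotone map
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  r <- spearman_with_category(x, exp(x))
  expect_equal(r$rho, 1.0)
  expect_equal(r$category, "very strong")

  # brute-force average-rank oracle on random permutations with ties
  set.seed(21)
  avg_rank <- function(v) {
    o <- order(v); rk <- numeric(length(v))
    i <- 1
    sv <- v[o]
    while (i <= length(v)) {
      j <- i
      while (j < length(v) && sv[j + 1] == sv[i]) j <- j + 1
      rk[o[i:j]] <- mean(i:j)
      i <- j + 1
    }
    rk
  }
  for (k in 1:5) {
    a <- sample(round(rnorm(50), 1)); b <- sample(round(rnorm(50), 1))
    oracle <- cor(avg_rank(a), avg_rank(b))   # Pearson on hand-built ranks
    expect_lt(abs(spearman_with_category(a, b)$rho - oracle), 1e-12)
  }

  # categorisation bands as printed, edges to the lower band
  expect_equal(correlation_category(0.65), "moderate")
  expect_equal(correlation_category(0.83), "strong")
  expect_equal(correlation_category(0.30), "very weak")
  expect_equal(correlation_category(0.91), "very strong")
  expect_equal(correlation_category(-0.45), "weak")

  # constant vector -> undefined
  r0 <- spearman_with_category(rep(1, 10), rnorm(10))
  expect_true(is.na(r0$rho))
  expect_equal(r0$category, "undefined")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(5)
  x <- rnorm(40); y <- x + rnorm(40)
  base <- spearman_with_category(x, y)$rho
  expect_equal(spearman_with_category(exp(x), y)$rho, base, tolerance = 1e-12)
  expect_equal(spearman_with_category(x, y^3 + 5 * y)$rho, base, tolerance = 1e-12)
})

test_that("crosstab reproduces cohort-table percentage arithmetic", {
  # age-by-cohort counts of evaluable patients: 180 total
  age <- rbind("lt46" = c(PTC = 59L, PAD = 5L, BDC = 24L),
               "ge46" = c(38L, 34L, 20L))
  ct <- crosstab_tests(age)
  expect_equal(ct$evaluable, 180L)
  expect_equal(ct$percent["lt46", "PTC"], 32.8)
  expect_equal(ct$percent["lt46", "PAD"], 2.8)
  expect_equal(ct$percent["lt46", "BDC"], 13.3)
  expect_equal(ct$percent["ge46", "PTC"], 21.1)
  expect_equal(ct$percent["ge46", "PAD"], 18.9)

  # uniform 2x2 table: zero association
  u <- matrix(5L, 2, 2)
  cu <- crosstab_tests(u)
  expect_equal(cu$chisq_stat, 0, tolerance = 1e-12)
  expect_equal(cu$chisq_p, 1, tolerance = 1e-12)

  expect_error(crosstab_tests(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  expect_warning(crosstab_tests(rbind(c(3L, 4L), c(0L, 0L))), "zero-margin")
})

test_that("Fisher p matches hypergeometric enumeration", {
  # two-sided Fisher p by direct enumeration over the 2x2 tables with the
  # observed margins (probability-ordering rule with the customary
  # (1 + 1e-7) relative slack)
  fisher_enum <- function(m) {
    a <- m[1, 1]; r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
    support <- max(0, c1 - (n - r1)):min(r1, c1)
    probs <- dhyper(support, r1, n - r1, c1)
    obs <- dhyper(a, r1, n - r1, c1)
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  set.seed(33)
  for (k in 1:25) {
    m <- matrix(rpois(4, 6) + 1L, 2, 2)
    expect_lt(abs(crosstab_tests(m)$fisher_p - fisher_enum(m)), 1e-10)
  }
})

test_that("two-way ANOVA with Bonferroni matches closed-form sums of squares", {
  # small balanced two-way layout; factor-A F from hand-computed SS
  score <- c(10, 12, 11, 13,  20, 22, 21, 23,  15, 17, 16, 18,  25, 27, 26, 28)
  A <- rep(rep(c("a1", "a2"), each = 4), 2)
  B <- rep(c("b1", "b2"), each = 8)
  out <- anova_bonferroni(score, A, B)

  gm <- mean(score)
  ssa <- sum(tapply(score, A, function(v) length(v) * (mean(v) - gm)^2))
  ssb <- sum(tapply(score, B, function(v) length(v) * (mean(v) - gm)^2))
  cellm <- tapply(score, interaction(A, B), mean)
  ssab <- 4 * sum((cellm - gm)^2) - ssa - ssb
  sse <- sum((score - ave(score, interaction(A, B)))^2)
  Fa <- (ssa / 1) / (sse / 12)
  expect_lt(abs(out$anova$F[out$anova$term == "groupA"] - Fa), 1e-10)

  # Bonferroni definition: adj = min(1, raw * m)
  m <- nrow(out$pairwise)
  expect_equal(out$pairwise$adj_p, pmin(1, out$pairwise$raw_p * m))
  expect_true(all(out$pairwise$adj_p >= out$pairwise$raw_p))
  expect_true(all(out$pairwise$adj_p <= 1))

  # three identical groups: all adjusted p = 1
  sc3 <- rep(c(1, 2, 3, 4), 3)
  g3 <- rep(c("x", "y", "z"), each = 4)
  b3 <- rep("b", 12)
  out3 <- anova_bonferroni(sc3, g3, b3)
  expect_true(all(out3$pairwise$adj_p == 1))

  expect_error(anova_bonferroni(c(1, 2), c("a", "a"), c("b", "b")), "2 levels")
})

test_that("Cox fit matches a hand-written Newton solver on a tiny dataset", {
  # n = 6, one covariate, no ties: maximise the partial likelihood directly
  d <- data.frame(pfd_months = c(2, 4, 5, 7, 9, 12),
                  event = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
                  x = c(1, 0, 1, 1, 0, 0))
  loglik_grad <- function(beta) {
    ll <- 0; g <- 0; h <- 0
    for (i in which(d$event)) {
      risk <- d$pfd_months >= d$pfd_months[i]
      w <- exp(beta * d$x[risk])
      s0 <- sum(w); s1 <- sum(w * d$x[risk]); s2 <- sum(w * d$x[risk]^2)
      ll <- ll + beta * d$x[i] - log(s0)
      g <- g + d$x[i] - s1 / s0
      h <- h - (s2 / s0 - (s1 / s0)^2)
    }
    list(ll = ll, g = g, h = h)
  }
  beta <- 0
  for (it in 1:50) {
    s <- loglik_grad(beta)
    step <- -s$g / s$h
    beta <- beta + step
    if (abs(step) < 1e-12) break
  }
  fit <- suppressWarnings(cox_fit(d, "x", mode = "univariate"))  # n = 6 by design
  expect_lt(abs(fit$beta - beta), 1e-8)
  expect_equal(fit$hazard_ratio, exp(fit$beta))
  expect_true(fit$ci95_low <= fit$hazard_ratio &
              fit$hazard_ratio <= fit$ci95_high)
})

test_that("Cox estimates are equivariant under covariate rescaling", {
  ch <- generate_cohort(300, effects = c(ng1_px = 0.03), censoring = 0.3,
                        seed = 8L)
  f1 <- cox_fit(ch, "ng1_px", mode = "univariate")
  ch$ng1_scaled <- ch$ng1_px / 10
  f2 <- cox_fit(ch, "ng1_scaled", mode = "univariate")
  expect_equal(f2$beta, f1$beta * 10, tolerance = 1e-8)
  expect_equal(f2$p_value, f1$p_value, tolerance = 1e-8)
})

test_that("Cox warns on few events and rejects constant covariates", {
  ch <- generate_cohort(30, censoring = 0.9, seed = 2L)
  if (sum(ch$event) < 10) {
    expect_warning(cox_fit(ch, "age", mode = "univariate"), "events")
  }
  ch2 <- generate_cohort(50, seed = 3L)
  ch2$flat <- 1
  expect_error(cox_fit(ch2, "flat"), "constant")
})

test_that("progression-free-disease report has the requested shape", {
  ch <- generate_cohort(200, effects = c(ng1_px = 0.04), censoring = 0.3,
                        seed = 4L)
  rep <- pfd_report(ch)
  expect_true(rep$estimable)
  expect_true(all(c("age_gt46", "male", "size_gt2cm", "nodes_pos",
                    "ng1_px", "pi_percent") %in% rep$univariate$covariate))
  expect_true(all(rep$univariate$hazard_ratio > 0, na.rm = TRUE))
  expect_true(all(rep$multivariate$ci95_low <= rep$multivariate$ci95_high,
                  na.rm = TRUE))

  # zero events: not estimable, no crash
  ch0 <- ch; ch0$event <- FALSE
  rep0 <- pfd_report(ch0)
  expect_false(rep0$estimable)
  expect_true(all(rep0$univariate$note == "not estimable"))
})

test_that("a planted NG1 hazard effect is detected with good power", {
  # per-SD log-HR of log(1.5) on the NG1 pixel score
  sd1 <- sd(generate_cohort(2000, seed = 1L)$ng1_px)
  hits <- vapply(1:20, function(r) {
    ch <- generate_cohort(500, effects = c(ng1_px = log(1.5) / sd1),
                          censoring = 0.3, seed = 100L + r)
    rep <- pfd_report(ch, covariates = c("age_gt46", "ng1_px"))
    rep$univariate$p_value[rep$univariate$covariate == "ng1_px"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
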