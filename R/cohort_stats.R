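## Cohort-level statistics: Spearman correlation with its categorisation
## bands, crosstabs with chi-squared/Fisher tests, two-way ANOVA with
## Bonferroni-adjusted pairwise comparisons, and Cox proportional-hazards
## modelling of progression-free disease.

#' Spearman correlation with strength categorisation
#'
#' Rank correlation (average ranks for ties) with the conventional
#' strength bands: |rho| 0-0.30 very weak, 0.31-0.50 weak, 0.51-0.70
#' moderate, 0.71-0.90 strong, 0.91-1.00 very strong. A coefficient
#' falling exactly on a printed band edge is assigned to the lower band
#' (0.30 is "very weak"). Note the bands as printed leave gaps
#' (e.g. 0.30-0.31); intermediate values belong to the lower band.
#'
#' @param x,y paired numeric vectors, n >= 3 after removing missing pairs.
#' @return list: `rho`, `p_value`, `category`, `n`. Constant input gives
#'   `rho = NA` and category `"undefined"`.
#' @export
spearman_with_category <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(rho = NA_real_, p_value = NA_real_,
                category = "undefined", n = length(x)))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  rho <- unname(ct$estimate)
  list(rho = rho, p_value = ct$p.value,
       category = correlation_category(rho), n = length(x))
}

#' @rdname spearman_with_category
#' @param rho a correlation coefficient in \[-1, 1\].
#' @export
correlation_category <- function(rho) {
  a <- abs(rho)
  if (is.na(a)) return("undefined")
  if (a <= 0.30) "very weak"
  else if (a <= 0.50) "weak"
  else if (a <= 0.70) "moderate"
  else if (a <= 0.90) "strong"
  else "very strong"
}

#' Crosstab percentages with chi-squared / Fisher tests
#'
#' Cell percentages are computed against the total of evaluable cases in
#' the table (cell / sum of all cells, as percentages rounded to one
#' decimal, matching clinicopathological summary tables). The chi-squared
#' test is Pearson's without continuity correction; Fisher's exact test is
#' reported for 2x2 tables. Rows or columns whose margin is zero are
#' dropped with a warning before testing.
#'
#' @param counts matrix (or table) of non-negative integer counts;
#'   rows = variable levels, columns = groups.
#' @return list: `percent` (matrix, 1 decimal), `evaluable` (total count),
#'   `chisq_stat`, `chisq_p`, `fisher_p` (`NA` unless 2x2).
#' @export
crosstab_tests <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  evaluable <- sum(counts)
  percent <- round(100 * counts / evaluable, 1)
  keep_r <- rowSums(counts) > 0
  keep_c <- colSums(counts) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping zero-margin rows/columns before testing")
  }
  m <- counts[keep_r, keep_c, drop = FALSE]
  chisq_stat <- chisq_p <- fisher_p <- NA_real_
  if (nrow(m) >= 2L && ncol(m) >= 2L) {
    ct <- suppressWarnings(chisq.test(m, correct = FALSE))
    chisq_stat <- unname(ct$statistic)
    chisq_p <- ct$p.value
    if (all(dim(m) == c(2L, 2L))) fisher_p <- fisher.test(m)$p.value
  }
  list(percent = percent, evaluable = evaluable,
       chisq_stat = chisq_stat, chisq_p = chisq_p, fisher_p = fisher_p)
}

#' Two-way ANOVA with Bonferroni-adjusted pairwise comparisons
#'
#' Fits the two-way layout `score ~ groupA * groupB` (tumour type x NG
#' class on case-level pixel scores) and reports the omnibus F tests plus
#' pairwise comparisons of `groupA` levels within each level of `groupB`
#' (Welch t-tests), Bonferroni-adjusted by multiplying each raw p-value by
#' the total number of comparisons and capping at 1.
#'
#' @param score numeric response.
#' @param groupA,groupB factors (coerced).
#' @return list: `anova` (data.frame of effects: term, df, F, p) and
#'   `pairwise` (data.frame: groupB level, pair, raw_p, adj_p).
#' @export
anova_bonferroni <- function(score, groupA, groupB) {
  groupA <- factor(groupA); groupB <- factor(groupB)
  ok <- is.finite(score)
  score <- score[ok]; groupA <- droplevels(groupA[ok]); groupB <- droplevels(groupB[ok])
  if (nlevels(groupA) < 2L) stop("need at least 2 levels in groupA")
  tab <- table(groupA, groupB)
  if (any(tab < 2L)) stop("every cell needs at least 2 observations")
  fit <- if (nlevels(groupB) >= 2L) {
    aov(score ~ groupA * groupB)
  } else {
    aov(score ~ groupA)            # single stratum: one-way layout
  }
  s <- summary(fit)[[1]]
  terms <- trimws(rownames(s))
  anova_tab <- data.frame(term = terms, df = s$Df, F = s$`F value`,
                          p = s$`Pr(>F)`, stringsAsFactors = FALSE)
  anova_tab <- anova_tab[anova_tab$term != "Residuals", , drop = FALSE]

  pairs_a <- utils::combn(levels(groupA), 2L, simplify = FALSE)
  rows <- list()
  for (lb in levels(groupB)) {
    for (pr in pairs_a) {
      s1 <- score[groupA == pr[1] & groupB == lb]
      s2 <- score[groupA == pr[2] & groupB == lb]
      raw <- if (var(s1) == 0 && var(s2) == 0) {
        if (mean(s1) == mean(s2)) 1 else 0
      } else {
        stats::t.test(s1, s2)$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        groupB = lb, pair = paste(pr, collapse = " vs "), raw_p = raw,
        stringsAsFactors = FALSE)
    }
  }
  pw <- do.call(rbind, rows)
  m <- nrow(pw)
  pw$adj_p <- pmin(1, pw$raw_p * m)
  list(anova = anova_tab, pairwise = pw)
}

#' Cox proportional-hazards fit with tidy output
#'
#' Wraps `survival::coxph` (Efron tie handling) in univariate or
#' multivariate mode and returns per-covariate hazard ratios with Wald 95%
#' confidence intervals and p-values. In univariate mode each covariate is
#' fitted alone; in multivariate mode all are fitted jointly.
#'
#' @param records data.frame with `pfd_months` (follow-up) and `event`
#'   (logical/0-1) columns.
#' @param covariates character vector of covariate column names.
#' @param mode `"univariate"` or `"multivariate"`.
#' @return data.frame: `covariate, term, beta, hazard_ratio, ci95_low,
#'   ci95_high, p_value, n, n_events`, with the model chi-squared and its
#'   p-value as attributes (`model_chisq`, `model_chisq_p`; multivariate
#'   mode only).
#' @export
cox_fit <- function(records, covariates, mode = c("multivariate", "univariate")) {
  mode <- match.arg(mode)
  stopifnot(all(c("pfd_months", "event") %in% names(records)),
            all(covariates %in% names(records)))
  if (sum(records$event) < 10L) {
    warning("fewer than 10 events; estimates may be unstable")
  }
  for (cv in covariates) {
    v <- records[[cv]][is.finite(as.numeric(factor(records[[cv]])))]
    if (length(unique(records[[cv]][!is.na(records[[cv]])])) < 2L) {
      stop("covariate is constant: ", cv)
    }
  }
  tidy_fit <- function(fit, covariate) {
    s <- summary(fit)
    co <- s$coefficients
    ci <- s$conf.int
    data.frame(
      covariate = covariate, term = rownames(co),
      beta = co[, "coef"], hazard_ratio = co[, "exp(coef)"],
      ci95_low = ci[, "lower .95"], ci95_high = ci[, "upper .95"],
      p_value = co[, "Pr(>|z|)"], n = s$n, n_events = s$nevent,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  if (mode == "univariate") {
    out <- do.call(rbind, lapply(covariates, function(cv) {
      f <- stats::as.formula(paste("survival::Surv(pfd_months, event) ~",
                                   paste0("`", cv, "`")))
      fit <- survival::coxph(f, data = records, ties = "efron")
      tidy_fit(fit, cv)
    }))
    return(out)
  }
  f <- stats::as.formula(paste("survival::Surv(pfd_months, event) ~",
                               paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(f, data = records, ties = "efron")
  out <- tidy_fit(fit, "joint")
  out$covariate <- out$term
  sc <- summary(fit)
  attr(out, "model_chisq") <- unname(sc$logtest["test"])
  attr(out, "model_chisq_p") <- unname(sc$logtest["pvalue"])
  out
}

#' Progression-free-disease report
#'
#' Emits the standard univariate + multivariate Cox table for the
#' image-derived NG scores alongside the clinical covariate menu (age,
#' gender, stage, tumour size, lymph nodes, NG1/NG2/NG3_4 pixel scores,
#' proliferation index), using the customary dichotomisations (age at 46
#' years, tumour size at 2 cm, nodes negative vs >= 1). Cohorts with no
#' events yield "not estimable" markers rather than an error.
#'
#' @param cohort data.frame of case records (see [generate_cohort()]).
#' @param covariates which covariates to include; default full menu
#'   (restricted to those present in `cohort`).
#' @param multivariate_adjust covariates forming the joint model; default
#'   all requested.
#' @return list with data.frames `univariate` and `multivariate` (columns
#'   HR, 95% CI, B, P per covariate) and `estimable` flag.
#' @export
pfd_report <- function(cohort, covariates = NULL, multivariate_adjust = NULL) {
  ch <- cohort
  ch$age_gt46 <- as.integer(ch$age > 46)
  if ("sex_male" %in% names(ch)) ch$male <- ch$sex_male
  else if ("sex" %in% names(ch)) ch$male <- as.integer(ch$sex == "male")
  if ("tumor_size" %in% names(ch)) ch$size_gt2cm <- as.integer(ch$tumor_size > 2)
  if ("ln_positive" %in% names(ch)) ch$nodes_pos <- as.integer(ch$ln_positive >= 1)
  if ("stage" %in% names(ch)) ch$stage <- factor(ch$stage)
  menu <- c("age_gt46", "male", "stage", "size_gt2cm", "nodes_pos",
            "ng1_px", "ng2_px", "ng34_px", "pi_percent")
  if (is.null(covariates)) covariates <- menu[menu %in% names(ch)]
  if (is.null(multivariate_adjust)) multivariate_adjust <- covariates
  if (sum(ch$event) == 0L) {
    ne <- data.frame(covariate = covariates, term = covariates,
                     beta = NA_real_, hazard_ratio = NA_real_,
                     ci95_low = NA_real_, ci95_high = NA_real_,
                     p_value = NA_real_, n = nrow(ch), n_events = 0L,
                     note = "not estimable", stringsAsFactors = FALSE)
    return(list(univariate = ne, multivariate = ne, estimable = FALSE))
  }
  uni <- cox_fit(ch, covariates, mode = "univariate")
  multi <- cox_fit(ch, multivariate_adjust, mode = "multivariate")
  list(univariate = uni, multivariate = multi, estimable = TRUE)
}
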