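# Longitudinal biomarker statistics: per-timepoint correlations with
# strength bands, standardized partial multiple regression of clinical
# score on the MRI parameters, and the acute-leakage -> later-%RD
# prediction model whose r^2 is read as predictive power.

CORRELATION_BANDS <- c("very weak to negligible", "weak", "moderate", "strong")
EFFECT_BANDS <- c("none or very weak", "weak", "moderate", "strong")

#' Classify correlation / effect-size strength
#'
#' Band boundaries 0.2 / 0.4 / 0.7 on the absolute value; boundary values
#' are assigned to the upper band (0.2 -> "weak", 0.4 -> "moderate",
#' 0.7 -> "strong").
#'
#' @param value correlation r or effect size r^2 (|value| <= 1).
#' @param scale `"correlation"` or `"effect_size"` (labels differ for the
#'   lowest band).
#' @return band label.
#' @export
classify_strength <- function(value, scale = c("correlation", "effect_size")) {
  scale <- match.arg(scale)
  if (!is.finite(value) || abs(value) > 1)
    stop_bscb("|value| must be <= 1 for strength classification")
  labels <- if (scale == "correlation") CORRELATION_BANDS else EFFECT_BANDS
  labels[findInterval(abs(value), c(0.2, 0.4, 0.7)) + 1L]
}

cohort_slice <- function(table, dpi = NULL, group = NULL) {
  tab <- as.data.frame(table)
  if (!is.null(dpi)) tab <- tab[tab$dpi %in% dpi, , drop = FALSE]
  if (!is.null(group)) tab <- tab[tab$group %in% group, , drop = FALSE]
  tab
}

spearman_rho <- function(x, y) stats::cor(rank(x), rank(y))

# two-sided p for a correlation via the t approximation
cor_p_t <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tval), df = n - 2)
}

# permutation p for Spearman's rho: exact enumeration for n <= 7,
# seeded Monte Carlo (10000 draws) otherwise
spearman_perm_p <- function(x, y, n_mc = 10000L, seed = 1L) {
  n <- length(x)
  obs <- abs(spearman_rho(x, y))
  rx <- rank(x)
  if (n <= 7L) {
    perms <- permutations_all(n)
    stat <- apply(perms, 1, function(p) abs(spearman_rho(rx, rank(y)[p])))
    mean(stat >= obs - 1e-12)
  } else {
    with_seed(seed, {
      stat <- replicate(n_mc, abs(spearman_rho(rx, sample(rank(y)))))
      (sum(stat >= obs - 1e-12) + 1) / (n_mc + 1)
    })
  }
}

permutations_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_all(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Correlation between two cohort variables at a timepoint
#'
#' Spearman (default; average ranks for ties, as clinical scores are
#' heavily tied) or Pearson correlation on pairwise-complete rows, with a
#' two-sided p-value and the strength band of |r|.
#'
#' @param table a `cohort_table` (or conforming data frame).
#' @param x,y variable (column) names.
#' @param dpi timepoint filter; `NULL` pools all rows.
#' @param method `"spearman"` or `"pearson"`.
#' @param group optional group filter.
#' @param p_method `"t"` (t approximation) or `"permutation"`
#'   (exact enumeration for n <= 7, seeded Monte Carlo otherwise;
#'   Spearman only).
#' @return object of class `correlation_result`: `r`, `p`, `n`, `method`,
#'   `band`.
#' @export
correlate <- function(table, x, y, dpi = NULL,
                      method = c("spearman", "pearson"), group = NULL,
                      p_method = c("t", "permutation")) {
  method <- match.arg(method)
  p_method <- match.arg(p_method)
  tab <- cohort_slice(table, dpi, group)
  xv <- tab[[x]]; yv <- tab[[y]]
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 3L) stop_bscb("undefined correlation: fewer than 3 complete pairs")
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    stop_bscb("undefined correlation: zero variance in %s",
              if (stats::sd(xv) == 0) x else y)
  r <- if (method == "spearman") spearman_rho(xv, yv) else stats::cor(xv, yv)
  p <- if (p_method == "permutation") {
    if (method != "spearman")
      stop_bscb("permutation p is implemented for Spearman only")
    spearman_perm_p(xv, yv)
  } else cor_p_t(r, n)
  structure(list(r = r, p = p, n = n, method = method,
                 band = classify_strength(r, "correlation")),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s r = %.3f (p = %.4g, n = %d): %s correlation\n",
              x$method, x$r, x$p, x$n, x$band))
  invisible(x)
}

#' Standardized partial multiple regression
#'
#' All variables are z-scored (sample mean/SD) and the response is fit on
#' the predictors by ordinary least squares; the coefficients are the
#' standardized partial regression coefficients (beta) with two-sided
#' per-coefficient p-values, plus the model r^2 as effect size.  With a
#' single predictor, beta equals the Pearson r.
#'
#' @param table a `cohort_table` (or conforming data frame).
#' @param response response column (default `clinical_score`).
#' @param predictors predictor columns.
#' @param dpi timepoint filter; `NULL` pools all rows.
#' @param group optional group filter.
#' @param max_condition condition-number bound above which the predictor
#'   matrix is declared collinear.
#' @return object of class `regression_result`: `beta`, `p` (per
#'   predictor), `r_squared`, `band`, `n`.
#' @export
standardized_regression <- function(table, response = "clinical_score",
                                    predictors = c("gd_leakage", "pct_fa",
                                                   "pct_ad", "pct_rd"),
                                    dpi = NULL, group = NULL,
                                    max_condition = 1e6) {
  tab <- cohort_slice(table, dpi, group)
  cols <- c(response, predictors)
  dat <- tab[, cols, drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n <= length(predictors) + 1L)
    stop_bscb("need n > number of predictors + 1 (have n = %d)", n)
  sds <- vapply(dat, stats::sd, numeric(1))
  if (any(sds == 0))
    stop_bscb("zero variance in: %s", paste(cols[sds == 0], collapse = ", "))
  z <- as.data.frame(scale(dat))
  X <- as.matrix(z[, predictors, drop = FALSE])
  kap <- kappa(crossprod(X), exact = TRUE)
  if (!is.finite(kap) || kap > max_condition) {
    cm <- abs(stats::cor(X)); diag(cm) <- 0
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    stop_bscb("collinear predictors (condition number %.3g): %s ~ %s",
              kap, predictors[worst[1]], predictors[worst[2]])
  }
  fml <- stats::as.formula(paste(response, "~", paste(predictors, collapse = " + ")))
  fit <- stats::lm(fml, data = z)
  sm <- summary(fit)
  beta <- stats::coef(fit)[predictors]
  pvals <- sm$coefficients[predictors, "Pr(>|t|)"]
  structure(list(beta = beta, p = pvals, r_squared = sm$r.squared,
                 band = classify_strength(sm$r.squared, "effect_size"),
                 n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("standardized multiple regression (n = %d), r^2 = %.3f (%s effect size)\n",
              x$n, x$r_squared, x$band))
  for (nm in names(x$beta))
    cat(sprintf("  beta[%s] = %+.3f (p = %.4g)\n", nm, x$beta[nm], x$p[nm]))
  invisible(x)
}

#' Predictive power of acute Gd leakage for later myelin integrity
#'
#' Simple linear regression of `output` at `output_dpi` on `input` at
#' `input_dpi`, pairing rows within animal; the effect size r^2 of the
#' regression is reported as predictive power.
#'
#' @param table a `cohort_table` (or conforming data frame).
#' @param input_dpi timepoint of the input variable.
#' @param output_dpi timepoint of the output (default `input_dpi + 7`).
#' @param input,output variable names (defaults: `gd_leakage` ->
#'   `pct_rd`).
#' @param group optional group filter.
#' @return object of class `prediction_result`: `slope`, `intercept`,
#'   `r_squared`, `p`, `n`, `band`, `input`, `output`.
#' @export
predictive_power <- function(table, input_dpi, output_dpi = input_dpi + 7,
                             input = "gd_leakage", output = "pct_rd",
                             group = NULL) {
  tin <- cohort_slice(table, input_dpi, group)
  tout <- cohort_slice(table, output_dpi, group)
  m <- merge(tin[, c("animal_id", input)], tout[, c("animal_id", output)],
             by = "animal_id", suffixes = c(".in", ".out"))
  xi <- m[[2]]; yo <- m[[3]]
  ok <- is.finite(xi) & is.finite(yo)
  xi <- xi[ok]; yo <- yo[ok]
  n <- length(xi)
  if (n < 3L) stop_bscb("fewer than 3 paired animals between %d and %d DPI",
                        input_dpi, output_dpi)
  fit <- stats::lm(yo ~ xi)
  sm <- summary(fit)
  structure(list(input = sprintf("%s (%d DPI)", input, input_dpi),
                 output = sprintf("%s (%d DPI)", output, output_dpi),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p = unname(sm$coefficients[2, "Pr(>|t|)"]),
                 n = n,
                 band = classify_strength(sm$r.squared, "effect_size")),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("%s -> %s: r^2 = %.3f (p = %.4g, n = %d): %s predictive power\n",
              x$input, x$output, x$r_squared, x$p, x$n, x$band))
  invisible(x)
}

#' Thin group-comparison reporting utility
#'
#' Mann-Whitney (Wilcoxon rank-sum) on clinical scores per timepoint, or
#' two-way (group x timepoint) ANOVA on an MRI parameter.  A reporting
#' convenience only; not part of the biomarker framework proper.
#'
#' @param table a `cohort_table`.
#' @param variable column to compare.
#' @param groups two group labels.
#' @param test `"mann_whitney"` (per-dpi) or `"anova2"` (group x dpi).
#' @return data frame (mann_whitney) or `anova` table (anova2).
#' @export
group_tests <- function(table, variable = "clinical_score",
                        groups = c("isotype_control", "anti_rgma"),
                        test = c("mann_whitney", "anova2")) {
  test <- match.arg(test)
  tab <- cohort_slice(table, group = groups)
  if (test == "mann_whitney") {
    do.call(rbind, lapply(sort(unique(tab$dpi)), function(d) {
      td <- tab[tab$dpi == d, ]
      wt <- suppressWarnings(
        stats::wilcox.test(td[[variable]] ~ factor(td$group, levels = groups)))
      data.frame(dpi = d, statistic = unname(wt$statistic), p = wt$p.value)
    }))
  } else {
    tab$group <- factor(tab$group, levels = groups)
    tab$dpi <- factor(tab$dpi)
    stats::anova(stats::lm(stats::reformulate(c("group", "dpi", "group:dpi"),
                                              response = variable), data = tab))
  }
}
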