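# Correlation, standardized regression, prediction model, strength bands.

toy_table <- function(x, y, dpi = 7) {
  data.frame(animal_id = sprintf("a%02d", seq_along(x)), group = "isotype_control",
             dpi = dpi, gd_leakage = x, pct_fa = NA, pct_ad = NA, pct_rd = NA,
             clinical_score = y)
}

test_that("Spearman correlation matches the rank-difference oracle", {
  x <- 1:5; y <- c(2, 1, 4, 3, 5)
  tab <- toy_table(x, y)
  cr <- correlate(tab, "gd_leakage", "clinical_score", dpi = 7)
  expect_equal(cr$r, 0.8)
  expect_equal(cr$r, spearman_oracle(x, y))
  expect_equal(cr$n, 5L)
  # and agrees with stats::cor.test
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(cr$r, unname(ct$estimate))
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(4)
  x <- rnorm(30); y <- x + rnorm(30, 0, 0.5)
  r0 <- correlate(toy_table(x, y), "gd_leakage", "clinical_score")$r
  r1 <- correlate(toy_table(exp(x), y), "gd_leakage", "clinical_score")$r
  r2 <- correlate(toy_table(x, y^3 + 5 * y), "gd_leakage", "clinical_score")$r
  expect_equal(r0, r1)
  expect_equal(r0, r2)
  # strictly increasing y = f(x) gives r = 1
  expect_equal(correlate(toy_table(x, exp(x)), "gd_leakage", "clinical_score")$r, 1)
})

test_that("tied data use average ranks and the t-approximate p", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  y <- c(0, 0, 0.5, 1, 1, 2, 2, 3)   # heavy clinical-score ties
  cr <- correlate(toy_table(x, y), "gd_leakage", "clinical_score")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(cr$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(cr$p, ct$p.value, tolerance = 1e-6)
})

test_that("permutation p agrees with enumeration on small samples", {
  x <- 1:6; y <- c(2, 1, 4, 3, 6, 5)
  cr_t <- correlate(toy_table(x, y), "gd_leakage", "clinical_score")
  cr_p <- correlate(toy_table(x, y), "gd_leakage", "clinical_score",
                    p_method = "permutation")
  # brute-force enumeration oracle over all 720 pairings
  perms <- bscbmark:::permutations_all(6)
  obs <- abs(spearman_oracle(x, y))
  stat <- apply(perms, 1, function(p) abs(cor(rank(x), rank(y[p]))))
  expect_equal(cr_p$p, mean(stat >= obs - 1e-12))
  expect_gt(cr_p$p, 0); expect_lte(cr_p$p, 1)
  expect_equal(cr_t$r, cr_p$r)
})

test_that("correlate rejects degenerate inputs", {
  expect_error(correlate(toy_table(1:2, 1:2), "gd_leakage", "clinical_score"),
               "fewer than 3")
  expect_error(correlate(toy_table(rep(1, 5), 1:5), "gd_leakage", "clinical_score"),
               "zero variance")
})

test_that("strength bands assign boundaries upward", {
  expect_equal(classify_strength(0.831), "strong")
  expect_equal(classify_strength(0), "very weak to negligible")
  expect_equal(classify_strength(-0.549), "moderate")
  expect_equal(classify_strength(0.2), "weak")
  expect_equal(classify_strength(0.4), "moderate")
  expect_equal(classify_strength(0.7), "strong")
  expect_equal(classify_strength(0.1, "effect_size"), "none or very weak")
  expect_error(classify_strength(1.2), "<= 1")
})

test_that("single-predictor standardized beta equals the Pearson r", {
  set.seed(7)
  x <- rnorm(40); y <- 0.6 * x + rnorm(40, 0, 0.8)
  tab <- toy_table(x, y)
  reg <- standardized_regression(tab, response = "clinical_score",
                                 predictors = "gd_leakage")
  cr <- correlate(tab, "gd_leakage", "clinical_score", method = "pearson")
  expect_equal(unname(reg$beta), cr$r, tolerance = 1e-12)
  expect_equal(reg$r_squared, cr$r^2, tolerance = 1e-12)
})

test_that("orthogonal predictors give betas equal to their simple correlations", {
  # exactly orthogonal design via QR
  set.seed(8)
  raw <- matrix(rnorm(60 * 2), 60, 2)
  q <- qr.Q(qr(cbind(1, raw)))[, 2:3]
  x1 <- q[, 1]; x2 <- q[, 2]
  y <- 1.5 * x1 - 0.8 * x2 + rnorm(60, 0, 0.3)
  tab <- data.frame(animal_id = sprintf("a%d", 1:60), group = "g", dpi = 7,
                    gd_leakage = x1, pct_fa = x2, clinical_score = y)
  reg <- standardized_regression(tab, predictors = c("gd_leakage", "pct_fa"))
  r1 <- cor(x1, y); r2 <- cor(x2, y)
  expect_equal(unname(reg$beta["gd_leakage"]), r1, tolerance = 1e-10)
  expect_equal(unname(reg$beta["pct_fa"]), r2, tolerance = 1e-10)
})

test_that("near-exact fits drive the matching beta to 1", {
  set.seed(9)
  x1 <- rnorm(50); x2 <- rnorm(50)
  y <- x1 + rnorm(50, 0, 1e-8)
  tab <- data.frame(animal_id = sprintf("a%d", 1:50), group = "g", dpi = 7,
                    gd_leakage = x1, pct_fa = x2, clinical_score = y)
  reg <- standardized_regression(tab, predictors = c("gd_leakage", "pct_fa"))
  expect_equal(unname(reg$beta["gd_leakage"]), 1, tolerance = 1e-6)
  expect_lt(abs(reg$beta["pct_fa"]), 1e-6)
})

test_that("collinear predictors are rejected with the offending pair named", {
  set.seed(10)
  x <- rnorm(30)
  tab <- data.frame(animal_id = sprintf("a%d", 1:30), group = "g", dpi = 7,
                    gd_leakage = x, pct_fa = 2 * x + 1e-12 * rnorm(30),
                    clinical_score = rnorm(30))
  err <- tryCatch(standardized_regression(tab, predictors = c("gd_leakage", "pct_fa")),
                  error = conditionMessage)
  expect_match(err, "collinear")
  expect_match(err, "gd_leakage")
  expect_match(err, "pct_fa")
})

test_that("multi-predictor beta recovery is unbiased within Monte-Carlo error", {
  # population beta = (0.7, 0, 0, -0.2) with independent predictors
  true_beta <- c(0.7, 0, 0, -0.2)
  sigma <- sqrt(1 - sum(true_beta^2))
  n <- 500
  betas <- vapply(1:100, function(seed) {
    set.seed(seed)
    X <- matrix(rnorm(n * 4), n, 4)
    y <- drop(X %*% true_beta) + rnorm(n, 0, sigma)
    tab <- data.frame(animal_id = seq_len(n), group = "g", dpi = 7,
                      gd_leakage = X[, 1], pct_fa = X[, 2], pct_ad = X[, 3],
                      pct_rd = X[, 4], clinical_score = y)
    standardized_regression(tab)$beta
  }, numeric(4))
  se_mean <- (sigma / sqrt(n)) / sqrt(100)
  for (j in 1:4)
    expect_lt(abs(mean(betas[j, ]) - true_beta[j]), 4 * se_mean)
})

test_that("predictive power is the squared correlation of paired animals", {
  set.seed(11)
  x <- rnorm(20)
  tab <- rbind(toy_table(x, 0, dpi = 7), toy_table(rnorm(20), 0, dpi = 14))
  tab$pct_rd <- c(rep(NA, 20), 3 - 2 * x)  # exact affine output at 14 DPI
  pr <- suppressWarnings(predictive_power(tab, input_dpi = 7))  # exact fit
  expect_equal(pr$r_squared, 1, tolerance = 1e-12)
  expect_equal(pr$slope, -2, tolerance = 1e-9)
  # cross-operation consistency on noisy data
  tab$pct_rd[21:40] <- 3 - 2 * x + rnorm(20)
  pr2 <- predictive_power(tab, input_dpi = 7)
  r <- cor(x, tab$pct_rd[21:40])
  expect_equal(pr2$r_squared, r^2, tolerance = 1e-12)
  expect_equal(pr2$n, 20L)
})

test_that("shuffled pairings drive mean predictive r^2 to 1/(n-1)", {
  set.seed(12)
  n <- 20
  x <- rnorm(n); y <- 2 * x + rnorm(n, 0, 0.5)
  r2s <- replicate(2000, cor(x, sample(y))^2)
  expect_lt(abs(mean(r2s) - 1 / (n - 1)), 3 * sd(r2s) / sqrt(2000))
  # and the same null expectation through predictive_power
  tab <- rbind(toy_table(x, 0, dpi = 7), toy_table(rnorm(n), 0, dpi = 14))
  r2p <- replicate(300, {
    tab$pct_rd <- c(rep(NA, n), sample(y))
    predictive_power(tab, input_dpi = 7)$r_squared
  })
  expect_lt(abs(mean(r2p) - 1 / (n - 1)), 4 * sd(r2p) / sqrt(300))
})

test_that("group test utility reports Mann-Whitney and two-way ANOVA", {
  coh <- rbind(generate_cohort(eae_cohort_preset(n_animals = 9, seed = 1))$table,
               generate_cohort(eae_cohort_preset(n_animals = 10, seed = 2,
                                                 group = "anti_rgma"))$table)
  mw <- group_tests(coh, "clinical_score")
  expect_equal(nrow(mw), 3L)
  expect_true(all(mw$p >= 0 & mw$p <= 1))
  av <- group_tests(coh, "pct_fa", test = "anova2")
  expect_true("group:dpi" %in% rownames(av))
})
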