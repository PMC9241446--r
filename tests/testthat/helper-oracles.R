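# Shared oracles and fixture builders for the test suite.

# Closed-form FA oracle, written against the pairwise-difference identity
# FA = sqrt(1/2) * sqrt((l1-l2)^2 + (l2-l3)^2 + (l3-l1)^2) / sqrt(l1^2+l2^2+l3^2),
# algebraically equivalent to (but coded independently of) the
# mean-dispersion form used in the package.
fa_oracle <- function(l1, l2, l3) {
  sqrt(0.5) * sqrt((l1 - l2)^2 + (l2 - l3)^2 + (l3 - l1)^2) /
    sqrt(l1^2 + l2^2 + l3^2)
}

# Spearman rank-difference oracle for untied data: 1 - 6*sum(d^2)/(n(n^2-1))
spearman_oracle <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# OLS slope oracle via explicit normal equations
ols_slope_oracle <- function(t, e) {
  sum((t - mean(t)) * (e - mean(e))) / sum((t - mean(t))^2)
}

# Monte-Carlo oracle for the finite-sample expectation of the squared
# sample correlation of a bivariate normal with correlation rho; used as
# the reference for preset-cohort r^2 recovery (E[r^2] carries an O(1/n)
# bias relative to rho^2, which this oracle shares).
r2_expectation_oracle <- function(rho, n, reps = 2000, seed = 99L) {
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- .Random.seed
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  mean(replicate(reps, {
    s <- rnorm(n)
    x <- rho_split(rho)$a * s + rho_split(rho)$b * rnorm(n)
    y <- rho_split(rho)$a * s + rho_split(rho)$b * rnorm(n)
    cor(x, y)^2
  }))
}
# split a correlation rho = a^2 into factor loading a and noise b, unit variance
rho_split <- function(rho) {
  a <- sqrt(abs(rho))
  list(a = a, b = sqrt(1 - a^2))
}

# independent pixel-center distance grid (distance from image center)
pixel_grid_oracle <- function(shape) {
  cy <- (shape[1] + 1) / 2; cx <- (shape[2] + 1) / 2
  outer(seq_len(shape[1]), seq_len(shape[2]),
        function(y, x) sqrt((y - cy)^2 + (x - cx)^2))
}

# single-vessel phantom used across ihc tests
annulus_phantom <- function(r_in = 12, r_out = 20, noise = 0.02, seed = 1L,
                            shape = c(96L, 96L)) {
  generate_vessel_image(vessel_phantom_spec(
    image_shape = shape,
    vessels = list(list(center = (shape + 1) / 2, inner_radius = r_in,
                        outer_radius = r_out)),
    noise_sigma = noise, seed = seed))
}

# python interpreter shared by the I/O oracle tests (same conda image)
python_bin <- Sys.which("python")
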