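#' bscbmark: imaging biomarkers of blood-spinal-cord-barrier disruption
#'
#' Quantitative analysis of longitudinal preclinical MRI (DTI + DCE-MRI)
#' and fluorescence vessel pathology in targeted EAE, together with seeded
#' synthetic phantoms/cohorts that make every stage testable without data
#' downloads.  See the package vignette for the underlying models.
#'
#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-stage child seed from a master seed; keeps results < 2^31.
child_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, dwi = 211L, dce = 307L, vessel = 401L,
               cohort = 503L, pipeline = 601L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

stop_bscb <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_bscb("`%s` must be a single finite number", name)
  if (strict_lower && x <= lower) stop_bscb("`%s` must be > %g", name, lower)
  if (!strict_lower && x < lower) stop_bscb("`%s` must be >= %g", name, lower)
  if (strict_upper && x >= upper) stop_bscb("`%s` must be < %g", name, upper)
  if (!strict_upper && x > upper) stop_bscb("`%s` must be <= %g", name, upper)
  x
}

# Pixel-center coordinate grids for an H x W image (row = y, col = x).
pixel_grid <- function(shape, center = NULL) {
  h <- shape[1]; w <- shape[2]
  if (is.null(center)) center <- c((h + 1) / 2, (w + 1) / 2)
  yy <- matrix(seq_len(h), h, w) - center[1]
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - center[2]
  list(y = yy, x = xx, r = sqrt(yy^2 + xx^2))
}
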