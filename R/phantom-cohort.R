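# Longitudinal cohort generator: one latent per-animal disease severity
# drives gadolinium leakage, DTI area scores, and the ordinal clinical
# score through a single-factor model,
#   obs[v, t] = mean[v, t] + scale[v, t] * (loading[v, t] * s + noise[v, t] * e),
# with s ~ N(severity_location, severity_scale^2) drawn once per animal and
# e ~ N(0, 1) fresh per observation.  When loading^2 + noise^2 = 1 and
# var(s) = 1, `loading` is the population correlation between the (latent)
# observation and severity, so the population correlation between any two
# observed variables is the product of their loadings -- which is how the
# EAE preset encodes its target correlation structure analytically.

COHORT_VARIABLES <- c("gd_leakage", "pct_fa", "pct_ad", "pct_rd", "clinical_score")
CLINICAL_LEVELS <- c(0, 0.5, 1, 1.5, 2, 3, 4, 5)

#' Cohort specification
#'
#' @param n_animals number of animals (>= 3).
#' @param timepoints days post cytokine injection (DPI).
#' @param severity_distribution `c(location, scale)` of the latent
#'   per-animal severity.
#' @param coupling named list mapping each observed variable
#'   (`gd_leakage`, `pct_fa`, `pct_ad`, `pct_rd`, `clinical_score`) to a
#'   list with `loading`, `noise`, and (except clinical_score) `mean` and
#'   `scale`; each entry a scalar or one value per timepoint.
#' @param score_cutpoints strictly increasing thresholds mapping the latent
#'   clinical variable onto the ordinal scale
#'   \{0, 0.5, 1, 1.5, 2, 3, 4, 5\} (7 cutpoints).
#' @param group group label for all animals (cohorts can be concatenated).
#' @param seed integer RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_animals = 10L,
                        timepoints = c(7L, 14L, 21L),
                        severity_distribution = c(0, 1),
                        coupling = default_coupling(),
                        score_cutpoints = c(-1.5, -0.8, -0.25, 0.35, 0.9, 2.6, 3.4),
                        group = "isotype_control",
                        seed = 1L) {
  if (n_animals < 3L) stop_bscb("n_animals must be >= 3")
  if (any(diff(score_cutpoints) <= 0))
    stop_bscb("score_cutpoints must be strictly increasing")
  if (length(score_cutpoints) != length(CLINICAL_LEVELS) - 1L)
    stop_bscb("need %d cutpoints for the %d-level clinical scale",
              length(CLINICAL_LEVELS) - 1L, length(CLINICAL_LEVELS))
  missing_vars <- setdiff(COHORT_VARIABLES, names(coupling))
  if (length(missing_vars))
    stop_bscb("coupling missing variables: %s", paste(missing_vars, collapse = ", "))
  nt <- length(timepoints)
  coupling <- lapply(coupling, function(cp) {
    cp$loading <- rep_len(cp$loading, nt)
    cp$noise <- rep_len(cp$noise, nt)
    cp$mean <- rep_len(if (is.null(cp$mean)) 0 else cp$mean, nt)
    cp$scale <- rep_len(if (is.null(cp$scale)) 1 else cp$scale, nt)
    if (any(cp$noise < 0) || any(cp$scale <= 0))
      stop_bscb("coupling noise must be >= 0 and scale > 0")
    cp
  })
  group <- match.arg(group, c("naive", "isotype_control", "anti_rgma"))
  structure(list(n_animals = as.integer(n_animals),
                 timepoints = as.integer(timepoints),
                 severity_distribution = severity_distribution,
                 coupling = coupling, score_cutpoints = score_cutpoints,
                 group = group, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default (weakly coupled) cohort coupling
#'
#' A neutral coupling for API examples; for the documented literature-informed
#' correlation structure use [eae_coupling_preset()].
#' @return named list usable as `coupling` in [cohort_spec()].
#' @export
default_coupling <- function() {
  list(gd_leakage = list(loading = 0.8, noise = 0.6, mean = 0.4, scale = 0.15),
       pct_fa = list(loading = -0.6, noise = 0.8, mean = 70, scale = 10),
       pct_ad = list(loading = -0.6, noise = 0.8, mean = 70, scale = 10),
       pct_rd = list(loading = -0.7, noise = sqrt(1 - 0.49), mean = 70, scale = 12),
       clinical_score = list(loading = 0.9, noise = sqrt(1 - 0.81)))
}

#' Literature-informed EAE coupling preset
#'
#' Loadings are chosen so the analytic population correlations reproduce
#' the observed cross-timepoint structure of a targeted-EAE cohort:
#' corr(gd_leakage at 7 DPI, pct_rd at 14 DPI) = -0.699 (population
#' r^2 = 0.489) and corr(gd_leakage at 14 DPI, pct_rd at 21 DPI) = -0.877
#' (r^2 = 0.769).  With unit-variance severity and loading^2 + noise^2 = 1,
#' corr(X, Y) = loading_X * loading_Y.  Per-timepoint means encode the
#' typical disease course: Gd leakage peaking acutely then decaying,
#' %RD-negative (and %FA/%AD) area declining as demyelination progresses.
#'
#' @return named list usable as `coupling` in [cohort_spec()].
#' @export
eae_coupling_preset <- function() {
  ld <- function(l) list(loading = l, noise = sqrt(1 - l^2))
  gd <- ld(c(sqrt(0.699), sqrt(0.877), 0.80))
  gd$mean <- c(0.45, 0.27, 0.18); gd$scale <- c(0.15, 0.09, 0.06)
  fa <- ld(c(-0.50, -0.60, -0.60)); fa$mean <- c(80, 70, 60); fa$scale <- 10
  adc <- ld(c(-0.40, -0.50, -0.50)); adc$mean <- c(80, 72, 65); adc$scale <- 10
  rd <- ld(c(-0.60, -sqrt(0.699), -sqrt(0.877)))
  rd$mean <- c(85, 70, 55); rd$scale <- c(8, 12, 15)
  list(gd_leakage = gd, pct_fa = fa, pct_ad = adc, pct_rd = rd,
       clinical_score = ld(0.9))
}

#' Literature-informed EAE cohort preset
#'
#' Convenience wrapper: [cohort_spec()] with [eae_coupling_preset()].
#' @inheritParams cohort_spec
#' @export
eae_cohort_preset <- function(n_animals = 10L, seed = 1L,
                              group = "isotype_control") {
  cohort_spec(n_animals = n_animals, coupling = eae_coupling_preset(),
              group = group, seed = seed)
}

#' Analytic population correlation implied by a cohort spec
#'
#' Computes corr(x at dpi_x, y at dpi_y) from the single-factor model:
#' corr = (a_x * a_y * var(s)) / sqrt((a_x^2 var(s) + n_x^2)(a_y^2 var(s) + n_y^2)).
#' For `clinical_score` the value refers to the latent (pre-cutpoint)
#' variable.
#'
#' @param spec a [cohort_spec()].
#' @param x,y variable names.
#' @param dpi_x,dpi_y timepoints.
#' @return population Pearson correlation.
#' @export
population_correlation <- function(spec, x, dpi_x, y, dpi_y) {
  vs <- spec$severity_distribution[2]^2
  ix <- match(dpi_x, spec$timepoints); iy <- match(dpi_y, spec$timepoints)
  if (is.na(ix) || is.na(iy)) stop_bscb("dpi not in spec timepoints")
  cx <- spec$coupling[[x]]; cy <- spec$coupling[[y]]
  ax <- cx$loading[ix]; ay <- cy$loading[iy]
  (ax * ay * vs) / sqrt((ax^2 * vs + cx$noise[ix]^2) * (ay^2 * vs + cy$noise[iy]^2))
}

#' Generate a longitudinal cohort table
#'
#' Draws one latent severity per animal, then per timepoint generates the
#' MRI variables and cutpoints the latent clinical variable onto the
#' ordinal 0-5 scale.
#'
#' @param spec a [cohort_spec()].
#' @return list with `table` (a `cohort_table` data frame with columns
#'   animal_id, group, dpi, gd_leakage, pct_fa, pct_ad, pct_rd,
#'   clinical_score) and `severity` (the latent draws).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  nt <- length(spec$timepoints)
  out <- with_seed(spec$seed, {
    s <- stats::rnorm(spec$n_animals, spec$severity_distribution[1],
                      spec$severity_distribution[2])
    rows <- vector("list", nt)
    for (ti in seq_len(nt)) {
      vals <- lapply(COHORT_VARIABLES, function(v) {
        cp <- spec$coupling[[v]]
        latent <- cp$loading[ti] * s +
          cp$noise[ti] * stats::rnorm(spec$n_animals)
        if (v == "clinical_score") {
          CLINICAL_LEVELS[findInterval(latent, spec$score_cutpoints) + 1L]
        } else {
          cp$mean[ti] + cp$scale[ti] * latent
        }
      })
      names(vals) <- COHORT_VARIABLES
      rows[[ti]] <- data.frame(
        animal_id = sprintf("%s_%02d", spec$group, seq_len(spec$n_animals)),
        group = spec$group, dpi = spec$timepoints[ti], vals,
        stringsAsFactors = FALSE)
    }
    list(severity = s, table = do.call(rbind, rows))
  })
  tab <- out$table[order(out$table$animal_id, out$table$dpi), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("cohort_table", "data.frame")
  list(table = tab, severity = out$severity)
}

#' Read / write cohort tables as CSV
#'
#' The schema is `animal_id, group, dpi, gd_leakage, pct_fa, pct_ad,
#' pct_rd, clinical_score`; clinical scores must lie on the ordinal scale
#' \{0, 0.5, 1, 1.5, 2, 3, 4, 5\} (missing values allowed).
#'
#' @param table a `cohort_table` (or conforming data frame).
#' @param path CSV file path.
#' @return `read_cohort` returns a validated `cohort_table`;
#'   `write_cohort` returns `path` invisibly.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_cohort_table(tab)
}

#' @rdname write_cohort
#' @export
as_cohort_table <- function(table) {
  needed <- c("animal_id", "group", "dpi", COHORT_VARIABLES)
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols))
    stop_bscb("cohort table missing columns: %s", paste(missing_cols, collapse = ", "))
  bad <- !is.na(table$clinical_score) &
    !(table$clinical_score %in% CLINICAL_LEVELS)
  if (any(bad))
    stop_bscb("clinical_score values off the 0-5 ordinal scale: %s",
              paste(unique(table$clinical_score[bad]), collapse = ", "))
  if (anyDuplicated(table[, c("animal_id", "dpi")]))
    stop_bscb("cohort table must have one row per animal x dpi")
  class(table) <- c("cohort_table", "data.frame")
  table
}
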