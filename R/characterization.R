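#' Synthetic unconfined-compression stress-strain series
#'
#' Stand-in generator for compression-test recordings of a linearly elastic
#' specimen: stress_i = E_true * strain_i * (1 + eps_i) with multiplicative
#' Gaussian noise eps_i ~ N(0, noise_sd_rel). Strain runs linearly from just
#' above zero to `max_strain` (compression protocols for these scaffolds
#' reach ~13% displacement).
#'
#' @param E_true true elastic modulus, Pa (> 0).
#' @param max_strain final strain (0 < max_strain <= 0.15).
#' @param n_points number of samples (>= 3).
#' @param noise_sd_rel relative noise standard deviation (>= 0).
#' @param seed integer RNG seed; the series is deterministic per seed.
#' @return A `stress_strain` object: `strain` (dimensionless, strictly
#'   increasing), `stress` (Pa), `provenance`.
#' @export
synth_stress_strain <- function(E_true, max_strain = 0.13, n_points = 100,
                                noise_sd_rel = 0.02, seed = 1) {
  if (E_true <= 0) stop("`E_true` must be positive")
  if (!(max_strain > 0 && max_strain <= 0.15))
    stop("`max_strain` must be in (0, 0.15]")
  if (n_points < 3) stop("`n_points` must be >= 3")
  if (noise_sd_rel < 0) stop("`noise_sd_rel` must be >= 0")
  strain <- seq(max_strain / n_points, max_strain, length.out = n_points)
  eps <- with_seed(seed, rnorm(n_points, 0, noise_sd_rel))
  structure(
    list(strain = strain, stress = E_true * strain * (1 + eps),
         provenance = list(type = "synthetic", E_true = E_true,
                           noise_sd_rel = noise_sd_rel, seed = seed)),
    class = "stress_strain")
}

#' Stress-strain series from measured data
#'
#' @param strain strictly increasing strain values (<= 0.15).
#' @param stress stresses, Pa, same length.
#' @return A `stress_strain` object.
#' @export
stress_strain <- function(strain, stress) {
  if (length(strain) != length(stress)) stop("unequal lengths")
  if (any(diff(strain) <= 0)) stop("`strain` must be strictly increasing")
  if (any(strain > 0.15)) stop("strain exceeds the supported 0-0.15 range")
  structure(list(strain = strain, stress = stress,
                 provenance = list(type = "measured")),
            class = "stress_strain")
}

#' Elastic modulus by strain-stress linear regression
#'
#' Ordinary-least-squares slope of stress on strain over a strain window,
#' the standard evaluation of unconfined compression tests on soft porous
#' scaffolds. The full loading range is used by default.
#'
#' @param series a `stress_strain` object.
#' @param strain_window `c(lo, hi)` strain window; points with
#'   lo <= strain <= hi enter the fit (>= 3 required).
#' @return A list: `E` (Pa), `se` (standard error of the slope, Pa),
#'   `n` points used, `window`.
#' @examples
#' s <- synth_stress_strain(30.5e3, noise_sd_rel = 0, seed = 1)
#' elastic_modulus(s)$E  # 30500
#' @export
elastic_modulus <- function(series, strain_window = NULL) {
  if (!inherits(series, "stress_strain")) stop("expected a `stress_strain`")
  w <- if (is.null(strain_window)) range(series$strain) else strain_window
  sel <- series$strain >= w[1] & series$strain <= w[2]
  if (sum(sel) < 3) stop("fewer than 3 points in the strain window")
  x <- series$strain[sel]
  y <- series$stress[sel]
  if (var(x) == 0) stop("zero strain variance in the window")
  fit <- lm(y ~ x)
  # suppress the "essentially perfect fit" note on noiseless input
  sm <- suppressWarnings(summary(fit))
  list(E = unname(coef(fit)[2]),
       se = unname(sm$coefficients["x", "Std. Error"]),
       n = sum(sel), window = w)
}

#' EDS surface composition
#'
#' Element weight percentages from energy-dispersive X-ray spectroscopy of
#' the scaffold surface.
#'
#' @param ... named element weight percentages (e.g. `Ca = 0.47, P = 0.6`),
#'   all >= 0, summing to at most 100.
#' @return An `eds_composition` named numeric vector.
#' @export
eds_composition <- function(...) {
  w <- c(...)
  if (is.null(names(w)) || any(names(w) == ""))
    stop("all weights must be named by element")
  if (any(w < 0)) stop("weights must be >= 0")
  if (sum(w) > 100) stop("weights sum to more than 100%")
  structure(w, class = "eds_composition")
}

#' Calcium-to-phosphorus weight ratio
#'
#' Ca wt% / P wt% of an EDS composition. The ratio is by weight, not molar
#' (the convention under which residual mineral in partially decalcified
#' scaffolds is reported).
#'
#' @param comp an [eds_composition()] containing `Ca` and `P`.
#' @return Dimensionless weight ratio.
#' @examples
#' ca_p_ratio(eds_composition(Ca = 0.47, P = 0.6))  # 0.783
#' @export
ca_p_ratio <- function(comp) {
  if (!all(c("Ca", "P") %in% names(comp)))
    stop("composition must contain Ca and P")
  if (comp[["P"]] <= 0) stop("P weight must be positive")
  unname(comp[["Ca"]] / comp[["P"]])
}
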