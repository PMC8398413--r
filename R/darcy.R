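#' Fluid, geometry and flow operating-point containers
#'
#' Small validated records holding the bioreactor operating point in SI
#' units. The `paper_*` constructors return the presets of the modeled
#' perfusion system: cell culture medium treated as water at 37 °C
#' (η = 0.6913 mPa·s, ρ = 993 kg/m³), a cartridge of cross-sectional area
#' 78.5 mm² (10.4 mm silicone housing holding three 3 mm scaffolds from a
#' 10 mm punch, total porous length L = 9 mm) and a continuous flow of
#' 1.7 mL/min.
#'
#' @param viscosity dynamic viscosity, Pa·s.
#' @param density density, kg/m³.
#' @return `fluid_props`, `cartridge_geometry` or `flow_condition` objects.
#' @name operating-point
NULL

#' @rdname operating-point
#' @export
fluid_props <- function(viscosity, density = 993) {
  if (viscosity <= 0) stop("`viscosity` must be positive")
  if (density <= 0) stop("`density` must be positive")
  structure(list(viscosity = viscosity, density = density),
            class = "fluid_props")
}

#' @rdname operating-point
#' @export
paper_fluid <- function() fluid_props(viscosity = 6.913e-4, density = 993)

#' @rdname operating-point
#' @param scaffold_length porous plug length L, m.
#' @param cartridge_area cartridge cross-sectional area A, m². Defaults to
#'   `pi/4 * cartridge_diameter^2` when omitted.
#' @param cartridge_diameter cartridge inner diameter, m.
#' @param tubing_diameter tubing inner diameter, m.
#' @export
cartridge_geometry <- function(scaffold_length, cartridge_area = NULL,
                               cartridge_diameter = 10.4e-3,
                               tubing_diameter = 3.2e-3) {
  if (is.null(cartridge_area))
    cartridge_area <- pi / 4 * cartridge_diameter^2
  if (scaffold_length <= 0 || cartridge_area <= 0)
    stop("`scaffold_length` and `cartridge_area` must be positive")
  structure(list(scaffold_length = scaffold_length,
                 cartridge_area = cartridge_area,
                 cartridge_diameter = cartridge_diameter,
                 tubing_diameter = tubing_diameter),
            class = "cartridge_geometry")
}

#' @rdname operating-point
#' @export
paper_cartridge <- function()
  cartridge_geometry(scaffold_length = 9e-3, cartridge_area = 78.5e-6,
                     cartridge_diameter = 10.4e-3, tubing_diameter = 3.2e-3)

#' @rdname operating-point
#' @param flow_rate volumetric flow rate.
#' @param units `"m3/s"` or `"mL/min"` (1 mL/min = 1/6 × 10⁻⁷ m³/s).
#' @export
flow_condition <- function(flow_rate, units = c("m3/s", "mL/min")) {
  units <- match.arg(units)
  Q <- if (units == "mL/min") flow_rate * 1e-6 / 60 else flow_rate
  if (Q < 0) stop("`flow_rate` must be non-negative")
  structure(list(Q = Q), class = "flow_condition")
}

#' @rdname operating-point
#' @export
paper_flow <- function() flow_condition(1.7, units = "mL/min")

#' Darcy-law permeability from measured differential pressure
#'
#' For a porous plug of length L and cross-section A perfused at flow rate Q
#' by a fluid of viscosity η, Darcy's law gives the intrinsic permeability
#' k = Q η L / (A Δp). Several Δp measurements (e.g. one per donor scaffold)
#' yield per-sample permeabilities and their mean ± SD.
#'
#' @param flow a [flow_condition()].
#' @param fluid a [fluid_props()].
#' @param geom a [cartridge_geometry()].
#' @param dp measured differential pressure(s), Pa (all > 0).
#' @return A `permeability_estimate`: `k` (per-sample, m²), `mean`, `sd`
#'   (`NA` for a single sample), `dp`.
#' @examples
#' permeability_from_pressure(paper_flow(), paper_fluid(), paper_cartridge(),
#'                            dp = 338.2)
#' @export
permeability_from_pressure <- function(flow, fluid, geom, dp) {
  if (length(dp) < 1 || any(!is.finite(dp)) || any(dp <= 0))
    stop("all `dp` values must be positive and finite")
  k <- flow$Q * fluid$viscosity * geom$scaffold_length /
    (geom$cartridge_area * dp)
  structure(list(k = k, mean = mean(k),
                 sd = if (length(k) > 1) sd(k) else NA_real_,
                 dp = dp),
            class = "permeability_estimate")
}

#' @export
print.permeability_estimate <- function(x, ...) {
  cat(sprintf("<permeability_estimate> k = %.3g", x$mean))
  if (!is.na(x$sd)) cat(sprintf(" +/- %.3g", x$sd))
  cat(sprintf(" m2 (n = %d)\n", length(x$k)))
  invisible(x)
}

#' Differential pressure implied by a permeability
#'
#' Algebraic inverse of [permeability_from_pressure()]:
#' Δp = Q η L / (A k). `Q = 0` gives Δp = 0.
#'
#' @inheritParams permeability_from_pressure
#' @param k permeability, m² (> 0).
#' @return Pressure drop in Pa.
#' @export
pressure_from_permeability <- function(flow, fluid, geom, k) {
  if (any(!is.finite(k)) || any(k <= 0)) stop("`k` must be positive")
  flow$Q * fluid$viscosity * geom$scaffold_length /
    (geom$cartridge_area * k)
}

#' Reduced-order axial profile of the bioreactor circuit
#'
#' One-dimensional plug-flow model of the perfusion line: superficial
#' velocity Q/A(z) in each segment (tubing, open cartridge, scaffold plug),
#' interstitial velocity (Q/A)/φ inside the porous plug, and outlet-gauge
#' pressure that is constant outside the plug and drops linearly across it
#' by the Darcy Δp. At creeping-flow Reynolds numbers with a uniform porous
#' plug the cross-section-averaged solution is one-dimensional, which is all
#' this model resolves; viscous tubing losses are neglected.
#'
#' @inheritParams permeability_from_pressure
#' @param k scaffold permeability, m².
#' @param porosity scaffold porosity, in (0, 1).
#' @param n_stations number of axial stations.
#' @param tubing_length length of each tubing stub, m.
#' @param cartridge_buffer open cartridge length on each side of the plug, m.
#' @return Data frame with `position` (m, from circuit inlet), `segment`,
#'   `area` (m²), `velocity` (superficial, m/s), `velocity_interstitial`
#'   (m/s, equals the superficial velocity outside the plug) and `pressure`
#'   (Pa, 0 at outlet).
#' @export
axial_profile <- function(geom, fluid, flow, k, porosity, n_stations = 200,
                          tubing_length = 20e-3, cartridge_buffer = 3e-3) {
  if (k <= 0) stop("`k` must be positive")
  if (!(porosity > 0 && porosity < 1)) stop("`porosity` must be in (0, 1)")
  A_tube <- pi / 4 * geom$tubing_diameter^2
  L <- c(tubing_length, cartridge_buffer, geom$scaffold_length,
         cartridge_buffer, tubing_length)
  seg <- c("tubing_in", "cartridge_in", "scaffold", "cartridge_out",
           "tubing_out")
  A <- c(A_tube, geom$cartridge_area, geom$cartridge_area,
         geom$cartridge_area, A_tube)
  edges <- c(0, cumsum(L))
  z <- seq(0, sum(L), length.out = n_stations)
  i <- pmin(findInterval(z, edges, rightmost.closed = TRUE), 5L)
  dp <- pressure_from_permeability(flow, fluid, geom, k)
  z0 <- edges[3]; z1 <- edges[4]
  pressure <- ifelse(z <= z0, dp,
               ifelse(z >= z1, 0, dp * (z1 - z) / (z1 - z0)))
  vel <- flow$Q / A[i]
  data.frame(position = z, segment = seg[i], area = A[i], velocity = vel,
             velocity_interstitial = ifelse(seg[i] == "scaffold",
                                            vel / porosity, vel),
             pressure = pressure)
}

#' Reynolds number
#'
#' Re = ρ v d / η; the regime check justifying the creeping-flow (Stokes)
#' treatment of the pore-scale problem (Re « 1 at the modeled operating
#' point).
#'
#' @param fluid a [fluid_props()].
#' @param velocity characteristic velocity, m/s.
#' @param length_scale characteristic length, m (e.g. mean pore diameter).
#' @return Dimensionless Reynolds number.
#' @export
reynolds <- function(fluid, velocity, length_scale) {
  if (velocity < 0 || length_scale <= 0)
    stop("`velocity` must be >= 0 and `length_scale` > 0")
  fluid$density * velocity * length_scale / fluid$viscosity
}
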