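#' Pore-scale flow solver configuration
#'
#' @param tol relative residual tolerance on the coupled momentum/continuity
#'   system (default 1e-5).
#' @param max_iter iteration bound for the linear solver.
#' @param buffer number of all-fluid buffer layers added before and after the
#'   scaffold along the flow axis (>= 5; the inlet plug profile relaxes over
#'   the upstream buffer).
#' @param inlet `"flow_rate"`: drive the domain with `flow$Q`;
#'   `"superficial_velocity"`: drive it with `superficial_velocity` (m/s),
#'   i.e. Q = v_s × domain cross-section. The latter maps a device operating
#'   point onto a subdomain narrower than the real cartridge.
#' @param superficial_velocity inlet superficial velocity, m/s (used when
#'   `inlet = "superficial_velocity"`).
#' @return A `solver_config` object.
#' @export
solver_config <- function(tol = 1e-5, max_iter = 20000L, buffer = 8L,
                          inlet = c("flow_rate", "superficial_velocity"),
                          superficial_velocity = NULL) {
  if (tol <= 0) stop("`tol` must be positive")
  if (max_iter < 1) stop("`max_iter` must be >= 1")
  if (buffer < 5) stop("`buffer` must be >= 5 layers")
  inlet <- match.arg(inlet)
  if (inlet == "superficial_velocity" &&
      (is.null(superficial_velocity) || superficial_velocity < 0))
    stop("`superficial_velocity` (m/s, >= 0) required for this inlet mode")
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 buffer = as.integer(buffer), inlet = inlet,
                 superficial_velocity = superficial_velocity),
            class = "solver_config")
}

#' Solve steady creeping (Stokes) flow through a voxelized scaffold
#'
#' Solves the incompressible Stokes equations on the pore space of `grid`,
#' placed in a straight duct with all-fluid buffer layers upstream and
#' downstream: uniform velocity inlet distributing the flow over the
#' inlet-face fluid cells, do-nothing outflow with outlet gauge pressure 0,
#' no-slip on all solid-fluid walls and on the duct side walls. The
#' discretization is a staggered-grid (MAC) finite-difference scheme; the
#' symmetric saddle-point system is solved matrix-free by preconditioned
#' MINRES with a fixed, deterministic iteration order, so identical inputs
#' give bit-identical fields and the solution is exactly linear in the flow
#' rate.
#'
#' Inertia is neglected: at the modeled operating point the pore Reynolds
#' number is ~0.5, well inside the creeping-flow regime; a warning is issued
#' if the estimated Re exceeds 10.
#'
#' @param grid a cleaned, percolating [voxel_grid()].
#' @param fluid a [fluid_props()].
#' @param flow a [flow_condition()] (ignored for the inlet when `config`
#'   specifies a superficial velocity).
#' @param config a [solver_config()].
#' @return A `flow_field`: staggered face-velocity arrays `u`, `v`, `w`
#'   (m/s, on the padded domain, flow along the third axis), cell pressure
#'   `p` (Pa, outlet gauge), cell-centred velocity components and magnitude,
#'   the padded fluid mask, voxel size `h` (m), buffer size, scaffold slab
#'   range, inlet flow rate `Q` (m³/s), and the convergence record
#'   (`iterations`, `converged`, `rel_residual`, `residual_history`).
#'   Non-convergence within `max_iter` yields a warning and
#'   `converged = FALSE`; the field is still returned.
#' @export
solve_flow <- function(grid, fluid, flow, config = solver_config()) {
  stopifnot_grid(grid)
  if (!percolates(grid))
    stop("grid does not percolate along the flow axis; clean it first")
  g <- permute_flow_last(grid)
  d <- g$dims
  h <- g$spacing * 1e-6  # m

  nb <- config$buffer
  dims_p <- c(d[1], d[2], d[3] + 2L * nb)
  fl <- array(1L, dims_p)
  fl[, , nb + seq_len(d[3])] <- 1L - g$labels  # 1 = fluid for the solver

  A_dom <- d[1] * d[2] * h^2
  Q <- if (config$inlet == "superficial_velocity")
    config$superficial_velocity * A_dom else flow$Q

  # creeping-flow regime check from the pore scale
  spec <- attr(grid, "scaffold_spec")
  pore_m <- if (!is.null(spec$pore_mean)) spec$pore_mean * 1e-6 else 20 * h
  phi <- max(porosity(g), 1e-3)
  Re <- reynolds(fluid, (Q / A_dom) / phi + 1e-300, pore_m)
  if (Re > 10)
    warning(sprintf(
      "pore Reynolds number ~%.2g exceeds 10; creeping-flow assumption is violated",
      Re))

  sol <- cpp_solve_stokes(as.integer(fl), dims_p, h, Q, fluid$viscosity,
                          config$tol, config$max_iter, 10L)
  if (!sol$converged)
    warning(sprintf(
      "flow solve did not converge: relative residual %.3g after %d iterations",
      sol$rel_residual, sol$iterations))

  # cell-centred velocities
  nx <- dims_p[1]; ny <- dims_p[2]; nz <- dims_p[3]
  uc <- 0.5 * (sol$u[1:nx, , , drop = FALSE] + sol$u[2:(nx + 1), , , drop = FALSE])
  vc <- 0.5 * (sol$v[, 1:ny, , drop = FALSE] + sol$v[, 2:(ny + 1), , drop = FALSE])
  wc <- 0.5 * (sol$w[, , 1:nz, drop = FALSE] + sol$w[, , 2:(nz + 1), drop = FALSE])
  speed <- sqrt(uc^2 + vc^2 + wc^2)

  structure(
    list(u = sol$u, v = sol$v, w = sol$w, p = sol$p,
         uc = uc, vc = vc, wc = wc, speed = speed,
         fluid_mask = fl, dims = dims_p, h = h, buffer = nb,
         scaffold_slabs = nb + seq_len(d[3]),
         Q = Q, viscosity = fluid$viscosity,
         inlet_velocity = sol$inlet_velocity,
         iterations = sol$iterations, converged = sol$converged == 1,
         rel_residual = sol$rel_residual,
         residual_history = sol$residual_history),
    class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> %d x %d x %d cells (incl. 2 x %d buffer), h = %.3g um\n",
              x$dims[1], x$dims[2], x$dims[3], x$buffer, x$h * 1e6))
  cat(sprintf("  Q = %.3g m3/s | %s in %d iterations (rel. residual %.2g)\n",
              x$Q, if (x$converged) "converged" else "NOT converged",
              x$iterations, x$rel_residual))
  invisible(x)
}

#' Volumetric flux through each cross-section
#'
#' Integrates the normal (axial) face velocities over every plane
#' perpendicular to the flow axis. For a converged incompressible solution
#' every plane carries the inlet flow rate.
#'
#' @param field a `flow_field` from [solve_flow()].
#' @return Numeric vector of fluxes (m³/s), one per face plane.
#' @export
cross_section_flux <- function(field) {
  apply(field$w, 3, sum) * field$h^2
}
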