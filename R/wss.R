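#' Wall shear stress on the solid-fluid interface
#'
#' For every voxel face separating a solid voxel from a fluid voxel, the
#' shear stress magnitude is estimated as τ = η ‖u_t‖ / (h/2): a one-sided
#' first-order gradient of the tangential velocity between the wall (no-slip,
#' halfway between the voxel centres) and the first fluid node. This is the
#' stress stimulus sensed by cells lining the trabecular surface. The known
#' stair-step voxelization bias of this estimator is accepted and not
#' smoothed.
#'
#' On a voxelized (stair-step) surface this per-face tangential estimator is
#' known to under-read the surface-averaged stress of the underlying smooth
#' wall: an oblique wall is rendered as steps, and part of the true surface
#' traction appears as pressure (form) drag on the step faces instead of
#' resolved shear. The report therefore also carries `mean_momentum`, the
#' momentum-balance (force-consistent) area-weighted mean: in steady Stokes
#' flow the net axial pressure force across the pore space equals the wall
#' shear drag (exactly so for a prismatic pore space), so the smooth-wall
#' mean shear stress is Δp·A_fluid / S_wall with Δp the solved pressure
#' drop across the scaffold region, A_fluid the pore (fluid) cross-section
#' of that region and S_wall the solid-fluid interface area. On wall-aligned
#' geometry (e.g. a plane slit) the two estimators agree; on stair-stepped
#' trabecular geometry `mean_momentum` is the resolution-robust estimate of
#' the mean, while the per-face values describe the distribution shape.
#'
#' @param field a `flow_field` from [solve_flow()].
#' @param fluid optional [fluid_props()]; defaults to the viscosity used in
#'   the solve.
#' @return A `wss_report`: per-face `tau` (Pa), `area` (m², uniform h²),
#'   `slab` (axial slab index of the fluid cell, padded coordinates), and
#'   the area-weighted summary `mean`, `median`, `p5`, `p95` (Pa),
#'   `mean_momentum` (Pa, see above; `NA` when the solve carried no flow),
#'   `band_fraction` (fraction of faces with τ in the 0.5-10 mPa
#'   osteogenic band), `total_area` (m²), and `per_slab` (data frame of
#'   slab-wise area-weighted means over the scaffold region).
#' @export
wall_shear_stress <- function(field, fluid = NULL) {
  if (!inherits(field, "flow_field")) stop("expected a `flow_field`")
  mu <- if (is.null(fluid)) field$viscosity else fluid$viscosity
  fl <- field$fluid_mask
  d <- dim(fl)
  if (!all(dim(field$p) == d)) stop("field/grid shape mismatch")
  h <- field$h

  # cell-centred tangential components per wall orientation
  tau <- numeric(0)
  slab <- integer(0)

  shifts <- list(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                 c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))
  kidx <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  for (s in shifts) {
    ax <- which(s != 0L)
    # fluid cell with a solid neighbour in direction s
    nb <- shift_array(fl, s, fill = 1L)  # outside domain treated as open
    wall <- fl == 1L & nb == 0L
    if (!any(wall)) next
    t1 <- switch(ax, field$vc, field$uc, field$uc)[wall]
    t2 <- switch(ax, field$wc, field$wc, field$vc)[wall]
    tau <- c(tau, mu * sqrt(t1^2 + t2^2) / (h / 2))
    slab <- c(slab, kidx[wall])
  }

  area <- rep(h^2, length(tau))
  wsum <- function(x, w) sum(x * w) / sum(w)

  # momentum-balance mean: solved pressure drop across the scaffold region
  # times the pore (fluid) cross-section, distributed over the wall area.
  # The fluid area, not the duct area, is the prismatic control-volume
  # identity (tau * S = dp * A_fluid for developed flow in a prismatic pore
  # space); using the full duct area would book the blunt-frontal form drag
  # on the solid as shear.
  mean_momentum <- NA_real_
  if (length(tau) > 0 && field$Q > 0) {
    sl <- field$scaffold_slabs
    flm <- fl == 1L
    pbar <- function(k) mean(field$p[, , k][flm[, , k]])
    dp <- pbar(min(sl) - 1L) - pbar(max(sl) + 1L)
    A_fluid <- mean(flm[, , sl]) * d[1] * d[2] * h^2
    if (is.finite(dp) && dp > 0)
      mean_momentum <- dp * A_fluid / (length(tau) * h^2)
  }
  per_slab <- if (length(tau) > 0) {
    agg <- tapply(tau, slab, mean)
    data.frame(slab = as.integer(names(agg)), mean_tau = as.numeric(agg))
  } else data.frame(slab = integer(), mean_tau = numeric())

  structure(
    list(tau = tau, area = area, slab = slab,
         mean = if (length(tau)) wsum(tau, area) else NA_real_,
         mean_momentum = mean_momentum,
         median = if (length(tau)) median(tau) else NA_real_,
         p5 = if (length(tau)) quantile(tau, 0.05, names = FALSE) else NA_real_,
         p95 = if (length(tau)) quantile(tau, 0.95, names = FALSE) else NA_real_,
         band_fraction = if (length(tau))
           mean(tau >= 0.5e-3 & tau <= 10e-3) else NA_real_,
         total_area = sum(area), per_slab = per_slab,
         scaffold_slabs = field$scaffold_slabs),
    class = "wss_report")
}

shift_array <- function(a, s, fill = 0L) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  for (ax in 1:3) {
    if (s[ax] == 1L) { dst[[ax]] <- 2:d[ax]; src[[ax]] <- 1:(d[ax] - 1) }
    if (s[ax] == -1L) { dst[[ax]] <- 1:(d[ax] - 1); src[[ax]] <- 2:d[ax] }
  }
  # neighbour value at +s: out[x] = a[x + s]
  out[src[[1]], src[[2]], src[[3]]] <- a[dst[[1]], dst[[2]], dst[[3]]]
  out
}

#' @export
print.wss_report <- function(x, ...) {
  cat(sprintf(paste0("<wss_report> %d wall faces, %.3g m2\n",
                     "  tau (per-face): mean %.3g mPa | median %.3g | P5 %.3g | P95 %.3g\n",
                     "  tau (momentum-balance mean): %.3g mPa\n",
                     "  %.1f%% of faces in the 0.5-10 mPa band\n"),
              length(x$tau), x$total_area, x$mean * 1e3, x$median * 1e3,
              x$p5 * 1e3, x$p95 * 1e3, x$mean_momentum * 1e3,
              100 * x$band_fraction))
  invisible(x)
}

#' Fluid-phase field summary
#'
#' Volume-averaged velocity magnitude and gauge pressure over the fluid
#' phase of the scaffold region, axial profiles of both over the whole
#' padded domain, and the locations of the velocity/pressure peaks.
#'
#' @param field a `flow_field` from [solve_flow()].
#' @return A list: `mean_velocity` (m/s), `mean_pressure` (Pa) over the
#'   scaffold fluid; `profile` data frame (`slab`, `mean_speed`,
#'   `mean_pressure`, `flux`); `peak_velocity_slab`, `peak_pressure_slab`.
#' @export
field_summary <- function(field) {
  if (!inherits(field, "flow_field")) stop("expected a `flow_field`")
  fl <- field$fluid_mask == 1L
  sl <- field$scaffold_slabs
  insc <- fl
  insc[, , -sl] <- FALSE
  prof_speed <- vapply(seq_len(field$dims[3]), function(k) {
    f <- fl[, , k]
    if (!any(f)) return(NA_real_)
    mean(field$speed[, , k][f])
  }, 0)
  prof_p <- vapply(seq_len(field$dims[3]), function(k) {
    f <- fl[, , k]
    if (!any(f)) return(NA_real_)
    mean(field$p[, , k][f])
  }, 0)
  flux <- cross_section_flux(field)
  list(mean_velocity = mean(field$speed[insc]),
       mean_pressure = mean(field$p[insc]),
       profile = data.frame(slab = seq_len(field$dims[3]),
                            mean_speed = prof_speed,
                            mean_pressure = prof_p,
                            flux = flux[seq_len(field$dims[3])]),
       peak_velocity_slab = which.max(prof_speed),
       peak_pressure_slab = which.max(prof_p))
}

#' Effective permeability of the solved geometry
#'
#' Applies Darcy's law to the resolved pore-scale solution:
#' k = Q η L / (A Δp) with Δp the solved plane-averaged pressure drop across
#' the scaffold region (buffer plane just upstream minus buffer plane just
#' downstream) and L the scaffold length. By Stokes linearity the result is
#' independent of Q. This is the cross-model consistency check between the
#' pore-scale solve and the Darcy calibration route.
#'
#' @param field a `flow_field` from [solve_flow()].
#' @return Permeability k in m².
#' @export
effective_permeability <- function(field) {
  if (!inherits(field, "flow_field")) stop("expected a `flow_field`")
  if (field$Q <= 0) stop("effective permeability requires a nonzero flow")
  fl <- field$fluid_mask == 1L
  sl <- field$scaffold_slabs
  k_in <- min(sl) - 1L   # last upstream buffer slab
  k_out <- max(sl) + 1L  # first downstream buffer slab
  pbar <- function(k) mean(field$p[, , k][fl[, , k]])
  dp <- pbar(k_in) - pbar(k_out)
  if (!is.finite(dp) || dp <= 0)
    stop("no resolvable pressure drop across the scaffold region")
  L <- length(sl) * field$h
  A <- field$dims[1] * field$dims[2] * field$h^2
  field$Q * field$viscosity * L / (A * dp)
}
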