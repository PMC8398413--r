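# Poiseuille-suite verification of the staggered-grid Stokes solver.
fl_water <- fluid_props(6.913e-4, 993)

test_that("developed duct profile matches the rectangular-duct series within 5%", {
  g <- open_duct_grid(side_fluid = 24, length = 36, spacing = 25)
  f <- solve_flow(g, fl_water, flow_condition(1e-9),
                  solver_config(tol = 1e-6, buffer = 6))
  expect_true(f$converged)

  h <- f$h
  a <- 24 * h
  kmid <- round(dim(f$w)[3] / 2)
  w <- f$w[, , kmid]
  sel <- 2:25  # fluid columns
  num <- w[sel, sel]
  yy <- (seq_len(24) - 0.5) * h
  ex <- outer(yy, yy, function(y, z) duct_series(y, z, a, a))
  # compare shapes normalized by their means
  rel_err <- abs(num / mean(num) - ex / mean(ex)) / max(ex / mean(ex))
  expect_lt(max(rel_err), 0.05)
})

test_that("zero flow gives an identically zero field; solution is exactly linear in Q", {
  g <- open_duct_grid(12, 20, 40)
  f0 <- solve_flow(g, fl_water, flow_condition(0), solver_config(buffer = 5))
  expect_identical(max(abs(f0$w)), 0)
  expect_identical(max(abs(f0$p)), 0)

  f1 <- solve_flow(g, fl_water, flow_condition(1e-9),
                   solver_config(tol = 1e-6, buffer = 5))
  f2 <- solve_flow(g, fl_water, flow_condition(2e-9),
                   solver_config(tol = 1e-6, buffer = 5))
  expect_identical(f2$u, 2 * f1$u)
  expect_identical(f2$w, 2 * f1$w)
  expect_identical(f2$p, 2 * f1$p)
})

test_that("flux is conserved through every cross-section within 1%", {
  g <- slit_grid(nx = 40, gap = 10, length = 24, spacing = 30)
  f <- solve_flow(g, fl_water, flow_condition(5e-10),
                  solver_config(tol = 1e-5, buffer = 5))
  flux <- cross_section_flux(f)
  flux <- flux[-1]  # first entry is the inlet Dirichlet plane itself
  expect_lt((max(flux) - min(flux)) / mean(flux), 0.01)
  expect_lt(abs(mean(flux) / f$Q - 1), 0.01)

  # independent per-voxel summation oracle for one interior plane
  k <- 12
  s <- 0
  for (i in seq_len(dim(f$w)[1]))
    for (j in seq_len(dim(f$w)[2]))
      s <- s + f$w[i, j, k]
  expect_equal(s * f$h^2, flux[k - 1], tolerance = 1e-12)
})

test_that("one-sided wall stress matches plane Poiseuille within 5% at a 24-voxel gap", {
  # wide slit, gap 24 voxels: central wall faces see plane Poiseuille
  g <- slit_grid(nx = 120, gap = 24, length = 30, spacing = 20)
  f <- solve_flow(g, fl_water, flow_condition(2e-9),
                  solver_config(tol = 1e-6, buffer = 6))
  h <- f$h
  gap <- 24 * h
  kmid <- 15 + f$buffer
  imid <- 60
  vbar <- mean(f$w[imid, 1 + seq_len(24), kmid])  # central column mean
  tau_plane <- 6 * f$viscosity * vbar / gap
  # one-sided estimate at the wall below the central column
  ut <- 0.5 * (f$w[imid, 2, kmid] + f$w[imid, 2, kmid + 1])
  tau_num <- f$viscosity * ut / (h / 2)
  expect_lt(abs(tau_num / tau_plane - 1), 0.05)

  # spec example numbers: h = 500 um slit, vbar = 0.333 mm/s
  expect_lt(abs(6 * 6.913e-4 * 0.333e-3 / 500e-6 - 2.77e-3) / 2.77e-3, 0.01)

  # zero-flow field has identically zero wall stress
  f0 <- solve_flow(g, fl_water, flow_condition(0), solver_config(buffer = 6))
  w0 <- wall_shear_stress(f0)
  expect_identical(max(w0$tau), 0)

  # WSS scales exactly with viscosity (same scaled solve, different eta)
  w1 <- wall_shear_stress(f)
  w2 <- wall_shear_stress(f, fluid_props(2 * 6.913e-4))
  expect_identical(w2$tau, 2 * w1$tau)
})

test_that("momentum-balance and per-face WSS means agree on wall-aligned geometry", {
  # long slit so entrance/exit pressure losses are a small fraction of dp
  g <- slit_grid(nx = 96, gap = 12, length = 100, spacing = 25)
  f <- solve_flow(g, fl_water, flow_condition(2e-9),
                  solver_config(tol = 1e-6, buffer = 6))
  w <- wall_shear_stress(f)
  # slit walls are grid-aligned: the tangential estimator carries the drag
  expect_lt(abs(w$mean_momentum / w$mean - 1), 0.15)
})

test_that("Poiseuille error decreases monotonically under grid refinement", {
  errs <- vapply(c(8, 16, 32), function(nf) {
    # duct long enough for full development at every resolution
    g <- open_duct_grid(nf, 2 * nf + 12, spacing = 600 / nf)
    f <- solve_flow(g, fl_water, flow_condition(1e-9),
                    solver_config(tol = 1e-7, buffer = 6))
    h <- f$h
    a <- nf * h
    kmid <- 6 + round((2 * nf + 12) * 0.75)
    sel <- 2:(nf + 1)
    num <- f$w[sel, sel, kmid]
    yy <- (seq_len(nf) - 0.5) * h
    ex <- outer(yy, yy, function(y, z) duct_series(y, z, a, a))
    max(abs(num / mean(num) - ex / mean(ex)) / max(ex / mean(ex)))
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("effective permeability recovers the slit closed form and is Q-independent", {
  # wide slit gap b: k = phi * b^2 / 12 (plane Poiseuille between plates)
  nx <- 192; gap <- 12
  g <- slit_grid(nx = nx, gap = gap, length = 60, spacing = 25)
  f <- solve_flow(g, fl_water, flow_condition(1e-9),
                  solver_config(tol = 1e-6, buffer = 6))
  b <- gap * f$h
  phi <- gap / (gap + 2)
  k_expect <- phi * b^2 / 12
  k_geom <- effective_permeability(f)
  expect_lt(abs(k_geom / k_expect - 1), 0.10)

  f2 <- solve_flow(g, fl_water, flow_condition(2e-9),
                   solver_config(tol = 1e-6, buffer = 6))
  expect_lt(abs(effective_permeability(f2) / k_geom - 1), 0.01)
})

test_that("field_summary reports exact means on hand-built fields", {
  d <- c(4L, 4L, 6L)
  fl <- array(1L, d)
  v0 <- 1e-4
  f <- structure(list(
    u = array(0, d + c(1, 0, 0)), v = array(0, d + c(0, 1, 0)),
    w = array(v0, d + c(0, 0, 1)),
    p = array(rep(seq(10, 0, length.out = d[3]), each = d[1] * d[2]), d),
    uc = array(0, d), vc = array(0, d), wc = array(v0, d),
    speed = array(v0, d), fluid_mask = fl, dims = d, h = 1e-5,
    buffer = 2L, scaffold_slabs = 3:4, Q = v0 * 16 * 1e-10,
    viscosity = 1e-3, iterations = 0, converged = TRUE,
    rel_residual = 0, residual_history = numeric()),
    class = "flow_field")
  s <- field_summary(f)
  expect_equal(s$mean_velocity, v0, tolerance = 1e-15)
  # linear ramp from 10 to 0 over 6 slabs, scaffold slabs 3:4 -> mean of slabs
  expect_equal(s$mean_pressure, mean(seq(10, 0, length.out = 6)[3:4]),
               tolerance = 1e-15)
  expect_equal(s$profile$flux, rep(v0 * 16 * 1e-10, 6), tolerance = 1e-15)
})

test_that("solver rejects non-percolating grids and flags non-convergence", {
  lab <- array(0L, c(8, 8, 8))
  lab[, , 4] <- 1L  # full blocking wall
  g <- voxel_grid(lab, 40)
  expect_error(solve_flow(g, fl_water, flow_condition(1e-9)), "percolat")

  g2 <- open_duct_grid(10, 16, 40)
  expect_warning(
    f <- solve_flow(g2, fl_water, flow_condition(1e-9),
                    solver_config(tol = 1e-10, max_iter = 5, buffer = 5)),
    "converge")
  expect_false(f$converged)
  expect_identical(f$iterations, 5L)
})

test_that("scaffold effective permeability sits in the Kozeny-Carman range, far above the measured-circuit value", {
  pf <- preset_field40()
  g <- pf$grid
  f <- pf$field
  m <- measure_morphometry(g)
  k_geom <- effective_permeability(f)
  # Kozeny-Carman oracle from measured porosity and specific surface
  sv <- m$specific_surface * 1e6  # 1/m
  k_kc <- m$porosity^3 / (5 * sv^2)
  expect_gt(k_geom, 100 * 6.64e-12)
  expect_gt(k_geom / k_kc, 1 / 20)
  expect_lt(k_geom / k_kc, 20)
})
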