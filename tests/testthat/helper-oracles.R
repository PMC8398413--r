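# Independent oracles used across tests. These deliberately avoid the
# package's compiled kernels: plain-R breadth-first search for connectivity,
# classical series solutions for duct flow, hand-written least squares.

# --- exact laminar profile in a rectangular duct a x b (no-slip), unit
# pressure gradient scale; returns relative profile (arbitrary scale)
duct_series <- function(y, z, a, b, nterm = 99) {
  u <- 0
  for (n in seq(1, nterm, by = 2)) {
    u <- u + (1 / n^3) *
      (1 - cosh(n * pi * (z - b / 2) / a) / cosh(n * pi * b / (2 * a))) *
      sin(n * pi * y / a)
  }
  u
}

# --- plain-R BFS connected-component labeling (exhaustive, slow)
r_label <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  lab <- array(0L, d)
  nxt <- 0L
  for (s in which(mask == 1L)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ci <- arrayInd(cur, d)
      for (o in seq_len(nrow(offs))) {
        p <- ci + as.integer(offs[o, ])
        if (any(p < 1) || any(p > d)) next
        q <- p[1] + d[1] * (p[2] - 1 + d[2] * (p[3] - 1))
        if (mask[q] == 1L && lab[q] == 0L) {
          lab[q] <- nxt
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# --- plain-R reimplementation of the island-removal / pore-sealing rules
# (iterated to a fixed point), used as the flood-fill oracle
r_clean_oracle <- function(lab, flow_axis = 3, max_passes = 10) {
  d <- dim(lab)
  for (pass in seq_len(max_passes)) {
    old <- lab
    comp <- r_label(lab, 26)
    if (max(comp) > 1) {
      sizes <- tabulate(comp)
      keep <- which.max(sizes)
      lab[comp > 0 & comp != keep] <- 0L
    }
    fcomp <- r_label(1L - lab, 6)
    inlet <- switch(flow_axis, fcomp[1, , ], fcomp[, 1, ], fcomp[, , 1])
    keepf <- unique(inlet[inlet > 0])
    lab[fcomp > 0 & !(fcomp %in% keepf)] <- 1L
    if (identical(lab, old)) break
  }
  lab
}

# --- hand-written OLS slope
ols_slope <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) / sum((x - mx)^2)
}

# --- small grid builders
solid_slab_grid <- function(n = 24, lo = 8, hi = 17, spacing = 10) {
  lab <- array(0L, c(n, n, n))
  lab[, , lo:hi] <- 1L
  voxel_grid(lab, spacing)
}

open_duct_grid <- function(side_fluid, length, spacing, wall = 1L) {
  n <- side_fluid + 2L * wall
  lab <- array(1L, c(n, n, length))
  lab[wall + seq_len(side_fluid), wall + seq_len(side_fluid), ] <- 0L
  voxel_grid(lab, spacing)
}

# wide slit: fluid layer of `gap` cells in y spanning the whole x width
slit_grid <- function(nx, gap, length, spacing) {
  ny <- gap + 2L
  lab <- array(1L, c(nx, ny, length))
  lab[, 1L + seq_len(gap), ] <- 0L
  voxel_grid(lab, spacing)
}

small_paper_scaffold <- function(seed = 1, spacing = 40,
                                 domain = c(4000, 4000, 4000)) {
  generate_scaffold(paper_scaffold_spec(seed = seed, spacing = spacing,
                                        domain_size = domain))
}

# the preset 4 mm / 40 um scaffold solved at the bioreactor operating point;
# memoized because the solve takes minutes and several tests inspect it
.preset40_cache <- new.env()
preset_field40 <- function() {
  if (is.null(.preset40_cache$val)) {
    grid <- generate_scaffold(paper_scaffold_spec(seed = 1, spacing = 40))
    flow <- paper_flow()
    cfg <- solver_config(tol = 1e-4, max_iter = 30000,
                         inlet = "superficial_velocity",
                         superficial_velocity = flow$Q /
                           paper_cartridge()$cartridge_area)
    field <- solve_flow(grid, paper_fluid(), flow, cfg)
    .preset40_cache$val <- list(grid = grid, field = field)
  }
  .preset40_cache$val
}
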