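test_that("Darcy permeability matches direct evaluation and is exactly inverse to the pressure form", {
  flow <- paper_flow()
  fl <- paper_fluid()
  geom <- paper_cartridge()

  # unit bookkeeping: 1.7 mL/min
  expect_equal(flow$Q, 1.7 * 1e-6 / 60, tolerance = 1e-15)

  # printed-constant evaluation (independent arithmetic)
  k_ref <- 6.64e-12
  dp <- (1.7e-6 / 60) * 6.913e-4 * 9e-3 / (78.5e-6 * k_ref)
  expect_lte(abs(dp - 338.2) / 338.2, 0.005)  # ~338 Pa implied drop
  est <- permeability_from_pressure(flow, fl, geom, dp)
  expect_equal(est$mean, k_ref, tolerance = 1e-12)

  # exact algebraic inverse, round trip to machine precision
  dp2 <- pressure_from_permeability(flow, fl, geom, est$mean)
  k2 <- permeability_from_pressure(flow, fl, geom, dp2)$mean
  expect_equal(k2, k_ref, tolerance = 1e-13)

  # homogeneity: doubling dp halves k exactly
  expect_identical(permeability_from_pressure(flow, fl, geom, 2 * dp)$mean,
                   est$mean / 2)

  # Q = 0 -> dp = 0
  expect_identical(
    pressure_from_permeability(flow_condition(0), fl, geom, k_ref), 0)

  # error contracts
  expect_error(permeability_from_pressure(flow, fl, geom, 0), "positive")
  expect_error(permeability_from_pressure(flow, fl, geom, c(300, -1)))
  expect_error(pressure_from_permeability(flow, fl, geom, 0), "positive")
})

test_that("multi-sample permeability statistics match a hand-computed oracle", {
  flow <- paper_flow(); fl <- paper_fluid(); geom <- paper_cartridge()
  dp <- c(300, 338.2, 380)
  est <- permeability_from_pressure(flow, fl, geom, dp)
  # independent spreadsheet-style arithmetic
  k_hand <- (1.7e-6 / 60) * 6.913e-4 * 9e-3 / (78.5e-6 * dp)
  m_hand <- sum(k_hand) / 3
  s_hand <- sqrt(sum((k_hand - m_hand)^2) / 2)
  expect_equal(est$k, k_hand, tolerance = 1e-14)
  expect_equal(est$mean, m_hand, tolerance = 1e-14)
  expect_equal(est$sd, s_hand, tolerance = 1e-12)
})

test_that("axial profile conserves flow, uses segment areas, and spans dp to 0", {
  flow <- paper_flow(); fl <- paper_fluid()
  geom <- paper_cartridge()
  k <- 6.64e-12
  pr <- axial_profile(geom, fl, flow, k, porosity = 0.9, n_stations = 400)

  # superficial velocity = Q/A at every station (flow conservation)
  expect_equal(pr$velocity * pr$area, rep(flow$Q, nrow(pr)), tolerance = 1e-15)

  # printed-geometry superficial velocity in the cartridge: Q/78.5mm2
  v_cart <- unique(pr$velocity[pr$segment == "scaffold"])
  expect_equal(v_cart, flow$Q / 78.5e-6, tolerance = 1e-12)
  expect_lte(abs(v_cart * 1e3 - 0.361) / 0.361, 0.01)  # 0.361 mm/s

  # interstitial velocity inside the plug is superficial / porosity
  expect_equal(unique(pr$velocity_interstitial[pr$segment == "scaffold"]),
               v_cart / 0.9, tolerance = 1e-12)

  # tubing velocity scales with the inverse area ratio
  g2 <- cartridge_geometry(9e-3, cartridge_diameter = 10e-3,
                           tubing_diameter = 5e-3)
  pr2 <- axial_profile(g2, fl, flow, k, 0.9)
  v_tube <- unique(pr2$velocity[pr2$segment == "tubing_in"])
  v_cart2 <- unique(pr2$velocity[pr2$segment == "cartridge_in"])
  expect_equal(v_tube / v_cart2, (10 / 5)^2, tolerance = 1e-12)

  # outlet pressure 0, inlet pressure = Darcy dp, non-increasing downstream
  dp <- pressure_from_permeability(flow, fl, geom, k)
  expect_equal(pr$pressure[1], dp, tolerance = 1e-12)
  expect_identical(pr$pressure[nrow(pr)], 0)
  expect_true(all(diff(pr$pressure) <= 1e-12))
})

test_that("Reynolds number evaluates the operating point and scales linearly", {
  fl <- paper_fluid()
  re <- reynolds(fl, velocity = 3.7e-4, length_scale = 839e-6)
  expect_equal(re, 993 * 3.7e-4 * 839e-6 / 6.913e-4, tolerance = 1e-15)
  expect_lte(abs(re - 0.45), 0.01)
  expect_identical(reynolds(fl, 0, 1e-3), 0)
  expect_equal(reynolds(fl, 3.7e-4, 2 * 839e-6), 2 * re, tolerance = 1e-15)
})
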