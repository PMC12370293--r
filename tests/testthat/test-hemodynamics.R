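# Analytical duct-flow model: constructors, series solution, friction-factor
# pressure model, hydrostatic outlet head.

paper_geom <- channel_geometry()              # 1 mm x 100 um x 17 mm
pinned_fluid <- fluid(viscosity = 1e-3)       # Table-reproducing viscosity

test_that("constructors validate physical parameters", {
  expect_error(channel_geometry(width = -1), "positive")
  expect_error(channel_geometry(height = 0), "positive")
  expect_error(fluid(density = 0), "positive")
  expect_error(flow_condition(-1), "non-negative")
  expect_error(flow_condition(1e-9, outlet_head = -0.1), "non-negative")
  expect_error(series_control(0), ">= 1")
  expect_equal(paper_geom$W, 5e-4)
  expect_equal(paper_geom$H, 5e-5)
})

test_that("mean velocity is Q over cross-sectional area", {
  expect_equal(mean_velocity(paper_geom, 0), 0)
  expect_equal(mean_velocity(paper_geom, uL_min(13)), 2.1667e-3,
               tolerance = 1e-4)
  # linear in Q
  expect_equal(mean_velocity(paper_geom, uL_min(1.3)),
               mean_velocity(paper_geom, uL_min(13)) / 10)
})

test_that("series constant c1: trivial cases and the frozen bracket value", {
  expect_equal(as.numeric(series_c1(paper_geom, 0)), 0)
  # homogeneity in the mean velocity
  c1a <- as.numeric(series_c1(paper_geom, 1e-3))
  c1b <- as.numeric(series_c1(paper_geom, 2e-3))
  expect_equal(c1b, 2 * c1a)
  # frozen bracket denominator for W/H = 10 (series summed to 1e-12 rel tol)
  um <- 1e-3
  bracket <- -3 * um / paper_geom$W^2 / c1a
  expect_equal(bracket, 0.009369751, tolerance = 1e-6)
  # very wide channels are ill-conditioned for this expansion
  wide <- channel_geometry(width = 1, height = 1e-5)
  expect_error(series_c1(wide, 1e-3), "ill-conditioned")
})

test_that("velocity field: no-slip, symmetry, non-negativity", {
  c1 <- series_c1(paper_geom, mean_velocity(paper_geom, uL_min(13)))
  W <- paper_geom$W; H <- paper_geom$H
  ys <- seq(-H, H, length.out = 7)
  expect_equal(velocity_at(paper_geom, c1, rep(W, 7), ys), rep(0, 7),
               tolerance = 1e-12)
  expect_equal(velocity_at(paper_geom, c1, rep(-W, 7), ys), rep(0, 7),
               tolerance = 1e-12)
  xs <- seq(0.1, 0.9, by = 0.2) * W
  for (yfrac in c(0.2, 0.7)) {
    u_pp <- velocity_at(paper_geom, c1, xs, yfrac * H)
    expect_equal(velocity_at(paper_geom, c1, -xs, yfrac * H), u_pp)
    expect_equal(velocity_at(paper_geom, c1, xs, -yfrac * H), u_pp)
    expect_true(all(u_pp > 0))
  }
  expect_error(velocity_at(paper_geom, c1, 2 * W, 0), "outside")
})

test_that("bottom-wall shear: corner zeros, symmetry, linearity in Q and mu", {
  Q <- uL_min(13)
  c1 <- series_c1(paper_geom, mean_velocity(paper_geom, Q))
  W <- paper_geom$W
  expect_equal(wss_bottom(paper_geom, pinned_fluid, c1, c(-W, W)), c(0, 0),
               tolerance = 1e-12)
  xs <- seq(0.1, 0.9, by = 0.2) * W
  expect_equal(wss_bottom(paper_geom, pinned_fluid, c1, xs),
               wss_bottom(paper_geom, pinned_fluid, c1, -xs))
  # homogeneous of degree 1 in Q and in mu
  p1 <- wss_profile(paper_geom, pinned_fluid, Q)$peak
  p2 <- wss_profile(paper_geom, pinned_fluid, 2 * Q)$peak
  expect_equal(p2, 2 * p1, tolerance = 1e-10)
  p3 <- wss_profile(paper_geom, fluid(viscosity = 2e-3), Q)$peak
  expect_equal(p3, 2 * p1, tolerance = 1e-10)
  # profile peaks at the centreline
  prof <- wss_profile(paper_geom, pinned_fluid, Q, n_samples = 101)
  expect_equal(prof$peak, prof$tau[51])
  expect_equal(prof$peak, max(prof$tau))
})

test_that("series truncation is converged at the default term count", {
  Q <- uL_min(13)
  p_def <- wss_profile(paper_geom, pinned_fluid, Q)$peak
  p_dbl <- wss_profile(paper_geom, pinned_fluid, Q,
                       ctrl = series_control(1000L, 0))$peak
  expect_lt(abs(p_dbl - p_def) / p_def, 1e-4)
})

test_that("hydraulic diameter is 4A/P and symmetric in W and H", {
  sq <- channel_geometry(width = 2e-4, height = 2e-4)
  expect_equal(hydraulic_diameter(sq), 2e-4)
  expect_equal(hydraulic_diameter(paper_geom), 1.8182e-4, tolerance = 1e-4)
  swapped <- channel_geometry(width = 1e-4, height = 1e-3)
  expect_equal(hydraulic_diameter(swapped), hydraulic_diameter(paper_geom))
})

test_that("friction factor: frozen alpha = 10 value and limits", {
  expect_equal(friction_factor(10, 1) * 1, 84.70357, tolerance = 1e-6)
  # parallel-plate limit
  expect_equal(friction_factor(1e8, 1), 96, tolerance = 1e-6)
  # lambda ~ 1/Re
  expect_equal(friction_factor(10, 2), friction_factor(10, 1) / 2)
  expect_error(friction_factor(0.5, 1), ">= 1")
  expect_error(friction_factor(10, 0), "> 0")
})

test_that("pressure gradient and channel delta-P follow the friction model", {
  Q <- uL_min(13)
  expect_equal(pressure_gradient(paper_geom, pinned_fluid, 0), 0)
  # closed-form cross-check: dp/dz = (lambda Re) mu um / (2 Dh^2)
  um <- mean_velocity(paper_geom, Q)
  Dh <- hydraulic_diameter(paper_geom)
  expected <- 84.70357 * 1e-3 * um / (2 * Dh^2)
  expect_equal(pressure_gradient(paper_geom, pinned_fluid, Q), expected,
               tolerance = 1e-6)
  expect_equal(channel_delta_p(paper_geom, pinned_fluid, Q),
               expected * paper_geom$L, tolerance = 1e-6)
  # linear in Q
  expect_equal(channel_delta_p(paper_geom, pinned_fluid, Q),
               10 * channel_delta_p(paper_geom, pinned_fluid, Q / 10))
})

test_that("outlet gauge pressure: hydrostatic head and sub-Pa tube friction", {
  cond0 <- flow_condition(uL_min(13), outlet_head = 0)
  expect_equal(outlet_gauge_pressure(pinned_fluid, cond0)$total, 0)
  # stated-viscosity fluid: friction term below 1 Pa for the default tubing
  stated <- fluid()
  og <- outlet_gauge_pressure(stated,
                              flow_condition(uL_min(13), outlet_head = 0.4))
  expect_equal(og$hydrostatic, 3924)
  expect_lt(og$friction, 1)
  expect_equal(og$total, og$hydrostatic)   # friction excluded by default
  with_fric <- outlet_gauge_pressure(stated,
    flow_condition(uL_min(13), outlet_head = 0.4, include_tube_friction = TRUE))
  expect_equal(with_fric$total, with_fric$hydrostatic + with_fric$friction)
})

test_that("pressure profile is affine and anchored at the outlet", {
  cond <- flow_condition(uL_min(13), outlet_head = 0)
  pp <- pressure_profile(paper_geom, pinned_fluid, cond, n_samples = 51)
  expect_equal(pp$p[51], 0)                      # no-head outlet is 0 gauge
  expect_equal(pp$inlet_gauge, pp$outlet_gauge + pp$dpdz * paper_geom$L)
  # affinity: p(0) - p(z) = z * dp/dz at every sample
  expect_equal(pp$p[1] - pp$p, pp$z * pp$dpdz, tolerance = 1e-12)
  expect_true(all(diff(pp$p) <= 0))
})

test_that("series flux matches the imposed flow rate (mass conservation)", {
  Q <- uL_min(13)
  c1 <- series_c1(paper_geom, mean_velocity(paper_geom, Q))
  n <- 200L
  xm <- seq(-paper_geom$W, paper_geom$W, length.out = 2L * n + 1L)[seq(2L, 2L * n, by = 2L)]
  ym <- seq(-paper_geom$H, paper_geom$H, length.out = 2L * n + 1L)[seq(2L, 2L * n, by = 2L)]
  g <- expand.grid(x = xm, y = ym)
  u <- velocity_at(paper_geom, c1, g$x, g$y)
  Qnum <- sum(u) * (2 * paper_geom$W / n) * (2 * paper_geom$H / n)
  expect_lt(abs(Qnum - Q) / Q, 0.005)
})

test_that("force balance: delta-P times area matches wall drag within 5%", {
  # the friction-factor correlation is itself approximate, so the comparison
  # of Delta-P * A against L * (integral of tau around the perimeter) carries
  # a loose tolerance
  Q <- uL_min(13)
  c1 <- series_c1(paper_geom, mean_velocity(paper_geom, Q))
  W <- paper_geom$W; H <- paper_geom$H
  nq <- 400L
  xs <- seq(-W, W, length.out = nq + 1L); xs <- (xs[-1] + xs[-(nq + 1L)]) / 2
  tau_b <- wss_bottom(paper_geom, pinned_fluid, c1, xs)
  drag_bottom <- sum(tau_b) * (2 * W / nq)
  # side walls: mu du/dx at x = +-W via a fine one-sided difference
  ys <- seq(-H, H, length.out = nq + 1L); ys <- (ys[-1] + ys[-(nq + 1L)]) / 2
  eps <- W * 1e-3   # well below the wall boundary-layer scale H
  dudx <- velocity_at(paper_geom, c1, rep(W - eps, nq), ys) / eps
  drag_side <- sum(abs(pinned_fluid$viscosity * dudx)) * (2 * H / nq)
  drag_total <- 2 * drag_bottom + 2 * drag_side   # top/bottom + both sides
  dp <- channel_delta_p(paper_geom, pinned_fluid, Q)
  lhs <- dp * 4 * W * H
  rhs <- drag_total * paper_geom$L
  expect_lt(abs(lhs - rhs) / rhs, 0.05)
})

test_that("condition summary reproduces structure and additivity", {
  conds <- list(
    flow_condition(uL_min(13), 0, label = "SS high only"),
    flow_condition(uL_min(1.3), 0.4, label = "SS low+HP"))
  summ <- summarize_conditions(paper_geom, pinned_fluid, conds)
  expect_equal(nrow(summ), 2L)
  expect_equal(summ$label, c("SS high only", "SS low+HP"))
  expect_equal(summ$inlet_gauge_pa, summ$outlet_gauge_pa + summ$delta_p_pa)
  expect_error(summarize_conditions(paper_geom, pinned_fluid, list()),
               "at least one")
})

test_that("zero flow short-circuits every flow quantity", {
  rep0 <- hemodynamics_report(paper_geom, pinned_fluid,
                              flow_condition(0, outlet_head = 0.4))
  expect_equal(rep0$peak_wss, 0)
  expect_equal(rep0$channel_delta_p, 0)
  expect_equal(rep0$mean_velocity, 0)
  expect_equal(rep0$inlet_gauge, rep0$outlet_gauge)
  expect_equal(rep0$outlet_gauge, 1000 * 9.81 * 0.4)
})
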