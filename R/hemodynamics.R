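#' Rectangular microchannel geometry
#'
#' Describes the cross-section and length of a rectangular flow channel.
#' Internally the half-width \eqn{W} and half-height \eqn{H} are stored, so a
#' channel of external width \eqn{2W} and height \eqn{2H} is created from its
#' full dimensions. The coordinate frame is centred: \eqn{x \in [-W, W]} across
#' the width, \eqn{y \in [-H, H]} across the height (the cell-covered bottom
#' wall is \eqn{y = -H}), and \eqn{z \in [0, L]} from inlet to outlet.
#'
#' Defaults are the Ibidi mu-slide VI 0.1 channel used for endothelium-on-chip
#' flow experiments: 1 mm wide, 100 um high, 17 mm long.
#'
#' @param width Full channel width \eqn{2W} in metres.
#' @param height Full channel height \eqn{2H} in metres.
#' @param length Channel length \eqn{L} in metres.
#' @return An object of class `channel_geometry` with elements `W`, `H`, `L`
#'   (half-width, half-height, length, all in metres) plus the full `width` and
#'   `height`.
#' @examples
#' geom <- channel_geometry()           # 1 mm x 100 um x 17 mm
#' geom$W                               # 5e-4 m
#' @export
channel_geometry <- function(width = 1e-3, height = 1e-4, length = 17e-3) {
  stopifnot(is.numeric(width), is.numeric(height), is.numeric(length))
  if (width <= 0 || height <= 0 || length <= 0)
    stop("channel dimensions must be strictly positive", call. = FALSE)
  structure(list(W = width / 2, H = height / 2, L = length,
                 width = width, height = height),
            class = "channel_geometry")
}

#' Newtonian fluid properties
#'
#' @param density Mass density \eqn{\rho} in kg m^-3. Default 1000 (culture
#'   medium).
#' @param viscosity Dynamic viscosity \eqn{\mu} in Pa s. Default 7.2e-4
#'   (culture medium at 37 C).
#' @return An object of class `fluid`.
#' @export
fluid <- function(density = 1000, viscosity = 7.2e-4) {
  if (density <= 0 || viscosity <= 0)
    stop("density and viscosity must be strictly positive", call. = FALSE)
  structure(list(density = density, viscosity = viscosity), class = "fluid")
}

#' Convert a flow rate from uL/min to m^3/s
#'
#' @param x Flow rate in microlitres per minute.
#' @return Flow rate in m^3 s^-1.
#' @examples
#' uL_min(13)   # 2.1667e-7 m^3/s
#' @export
uL_min <- function(x) x * 1e-9 / 60

#' Flow condition: imposed flow rate and outlet boundary pressure
#'
#' Bundles the perfusion flow rate with the hydrostatic outlet condition: an
#' elevated outlet tube of height `outlet_head` adds a gauge pressure
#' \eqn{\rho g h} at the channel exit, and the outlet tubing itself
#' contributes a (sub-pascal) laminar friction term
#' \eqn{\mu Q L_t \, C / (\pi D^4)} with `C = tube_friction_coefficient`.
#'
#' @param flow_rate Volumetric flow rate \eqn{Q} in m^3 s^-1 (see [uL_min()]).
#' @param outlet_head Height \eqn{h} of the outlet tube above the inlet, in
#'   metres.
#' @param tube_diameter Inner diameter \eqn{D} of the outlet tubing (m).
#' @param tube_length Length of the outlet tubing (m).
#' @param gravity Gravitational acceleration (m s^-2).
#' @param include_tube_friction Include the tubing friction term in the outlet
#'   gauge pressure? The term is reported separately either way.
#' @param label Optional condition label (e.g. `"SS high+HP"`).
#' @return An object of class `flow_condition`.
#' @export
flow_condition <- function(flow_rate, outlet_head = 0, tube_diameter = 1e-3,
                           tube_length = 0.5, gravity = 9.81,
                           include_tube_friction = FALSE, label = NULL) {
  stopifnot(is.numeric(flow_rate), length(flow_rate) == 1L)
  if (flow_rate < 0) stop("flow rate must be non-negative", call. = FALSE)
  if (outlet_head < 0) stop("outlet head must be non-negative", call. = FALSE)
  if (tube_diameter <= 0 || gravity <= 0 || tube_length < 0)
    stop("invalid tube/gravity parameters", call. = FALSE)
  structure(list(flow_rate = flow_rate, outlet_head = outlet_head,
                 tube_diameter = tube_diameter, tube_length = tube_length,
                 gravity = gravity,
                 include_tube_friction = isTRUE(include_tube_friction),
                 label = label),
            class = "flow_condition")
}

#' Series evaluation control
#'
#' The velocity and wall-shear series are truncated at `n_terms` terms, or
#' earlier once the last term's relative contribution falls below
#' `convergence_tol`.
#'
#' @param n_terms Maximum number of series terms (>= 1).
#' @param convergence_tol Relative early-stopping tolerance.
#' @return An object of class `series_control`.
#' @export
series_control <- function(n_terms = 500L, convergence_tol = 1e-12) {
  n_terms <- as.integer(n_terms)
  if (is.na(n_terms) || n_terms < 1L) stop("n_terms must be >= 1", call. = FALSE)
  if (convergence_tol < 0) stop("convergence_tol must be >= 0", call. = FALSE)
  structure(list(n_terms = n_terms, convergence_tol = convergence_tol),
            class = "series_control")
}

#' Laminar friction coefficient of the outlet tubing pressure-drop term
#'
#' The outlet tubing friction pressure drop is written
#' \eqn{\mu Q L_t \, C / (\pi D^4)} with \eqn{C} this constant (32). For the
#' flow rates of interest the whole term is below 1 Pa, i.e. negligible
#' against the hydrostatic head.
#' @export
tube_friction_coefficient <- 32

# cosh(a)/cosh(b) for 0 <= |a| <= b, stable for large arguments; vectorised
# over a (b scalar)
.cosh_ratio <- function(a, b) {
  a <- abs(a)
  if (b < 30) return(cosh(a) / cosh(b))
  exp(a - b) * (1 + exp(-2 * a)) / (1 + exp(-2 * b))
}

#' Cross-sectional mean velocity
#'
#' \eqn{u_m = Q / (2W \times 2H)}: flow rate over cross-sectional area.
#'
#' @param geom A [channel_geometry()].
#' @param Q Flow rate in m^3 s^-1.
#' @return Mean velocity in m s^-1.
#' @examples
#' mean_velocity(channel_geometry(), uL_min(13))  # 2.1667e-3 m/s
#' @export
mean_velocity <- function(geom, Q) {
  stopifnot(inherits(geom, "channel_geometry"))
  if (any(Q < 0)) stop("flow rate must be non-negative", call. = FALSE)
  Q / (4 * geom$W * geom$H)
}

#' Series normalisation constant c1 of the duct velocity field
#'
#' Evaluates
#' \deqn{c_1 = \frac{-3 u_m / W^2}{1 - \frac{192}{\pi^5}\frac{W}{H}
#'   \sum_{n \ge 0} \frac{\tanh((2n+1)\pi H / 2W)}{(2n+1)^5}}}
#' which ties the separable cosine/cosh series for the axial velocity to the
#' prescribed mean velocity. The bracketed denominator tends to zero for very
#' wide channels (W >> H along the series axis), in which case the geometry is
#' ill-conditioned for this expansion and an error is raised.
#'
#' @param geom A [channel_geometry()].
#' @param um Mean velocity (m s^-1), from [mean_velocity()].
#' @param ctrl A [series_control()].
#' @return `c1` (m^-1 s^-1), with attribute `n_terms` giving the number of
#'   series terms actually summed.
#' @export
series_c1 <- function(geom, um, ctrl = series_control()) {
  stopifnot(inherits(geom, "channel_geometry"), inherits(ctrl, "series_control"))
  if (!is.finite(um)) stop("mean velocity must be finite", call. = FALSE)
  W <- geom$W; H <- geom$H
  s <- 0; used <- 0L
  for (n in seq_len(ctrl$n_terms) - 1L) {
    term <- tanh((2 * n + 1) * pi * H / (2 * W)) / (2 * n + 1)^5
    s <- s + term
    used <- n + 1L
    if (s > 0 && term / s < ctrl$convergence_tol) break
  }
  bracket <- 1 - 192 / pi^5 * (W / H) * s
  if (bracket <= 1e-6)
    stop("ill-conditioned geometry: series denominator ", format(bracket),
         " is at or below the positive floor (channel too wide for this ",
         "series orientation)", call. = FALSE)
  structure(-3 * um / W^2 / bracket, n_terms = used)
}

# shared series evaluator: sum_n coef(n) * f_n(x[, y]) with early stopping
.duct_series <- function(x, ctrl, term_fun) {
  acc <- numeric(length(x))
  for (n in seq_len(ctrl$n_terms) - 1L) {
    t_n <- term_fun(n)
    acc <- acc + t_n
    sc <- max(abs(acc))
    if (sc > 0 && max(abs(t_n)) / sc < ctrl$convergence_tol) break
  }
  acc
}

#' Axial velocity at a point of the cross-section
#'
#' Evaluates the separable series solution of the Stokes duct problem,
#' \deqn{u(x, y) = \frac{-16 c_1 W^2}{\pi^3} \sum_{n \ge 0}
#'   \frac{(-1)^n}{(2n+1)^3}
#'   \left[1 - \frac{\cosh((2n+1)\pi y / 2W)}{\cosh((2n+1)\pi H / 2W)}\right]
#'   \cos\!\left(\frac{(2n+1)\pi x}{2W}\right),}
#' vectorised over `x` and `y` (recycled to a common length).
#'
#' @inheritParams series_c1
#' @param c1 Normalisation constant from [series_c1()].
#' @param x,y Cross-section coordinates in metres; must satisfy
#'   \eqn{|x| \le W}, \eqn{|y| \le H}.
#' @return Axial velocity (m s^-1).
#' @export
velocity_at <- function(geom, c1, x, y, ctrl = series_control()) {
  stopifnot(inherits(geom, "channel_geometry"))
  W <- geom$W; H <- geom$H
  n_out <- max(length(x), length(y))
  x <- rep_len(x, n_out); y <- rep_len(y, n_out)
  if (any(abs(x) > W + 1e-15) || any(abs(y) > H + 1e-15))
    stop("point outside the channel cross-section", call. = FALSE)
  u <- .duct_series(x, ctrl, function(n) {
    k <- (2 * n + 1) * pi / (2 * W)
    ratio <- .cosh_ratio(k * y, k * H)
    (-1)^n / (2 * n + 1)^3 * (1 - ratio) * cos(k * x)
  })
  -16 * c1 * W^2 / pi^3 * u
}

#' Wall shear stress magnitude on the bottom wall
#'
#' Termwise differentiation of the velocity series at \eqn{y = -H} gives the
#' bottom-wall shear stress
#' \eqn{\tau(x) = \mu \, \partial u / \partial y |_{y=-H}}, reported as a
#' magnitude:
#' \deqn{\tau(x) = \left| \frac{16 \mu c_1 W^2}{\pi^3} \sum_{n \ge 0}
#'   \frac{(-1)^n}{(2n+1)^3} \frac{(2n+1)\pi}{2W}
#'   \tanh\!\left(\frac{(2n+1)\pi H}{2W}\right)
#'   \cos\!\left(\frac{(2n+1)\pi x}{2W}\right) \right|.}
#'
#' @inheritParams velocity_at
#' @param fl A [fluid()].
#' @param x Positions along the bottom wall (m), \eqn{|x| \le W}; vectorised.
#' @return Shear stress magnitude (Pa).
#' @export
wss_bottom <- function(geom, fl, c1, x, ctrl = series_control()) {
  stopifnot(inherits(geom, "channel_geometry"), inherits(fl, "fluid"))
  W <- geom$W; H <- geom$H
  if (any(abs(x) > W + 1e-15))
    stop("position outside the bottom wall", call. = FALSE)
  s <- .duct_series(x, ctrl, function(n) {
    k <- (2 * n + 1) * pi / (2 * W)
    (-1)^n / (2 * n + 1)^3 * k * tanh(k * H) * cos(k * x)
  })
  abs(fl$viscosity * 16 * c1 * W^2 / pi^3 * s)
}

#' Bottom-wall shear stress profile across the channel width
#'
#' Uniformly samples [wss_bottom()] on \eqn{[-W, W]}. The peak is attained at
#' the centreline \eqn{x = 0} for this geometry.
#'
#' @inheritParams wss_bottom
#' @param Q Flow rate (m^3 s^-1).
#' @param n_samples Number of sample positions (>= 3).
#' @return A list with `x` (m), `tau` (Pa) and `peak` (Pa).
#' @export
wss_profile <- function(geom, fl, Q, n_samples = 201L,
                        ctrl = series_control()) {
  if (n_samples < 3L) stop("n_samples must be >= 3", call. = FALSE)
  x <- seq(-geom$W, geom$W, length.out = n_samples)
  if (Q == 0) return(list(x = x, tau = numeric(n_samples), peak = 0))
  c1 <- series_c1(geom, mean_velocity(geom, Q), ctrl)
  tau <- wss_bottom(geom, fl, c1, x, ctrl)
  list(x = x, tau = tau, peak = max(tau))
}

#' Hydraulic diameter of the rectangular cross-section
#'
#' \eqn{D_h = 4 A / P = 4 (2W)(2H) / (2(2W + 2H))}, the standard
#' area-over-wetted-perimeter definition. Symmetric in W and H.
#'
#' @inheritParams mean_velocity
#' @return Hydraulic diameter (m).
#' @export
hydraulic_diameter <- function(geom) {
  stopifnot(inherits(geom, "channel_geometry"))
  4 * geom$W * geom$H / (geom$W + geom$H)
}

#' Reynolds number of the channel flow
#'
#' \eqn{Re = \rho u_m D_h / \mu}.
#'
#' @inheritParams wss_profile
#' @return Reynolds number (dimensionless).
#' @export
reynolds_number <- function(geom, fl, Q) {
  fl$density * mean_velocity(geom, Q) * hydraulic_diameter(geom) / fl$viscosity
}

#' Laminar friction factor of a rectangular duct
#'
#' The aspect-ratio polynomial correlation
#' \deqn{\lambda = \frac{96}{Re}\left(1 - 1.3553\alpha^{-1} + 1.9467\alpha^{-2}
#'   - 1.7012\alpha^{-3} + 0.9564\alpha^{-4} - 0.2537\alpha^{-5}\right)}
#' valid for the wider-than-tall orientation \eqn{\alpha = W/H \ge 1}; in the
#' parallel-plate limit \eqn{\alpha \to \infty}, \eqn{\lambda Re \to 96}.
#'
#' @param alpha Aspect ratio \eqn{W/H \ge 1}.
#' @param Re Reynolds number (> 0).
#' @return Friction factor \eqn{\lambda} (dimensionless).
#' @export
friction_factor <- function(alpha, Re) {
  if (any(alpha < 1)) stop("aspect ratio must be >= 1 (pass the wider-than-tall orientation)",
                           call. = FALSE)
  if (any(Re <= 0)) stop("Reynolds number must be > 0", call. = FALSE)
  96 / Re * (1 - 1.3553 / alpha + 1.9467 / alpha^2 - 1.7012 / alpha^3 +
               0.9564 / alpha^4 - 0.2537 / alpha^5)
}

#' Axial pressure gradient from the friction-factor model
#'
#' \eqn{dp/dz = \lambda \rho u_m^2 / (2 D_h)}, with \eqn{\lambda} from
#' [friction_factor()] at \eqn{\alpha = \max(W/H, H/W)} and
#' \eqn{Re = \rho u_m D_h / \mu}. Because \eqn{\lambda \propto 1/Re}, the
#' gradient is linear in both Q and viscosity. `Q = 0` returns 0 without
#' touching the \eqn{1/Re} path.
#'
#' @inheritParams wss_profile
#' @return Pressure gradient (Pa m^-1), as a positive magnitude.
#' @export
pressure_gradient <- function(geom, fl, Q) {
  if (Q == 0) return(0)
  um <- mean_velocity(geom, Q)
  Dh <- hydraulic_diameter(geom)
  alpha <- max(geom$W / geom$H, geom$H / geom$W)
  Re <- reynolds_number(geom, fl, Q)
  friction_factor(alpha, Re) * fl$density * um^2 / (2 * Dh)
}

#' Pressure difference along the channel
#'
#' \eqn{\Delta P = (dp/dz) \cdot L}.
#'
#' @inheritParams pressure_gradient
#' @return Pressure difference (Pa).
#' @export
channel_delta_p <- function(geom, fl, Q) {
  pressure_gradient(geom, fl, Q) * geom$L
}

#' Outlet gauge pressure from the hydrostatic head and tubing friction
#'
#' \eqn{P_{out} - P_{atm} = \rho g h \, [+\, \mu Q L_t C / (\pi D^4)]}, with
#' the tubing friction term (coefficient `C =`
#' [tube_friction_coefficient]) added only when the condition requests it.
#' The term is returned separately so callers can confirm it is negligible
#' (< 1 Pa at these flow rates).
#'
#' @param fl A [fluid()].
#' @param cond A [flow_condition()].
#' @return A list with `total`, `hydrostatic` and `friction` gauge pressures
#'   (Pa). `total` includes `friction` only if
#'   `cond$include_tube_friction` is TRUE.
#' @examples
#' outlet_gauge_pressure(fluid(), flow_condition(uL_min(13), outlet_head = 0.4))
#' @export
outlet_gauge_pressure <- function(fl, cond) {
  stopifnot(inherits(fl, "fluid"), inherits(cond, "flow_condition"))
  hydro <- fl$density * cond$gravity * cond$outlet_head
  fric <- fl$viscosity * cond$flow_rate * cond$tube_length *
    tube_friction_coefficient / (pi * cond$tube_diameter^4)
  total <- hydro + if (cond$include_tube_friction) fric else 0
  list(total = total, hydrostatic = hydro, friction = fric)
}

#' Gauge pressure profile along the channel
#'
#' Affine profile \eqn{p(z) = P_{out,gauge} + (L - z) \, dp/dz}, monotone
#' non-increasing from inlet (z = 0) to outlet (z = L).
#'
#' @inheritParams pressure_gradient
#' @param cond A [flow_condition()].
#' @param n_samples Number of z samples (>= 2).
#' @return A list with `z` (m), `p` (Pa, gauge), `inlet_gauge`,
#'   `outlet_gauge` and `dpdz`.
#' @export
pressure_profile <- function(geom, fl, cond, n_samples = 100L) {
  if (n_samples < 2L) stop("n_samples must be >= 2", call. = FALSE)
  z <- seq(0, geom$L, length.out = n_samples)
  pout <- outlet_gauge_pressure(fl, cond)$total
  dpdz <- pressure_gradient(geom, fl, cond$flow_rate)
  p <- pout + (geom$L - z) * dpdz
  list(z = z, p = p, inlet_gauge = pout + geom$L * dpdz, outlet_gauge = pout,
       dpdz = dpdz)
}

#' Full hemodynamic report for one flow condition
#'
#' Gathers the derived flow quantities for one channel/fluid/condition
#' combination: mean velocity, series constant, bottom-wall shear-stress
#' profile and peak, hydraulic diameter, Reynolds number, friction factor,
#' axial pressure gradient, channel pressure difference, and inlet/outlet
#' gauge pressures with the sampled axial profile.
#'
#' @inheritParams pressure_profile
#' @param ctrl A [series_control()].
#' @param n_samples Samples for the shear and pressure profiles.
#' @return An object of class `hemodynamics_report`.
#' @export
hemodynamics_report <- function(geom, fl, cond, ctrl = series_control(),
                                n_samples = 201L) {
  Q <- cond$flow_rate
  um <- mean_velocity(geom, Q)
  c1 <- if (Q > 0) series_c1(geom, um, ctrl) else structure(0, n_terms = 0L)
  wss <- wss_profile(geom, fl, Q, n_samples, ctrl)
  pp <- pressure_profile(geom, fl, cond, max(2L, n_samples))
  Re <- if (Q > 0) reynolds_number(geom, fl, Q) else 0
  lam <- if (Q > 0)
    friction_factor(max(geom$W / geom$H, geom$H / geom$W), Re) else NA_real_
  structure(list(
    label = cond$label, flow_rate = Q, mean_velocity = um, c1 = as.numeric(c1),
    wss_x = wss$x, wss = wss$tau, peak_wss = wss$peak,
    hydraulic_diameter = hydraulic_diameter(geom), reynolds = Re,
    friction_factor = lam, pressure_gradient = pp$dpdz,
    channel_delta_p = pp$dpdz * geom$L,
    outlet_gauge = pp$outlet_gauge, inlet_gauge = pp$inlet_gauge,
    pressure_z = pp$z, pressure = pp$p,
    series_terms = attr(c1, "n_terms")), class = "hemodynamics_report")
}

#' @export
print.hemodynamics_report <- function(x, ...) {
  cat("Hemodynamics report", if (!is.null(x$label)) paste0("(", x$label, ")"),
      "\n")
  cat(sprintf("  Q          = %.4g uL/min\n", x$flow_rate / 1e-9 * 60))
  cat(sprintf("  u_m        = %.4g m/s\n", x$mean_velocity))
  cat(sprintf("  peak WSS   = %.3g Pa\n", x$peak_wss))
  cat(sprintf("  Re         = %.3g\n", x$reynolds))
  cat(sprintf("  dp/dz      = %.4g Pa/m\n", x$pressure_gradient))
  cat(sprintf("  delta P    = %.4g Pa\n", x$channel_delta_p))
  cat(sprintf("  inlet  (g) = %.6g Pa\n", x$inlet_gauge))
  cat(sprintf("  outlet (g) = %.6g Pa\n", x$outlet_gauge))
  invisible(x)
}

#' Summarise a set of flow conditions
#'
#' One row per condition: flow rate, peak bottom-wall WSS, channel pressure
#' difference, and outlet/inlet gauge pressures. With the four standard
#' perfusion conditions (two flow rates, with and without a raised outlet)
#' this reproduces the experiment summary table.
#'
#' @inheritParams hemodynamics_report
#' @param conditions A list of [flow_condition()] objects (>= 1).
#' @return A data.frame with columns `label`, `flow_rate_ul_min`,
#'   `peak_wss_pa`, `delta_p_pa`, `outlet_gauge_pa`, `inlet_gauge_pa`.
#' @export
summarize_conditions <- function(geom, fl, conditions,
                                 ctrl = series_control()) {
  if (!length(conditions)) stop("need at least one condition", call. = FALSE)
  if (inherits(conditions, "flow_condition")) conditions <- list(conditions)
  rows <- lapply(seq_along(conditions), function(i) {
    r <- hemodynamics_report(geom, fl, conditions[[i]], ctrl)
    data.frame(label = if (is.null(r$label)) paste0("condition_", i) else r$label,
               flow_rate_ul_min = r$flow_rate / 1e-9 * 60,
               peak_wss_pa = r$peak_wss, delta_p_pa = r$channel_delta_p,
               outlet_gauge_pa = r$outlet_gauge, inlet_gauge_pa = r$inlet_gauge,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
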