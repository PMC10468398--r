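# Transient 1-D finite-volume Nernst-Planck solver for the five-compartment
# droplet chain (high-salt | cation-selective | low-salt | anion-selective |
# high-salt) with two monovalent species (K+ / Cl-, as in the published
# simulation setup).
#
# Discretization: conservative finite volumes with Scharfetter-Gummel face
# fluxes and explicit time stepping under a CFL bound. The potential is
# closed either algebraically ("electroneutral": the face potential drops
# are solved so that the total ionic current is spatially uniform and equal
# to the circuit current, which keeps F*(cK - cCl) + rho_fix exactly
# invariant) or by a Poisson solve with an artificially enlarged
# permittivity ("poisson_scaled", open-circuit only) so that interface
# space-charge layers are resolvable on micrometre grids.
#
# Electrodes are ideal non-polarizable Ag/AgCl: they exchange Cl- only, so
# the terminal voltage is phi(right) - phi(left) - (RT/F) ln(cCl_R/cCl_L)
# and the boundary Cl- flux carries the full circuit current.

# Bernoulli function B(x) = x / (exp(x) - 1), numerically stable
.bernoulli <- function(x) {
  out <- x / expm1(x)
  small <- abs(x) < 1e-8
  out[small] <- 1 - x[small] / 2
  out
}

# dB/dx, stable near 0
.bernoulli_d <- function(x) {
  small <- abs(x) < 1e-5
  ex <- expm1(x)
  out <- (ex - x * (ex + 1)) / ex^2
  out[small] <- -0.5 + x[small] / 6
  out
}

#' Solver configuration for the droplet-chain transport simulation
#'
#' @param mode one of `"open_circuit"`, `"short_circuit"`, `"load"`,
#'   `"applied_potential"`.
#' @param cells_per_region finite-volume cells per droplet compartment.
#' @param t_start_s,t_end_s simulated time span in seconds (the published
#'   transient analysis covers 0-1,800 s).
#' @param dt_max_s upper bound on the adaptive time step.
#' @param cfl stability fraction of the explicit step limit, in (0, 1).
#' @param r_ext_kOhm external load for `mode = "load"`.
#' @param applied_mV terminal voltage for `mode = "applied_potential"`;
#'   negative values reverse the discharge polarity (recharging).
#' @param sample_interval_s spacing of recorded trace samples.
#' @param coupling `"electroneutral"` (default) or `"poisson_scaled"`
#'   (open-circuit only; see Details).
#' @param permittivity_scale multiplier on the aqueous permittivity in
#'   `"poisson_scaled"` coupling, enlarging the Debye length to a
#'   grid-resolvable scale.
#' @param newton_tol relative tolerance of the per-face current solve.
#' @param max_iter iteration caps for the face and circuit solves.
#' @return An object of class `npp_config`.
#' @details True electric double layers at the membrane interfaces are
#'   nanometres thick and cannot be resolved on a grid spanning hundreds of
#'   micrometres; the electroneutral closure treats them as sharp Donnan
#'   steps, while the scaled-permittivity Poisson closure smears them over
#'   an artificial Debye length for verification of the interface
#'   equilibria. All quantitative discharge results use the electroneutral
#'   closure.
#' @export
npp_config <- function(mode = c("open_circuit", "short_circuit", "load",
                                "applied_potential"),
                       cells_per_region = 12,
                       t_start_s = 0, t_end_s = 1800,
                       dt_max_s = 0.5, cfl = 0.4,
                       r_ext_kOhm = NULL, applied_mV = NULL,
                       sample_interval_s = 1,
                       coupling = c("electroneutral", "poisson_scaled"),
                       permittivity_scale = 4e7,
                       newton_tol = 1e-10, max_iter = 60) {
  mode <- match.arg(mode)
  coupling <- match.arg(coupling)
  if (cells_per_region < 2) stop_invalid("need at least 2 cells per region")
  if (t_end_s < t_start_s) stop_invalid("time span end before start")
  if (dt_max_s <= 0 || cfl <= 0 || cfl >= 1)
    stop_invalid("need dt_max_s > 0 and cfl in (0, 1)")
  if (newton_tol <= 0) stop_invalid("tolerances must be positive")
  if (mode == "load" && (is.null(r_ext_kOhm) || r_ext_kOhm <= 0))
    stop_invalid("mode 'load' needs a positive r_ext_kOhm")
  if (mode == "applied_potential" && is.null(applied_mV))
    stop_invalid("mode 'applied_potential' needs applied_mV")
  if (coupling == "poisson_scaled" && mode != "open_circuit")
    stop_invalid("poisson_scaled coupling supports open_circuit mode only")
  structure(list(
    mode = mode, cells_per_region = as.integer(cells_per_region),
    t_start_s = t_start_s, t_end_s = t_end_s, dt_max_s = dt_max_s,
    cfl = cfl, r_ext_kOhm = r_ext_kOhm, applied_mV = applied_mV,
    sample_interval_s = sample_interval_s, coupling = coupling,
    permittivity_scale = permittivity_scale,
    newton_tol = newton_tol, max_iter = as.integer(max_iter)
  ), class = "npp_config")
}

#' Build the 1-D finite-volume grid of a power unit
#'
#' Maps the five droplets to contiguous 1-D regions: each region's length
#' is the droplet thickness (one sphere diameter by default) and its
#' transport cross-section is the droplet contact area, while each cell's
#' storage volume is its share of the full droplet volume (the droplet
#' bulges beyond the contact cylinder, and that salt inventory governs
#' both the discharge capacity and the gradient run-down). Fixed charge is
#' nonzero only in the two selective regions.
#'
#' @param unit a [power_unit()].
#' @param config an [npp_config()].
#' @return An object of class `npp_grid`.
#' @export
build_grid <- function(unit, config = npp_config()) {
  stopifnot(inherits(unit, "power_unit"), inherits(config, "npp_config"))
  m <- config$cells_per_region
  lens <- vapply(unit$droplets, `[[`, numeric(1), "thickness_m")
  areas <- vapply(unit$droplets, `[[`, numeric(1), "contact_area_m2")
  fixq <- vapply(unit$droplets, `[[`, numeric(1), "fixed_charge_Cm3")
  if (any(lens <= 0) || any(areas <= 0))
    stop_invalid("degenerate droplet geometry in grid construction")
  n <- 5L * m
  region <- rep(seq_len(5L), each = m)
  h <- rep(lens / m, each = m)
  x <- cumsum(h) - h / 2
  area_cell <- rep(areas, each = m)
  dxf <- (h[-n] + h[-1]) / 2                      # interior face spacing
  area_face <- c(area_cell[1],
                 2 / (1 / area_cell[-n] + 1 / area_cell[-1]),
                 area_cell[n])
  vols <- vapply(unit$droplets, `[[`, numeric(1), "volume_nl") * 1e-12
  structure(list(
    n = n, region = region, h = h, x = x, dxf = dxf,
    area_cell = area_cell, area_face = area_face,
    vol_cell = rep(vols / m, each = m),
    fix_mol = rep(fixq, each = m) / FARADAY,      # signed mol m^-3
    D = c(K = unit$salt$cation_diffusivity,
          Cl = unit$salt$anion_diffusivity),
    temperature_K = unit$temperature_K,
    c_high = unit$c_high * 1000, c_low = unit$c_low * 1000  # mol m^-3
  ), class = "npp_grid")
}

#' Initial field state of a grid
#'
#' Non-selective compartments start at their nominal salt concentrations;
#' selective compartments start at Donnan equilibrium with the low-salt
#' compartment (counter-ion at the fixed-site concentration plus the
#' excluded co-ion). The potential starts at the zero-current solution.
#'
#' @param grid an [npp_grid()].
#' @return An object of class `npp_state` with per-cell concentrations
#'   `cK`, `cCl` (mol m^-3), potential `phi` (V, referenced to the left
#'   electrode), time `time_s` and the instantaneous current `I_uA`.
#' @export
init_state <- function(grid) {
  stopifnot(inherits(grid, "npp_grid"))
  csalt <- ifelse(grid$region %in% c(1L, 5L), grid$c_high,
                  ifelse(grid$region == 3L, grid$c_low, NA_real_))
  cK <- cCl <- csalt
  sel <- is.na(csalt)
  X <- abs(grid$fix_mol[sel])
  co <- (-X + sqrt(X^2 + 4 * grid$c_low^2)) / 2   # excluded co-ion
  cat_sel <- grid$fix_mol[sel] < 0
  cK[sel] <- ifelse(cat_sel, co + X, co)
  cCl[sel] <- ifelse(cat_sel, co, co + X)
  st <- structure(list(cK = cK, cCl = cCl, phi = numeric(grid$n),
                       time_s = 0, I_uA = 0,
                       w_face = numeric(grid$n - 1L)),
                  class = "npp_state")
  ft <- thermal_voltage(grid$temperature_K)
  w <- .solve_faces(grid, st$cK, st$cCl, 0, st$w_face)
  st$w_face <- w
  st$phi <- c(0, cumsum(w)) * ft
  st
}

# Solve the face potential rises w = F(phi_R - phi_L)/RT so that every face
# carries current I_A. Vectorized damped Newton; g(w) strictly decreasing.
.solve_faces <- function(grid, cK, cCl, I_A, w0, tol = 1e-10, max_iter = 60) {
  n <- grid$n
  a <- grid$D[["K"]] * cK[-n] + grid$D[["Cl"]] * cCl[-1]
  b <- grid$D[["K"]] * cK[-1] + grid$D[["Cl"]] * cCl[-n]
  G <- I_A * grid$dxf / (FARADAY * grid$area_face[2:n])
  w <- w0
  scale <- a + b + abs(G)
  for (it in seq_len(max_iter)) {
    Bw <- .bernoulli(w)
    r <- Bw * (a - b) - w * b - G
    if (all(abs(r) <= tol * scale)) return(w)
    dr <- .bernoulli_d(w) * (a - b) - b
    step <- r / dr
    step <- pmin(pmax(step, -5), 5)
    w <- w - step
  }
  stop("solver failure: face potential Newton did not converge (max |res| = ",
       signif(max(abs(r / scale)), 3), ")", call. = FALSE)
}

# Scharfetter-Gummel face fluxes (mol m^-2 s^-1) for both species at all
# n+1 faces, given face potential rises w (interior) and circuit current.
.face_fluxes <- function(grid, cK, cCl, w, I_A) {
  n <- grid$n
  DK <- grid$D[["K"]]; DCl <- grid$D[["Cl"]]
  JK_i <- (DK / grid$dxf) *
    (.bernoulli(w) * cK[-n] - .bernoulli(-w) * cK[-1])
  JCl_i <- (DCl / grid$dxf) *
    (.bernoulli(-w) * cCl[-n] - .bernoulli(w) * cCl[-1])
  # electrodes: K+ blocked, Cl- carries the Faradaic current
  JCl_b1 <- -I_A / (FARADAY * grid$area_face[1])
  JCl_bn <- -I_A / (FARADAY * grid$area_face[n + 1L])
  list(JK = c(0, JK_i, 0), JCl = c(JCl_b1, JCl_i, JCl_bn))
}

# terminal voltage (V) for a solved face profile
.terminal_voltage <- function(grid, cCl, w) {
  ft <- thermal_voltage(grid$temperature_K)
  ft * sum(w) - ft * log(cCl[grid$n] / cCl[1])
}

# circuit current (A) for the configured mode, by secant iteration on the
# terminal condition; returns list(I_A, w)
.solve_circuit <- function(grid, cK, cCl, st_w, I_prev, config) {
  target <- function(I_A) switch(config$mode,
    short_circuit = 0,
    load = I_A * config$r_ext_kOhm * 1000,
    applied_potential = config$applied_mV / 1000)
  if (config$mode == "open_circuit") {
    w <- .solve_faces(grid, cK, cCl, 0, st_w, config$newton_tol,
                      config$max_iter)
    return(list(I_A = 0, w = w))
  }
  f <- function(I_A, w_init) {
    w <- .solve_faces(grid, cK, cCl, I_A, w_init, config$newton_tol,
                      config$max_iter)
    list(r = .terminal_voltage(grid, cCl, w) - target(I_A), w = w)
  }
  I0 <- I_prev
  e0 <- f(I0, st_w)
  I1 <- if (abs(I0) > 1e-12) I0 * 1.02 else 1e-8
  e1 <- f(I1, e0$w)
  for (it in seq_len(config$max_iter)) {
    if (abs(e1$r) < 1e-10) break
    dI <- (I1 - I0) / (e1$r - e0$r) * e1$r
    if (!is.finite(dI)) break
    I0 <- I1; e0 <- e1
    I1 <- I1 - dI
    e1 <- f(I1, e0$w)
  }
  if (abs(e1$r) > 1e-7)
    stop("solver failure: circuit current iteration stalled (residual ",
         signif(e1$r, 3), " V)", call. = FALSE)
  list(I_A = I1, w = e1$w)
}

# one explicit conservative update; returns the new state
.npp_step_en <- function(grid, st, config) {
  sol <- .solve_circuit(grid, st$cK, st$cCl, st$w_face, st$I_uA * 1e-6,
                        config)
  fl <- .face_fluxes(grid, st$cK, st$cCl, sol$w, sol$I_A)
  n <- grid$n
  dt <- min(config$dt_max_s, .cfl_dt(grid, sol$w, config$cfl),
            config$t_end_s - st$time_s)
  AJK <- grid$area_face * fl$JK
  AJCl <- grid$area_face * fl$JCl
  inv <- dt / grid$vol_cell
  cK <- st$cK + inv * (AJK[-(n + 1L)] - AJK[-1])
  cCl <- st$cCl + inv * (AJCl[-(n + 1L)] - AJCl[-1])
  ft <- thermal_voltage(grid$temperature_K)
  structure(list(cK = cK, cCl = cCl, phi = c(0, cumsum(sol$w)) * ft,
                 time_s = st$time_s + dt, I_uA = sol$I_A * 1e6,
                 V_mV = 1000 * .terminal_voltage(grid, st$cCl, sol$w),
                 w_face = sol$w),
            class = "npp_state")
}

# explicit stability bound: per cell, the outflow coefficient
# D * sum_faces A (1 + |w|) / dxf must not exceed cfl * V_cell / dt
.cfl_dt <- function(grid, w, cfl) {
  n <- grid$n
  term <- grid$area_face[2:n] * (1 + abs(w)) / grid$dxf
  coef <- numeric(n)
  coef[-n] <- term
  coef[-1] <- coef[-1] + term
  cfl / max(max(grid$D) * coef / grid$vol_cell)
}

# tridiagonal solve (Thomas algorithm)
.thomas <- function(lower, diag, upper, rhs) {
  n <- length(diag)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- upper[1] / diag[1]
  dp[1] <- rhs[1] / diag[1]
  for (i in 2:n) {
    m <- diag[i] - lower[i - 1] * cp[i - 1]
    cp[i] <- if (i < n) upper[i] / m else 0
    dp[i] <- (rhs[i] - lower[i - 1] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

# one explicit step under scaled-permittivity Poisson coupling
# (open circuit: both species blocked at the electrodes, phi(left) = 0,
# zero field at the right electrode)
.npp_step_poisson <- function(grid, st, config) {
  n <- grid$n
  eps <- config$permittivity_scale * 78.5 * 8.8541878128e-12
  rho <- FARADAY * (st$cK - st$cCl) + grid$fix_mol * FARADAY
  # -eps * d2phi/dx2 = rho on cell centres
  hl <- c(Inf, grid$dxf)      # spacing to left neighbour
  hr <- c(grid$dxf, Inf)      # spacing to right neighbour
  al <- eps / (hl * grid$h); ar <- eps / (hr * grid$h)
  dg <- al + ar
  rhs <- rho
  # phi(1) anchored to 0 through a strong diagonal, zero-field right end
  dg[1] <- dg[1] + eps / (grid$h[1] / 2) / grid$h[1]
  phi <- .thomas(-al[-1], dg, -ar[-n], rhs)
  ft <- thermal_voltage(grid$temperature_K)
  w <- (phi[-1] - phi[-n]) / ft
  fl <- .face_fluxes(grid, st$cK, st$cCl, w, 0)
  sigma <- FARADAY^2 / (GAS_CONSTANT * grid$temperature_K) *
    (grid$D[["K"]] * st$cK + grid$D[["Cl"]] * st$cCl)
  dt <- min(config$dt_max_s, .cfl_dt(grid, w, config$cfl),
            0.5 * eps / max(sigma), config$t_end_s - st$time_s)
  AJK <- grid$area_face * fl$JK
  AJCl <- grid$area_face * fl$JCl
  inv <- dt / grid$vol_cell
  structure(list(cK = st$cK + inv * (AJK[-(n + 1L)] - AJK[-1]),
                 cCl = st$cCl + inv * (AJCl[-(n + 1L)] - AJCl[-1]),
                 phi = phi - phi[1], time_s = st$time_s + dt,
                 I_uA = 0,
                 V_mV = 1000 * .terminal_voltage(grid, st$cCl, w),
                 w_face = w),
            class = "npp_state")
}

#' Advance the transport state by one time step
#'
#' @param state an [init_state()] result (or a previously stepped state).
#' @param grid the matching [build_grid()] grid.
#' @param config an [npp_config()].
#' @return the advanced `npp_state`.
#' @export
npp_step <- function(state, grid, config = npp_config()) {
  stopifnot(inherits(state, "npp_state"), inherits(grid, "npp_grid"))
  if (config$coupling == "poisson_scaled")
    .npp_step_poisson(grid, state, config)
  else .npp_step_en(grid, state, config)
}

#' Nernst-Planck face fluxes of a state
#'
#' Evaluates the Scharfetter-Gummel flux
#' `J = -D (dc/dx + (zF/RT) c dphi/dx)` of one species at the interior
#' faces, from the state's concentrations and potential.
#'
#' @param state an `npp_state`.
#' @param grid the matching `npp_grid`.
#' @param species `"K"` (cation, z = +1) or `"Cl"` (anion, z = -1).
#' @return fluxes in mol m^-2 s^-1 at the `n - 1` interior faces.
#' @export
npp_flux <- function(state, grid, species = c("K", "Cl")) {
  species <- match.arg(species)
  n <- grid$n
  ft <- thermal_voltage(grid$temperature_K)
  w <- (state$phi[-1] - state$phi[-n]) / ft
  D <- grid$D[[species]]
  cc <- if (species == "K") state$cK else state$cCl
  delta <- if (species == "K") w else -w
  (D / grid$dxf) *
    (.bernoulli(delta) * cc[-n] - .bernoulli(-delta) * cc[-1])
}

#' Total ionic current through each interior face
#'
#' `I = A F (J_K - J_Cl)` per face. At steady operating points the current
#' is spatially uniform; the spread across faces is a consistency
#' diagnostic of the potential solve.
#'
#' @inheritParams npp_flux
#' @return currents in uA at the interior faces.
#' @export
compute_current <- function(state, grid) {
  jk <- npp_flux(state, grid, "K")
  jcl <- npp_flux(state, grid, "Cl")
  grid$area_face[2:grid$n] * FARADAY * (jk - jcl) * 1e6
}

#' Run a transient discharge (or recharge) simulation
#'
#' Integrates the droplet-chain transport equations over the configured
#' time span and mode, recording the terminal voltage, circuit current and
#' cumulative released charge.
#'
#' @param unit a [power_unit()] (ignored when `state` and `grid` are both
#'   supplied).
#' @param config an [npp_config()].
#' @param state optional starting `npp_state` (to continue a run).
#' @param grid optional prebuilt `npp_grid`.
#' @return A `trace_result`: data.frame with columns `t_s`, `V_mV`, `I_uA`,
#'   `Q_mC` (cumulative trapezoidal charge), with the final `npp_state` and
#'   the grid attached as attributes `final_state` and `grid`.
#' @examples
#' \donttest{
#' u <- power_unit("KCl", volume_nl = 50)
#' tr <- run_transient(u, npp_config(t_end_s = 5, cells_per_region = 6))
#' tail(tr, 2)
#' }
#' @export
run_transient <- function(unit, config = npp_config(), state = NULL,
                          grid = NULL) {
  if (is.null(grid)) grid <- build_grid(unit, config)
  if (is.null(state)) state <- init_state(grid)
  samples <- list()
  rec <- function(st) list(
    t_s = st$time_s,
    V_mV = st$V_mV %||% (1000 * .terminal_voltage(grid, st$cCl, st$w_face)),
    I_uA = st$I_uA)
  # the initial sample reports the zero-time operating point of the mode
  st0 <- npp_peek(grid, state, config)
  samples[[1]] <- rec(st0)
  next_sample <- state$time_s + config$sample_interval_s
  st <- state
  while (st$time_s < config$t_end_s - 1e-12) {
    st <- npp_step(st, grid, config)
    if (st$time_s >= next_sample - 1e-9 ||
        st$time_s >= config$t_end_s - 1e-12) {
      samples[[length(samples) + 1L]] <- rec(st)
      next_sample <- next_sample + config$sample_interval_s
    }
  }
  trace_result(vapply(samples, `[[`, 0, "t_s"),
               vapply(samples, `[[`, 0, "V_mV"),
               vapply(samples, `[[`, 0, "I_uA"),
               grid = grid, final_state = st)
}

# operating point at the current time without advancing concentrations
npp_peek <- function(grid, state, config) {
  sol <- .solve_circuit(grid, state$cK, state$cCl, state$w_face,
                        state$I_uA * 1e-6, config)
  state$w_face <- sol$w
  state$I_uA <- sol$I_A * 1e6
  state$V_mV <- 1000 * .terminal_voltage(grid, state$cCl, sol$w)
  ft <- thermal_voltage(grid$temperature_K)
  state$phi <- c(0, cumsum(sol$w)) * ft
  state
}

#' Construct a discharge trace
#'
#' @param t_s,V_mV,I_uA sampled times, terminal voltages and currents.
#' @param grid,final_state optional solver artefacts kept as attributes.
#' @return data.frame of class `trace_result` with the cumulative
#'   trapezoidal charge `Q_mC`.
#' @export
trace_result <- function(t_s, V_mV, I_uA, grid = NULL, final_state = NULL) {
  if (is.unsorted(t_s, strictly = FALSE))
    stop_invalid("trace times must be non-decreasing")
  df <- data.frame(t_s = t_s, V_mV = V_mV, I_uA = I_uA,
                   Q_mC = cumtrapz(t_s, I_uA) / 1000)
  attr(df, "grid") <- grid
  attr(df, "final_state") <- final_state
  class(df) <- c("trace_result", "data.frame")
  df
}

#' Cumulative trapezoidal integral
#'
#' @param x,y sample locations and values.
#' @return vector of the running integral, starting at 0.
#' @keywords internal
#' @export
cumtrapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(numeric(n))
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
}

#' Recharge a discharged power unit by a reverse applied potential
#'
#' Continues a simulation from a (typically discharged) state with the
#' terminal voltage held at a reversed value, driving salt back up the
#' gradient by electrodialysis.
#'
#' @param unit the [power_unit()] that produced `state`.
#' @param state the `npp_state` to recharge (e.g. `attr(trace,
#'   "final_state")` after a discharge run).
#' @param duration_s recharge duration.
#' @param applied_mV terminal voltage held during recharge. A value above
#'   the remaining cell EMF (the recharging protocol uses 200 mV) reverses
#'   the current, moving cations back from the low- to the high-salt side
#'   by electrodialysis; the trace current is negative while recharging.
#' @param config an [npp_config()] used for grid/numerics settings; its
#'   mode and span are overridden.
#' @return a `trace_result` of the recharge phase, with the recharged
#'   state attached.
#' @export
recharge <- function(unit, state, duration_s, applied_mV = 200,
                     config = npp_config()) {
  cfg <- config
  cfg$mode <- "applied_potential"
  cfg$applied_mV <- applied_mV
  cfg$t_start_s <- state$time_s
  cfg$t_end_s <- state$time_s + duration_s
  run_transient(unit, cfg, state = state,
                grid = build_grid(unit, config))
}
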