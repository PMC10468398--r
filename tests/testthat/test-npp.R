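# transient 1-D Nernst-Planck solver for the five-compartment chain

test_that("grid construction maps droplets to contiguous resolved regions", {
  u <- power_unit("KCl", volume_nl = 50)
  g <- build_grid(u, npp_config(cells_per_region = 20))
  expect_equal(g$n, 100L)
  expect_equal(as.vector(table(g$region)), rep(20L, 5))
  expect_true(all(diff(g$x) > 0))
  # equal droplets: equal region lengths
  lens <- tapply(g$h, g$region, sum)
  expect_equal(unname(diff(range(lens))), 0)
  # fixed charge only in the selective regions, with opposite signs
  expect_true(all(g$fix_mol[g$region %in% c(1, 3, 5)] == 0))
  expect_true(all(g$fix_mol[g$region == 2] < 0))
  expect_true(all(g$fix_mol[g$region == 4] > 0))
  # cell storage volume adds up to the physical droplet volumes
  expect_equal(sum(g$vol_cell), 5 * 50e-12)
  # unequal volumes: region lengths scale as the droplet diameters
  u2 <- power_unit("KCl", volume_nl = c(400, 50, 50, 50, 50))
  g2 <- build_grid(u2, npp_config(cells_per_region = 10))
  lens2 <- tapply(g2$h, g2$region, sum)
  expect_equal(unname(lens2[[1]] / lens2[[3]]), 2, tolerance = 1e-12)
  expect_error(droplet("high_salt", 0, 2), "invalid input")
})

test_that("face fluxes reduce to the Fick and drift limits", {
  u <- power_unit("KCl", volume_nl = 50)
  g <- build_grid(u, npp_config(cells_per_region = 4))
  st <- init_state(g)
  # uniform concentrations and potential: zero flux
  st$cK <- rep(100, g$n); st$cCl <- rep(100, g$n)
  st$phi <- rep(0, g$n)
  expect_equal(npp_flux(st, g, "K"), rep(0, g$n - 1))
  expect_equal(npp_flux(st, g, "Cl"), rep(0, g$n - 1))
  # pure diffusion: linear profile gives J = -D dc/dx everywhere
  st$cK <- 100 + 5 * g$x / max(g$x)
  st$cCl <- st$cK
  grad <- 5 / max(g$x)
  expect_equal(npp_flux(st, g, "K"), rep(-g$D[["K"]] * grad, g$n - 1),
               tolerance = 1e-10)
  # drift only: uniform c, linear potential; J = -D c (zF/RT) dphi/dx
  st$cK <- rep(100, g$n); st$cCl <- rep(100, g$n)
  E <- 1e-3 / max(g$x)                     # 1 mV across the domain
  st$phi <- g$x * E
  ft <- 8.314462618 * 298.15 / 96485.33212
  jk <- npp_flux(st, g, "K")
  expect_equal(jk, rep(-g$D[["K"]] * 100 * E / ft, g$n - 1),
               tolerance = 1e-3)
  # anion drifts the other way
  expect_equal(npp_flux(st, g, "Cl"),
               rep(g$D[["Cl"]] * 100 * E / ft, g$n - 1), tolerance = 1e-3)
})

test_that("a gradient-free, charge-free chain is a fixed point", {
  u <- power_unit("KCl", c_high = 0.5, c_low = 0.5, volume_nl = 50,
                  fixed_charge_mol_m3 = 1e-9)
  tr <- run_transient(u, npp_config(mode = "open_circuit", t_end_s = 10,
                                    cells_per_region = 6))
  expect_true(all(abs(tr$V_mV) < 0.1))
  expect_true(all(abs(tr$I_uA) < 1e-3))
  sf <- attr(tr, "final_state")
  expect_equal(sf$cK, rep(500, length(sf$cK)), tolerance = 1e-9)
})

test_that("closed boundaries conserve species mass to machine precision", {
  u <- calibrated_kcl_unit()
  cfg <- npp_config(mode = "open_circuit", t_end_s = 100,
                    cells_per_region = 8)
  g <- build_grid(u, cfg)
  s0 <- init_state(g)
  tr <- run_transient(u, cfg)
  sf <- attr(tr, "final_state")
  for (sp in c("cK", "cCl")) {
    m0 <- sum(s0[[sp]] * g$vol_cell)
    expect_lt(abs(sum(sf[[sp]] * g$vol_cell) - m0) / m0, 1e-12)
  }
  # electroneutrality (including fixed charge) is preserved
  expect_lt(max(abs(sf$cK - sf$cCl + g$fix_mol)), 1e-5)
})

test_that("interface potentials equilibrate to the Donnan closed form", {
  # no gradient: each membrane interface is an isolated Donnan system with
  # step (RT/F) asinh(X / 2 c_s)
  cs <- 0.1
  u <- power_unit("KCl", c_high = cs, c_low = cs, volume_nl = 0.05,
                  fixed_charge_mol_m3 = 1000)
  cfg <- npp_config(mode = "open_circuit", t_end_s = 2,
                    cells_per_region = 10)
  g <- build_grid(u, cfg)
  sf <- attr(run_transient(u, cfg), "final_state")
  ft <- 8.314462618 * 298.15 / 96485.33212
  step_th <- ft * asinh(1000 / (2 * cs * 1000))
  mid <- function(r) round(mean(which(g$region == r)))
  expect_equal(sf$phi[mid(2)] - sf$phi[mid(1)], -step_th, tolerance = 1e-6)
  expect_equal(sf$phi[mid(4)] - sf$phi[mid(3)], +step_th, tolerance = 1e-6)

  # scaled-permittivity Poisson coupling approaches the same step once the
  # artificial space-charge layers have relaxed
  cfgp <- npp_config(mode = "open_circuit", t_end_s = 0.5,
                     cells_per_region = 20, coupling = "poisson_scaled",
                     permittivity_scale = 4e7)
  gp <- build_grid(u, cfgp)
  sp <- attr(run_transient(u, cfgp), "final_state")
  midp <- function(r) round(mean(which(gp$region == r)))
  expect_equal(sp$phi[midp(2)] - sp$phi[midp(1)], -step_th,
               tolerance = 0.1)
})

test_that("open-circuit voltage reaches the Nernst stack limit", {
  # fixed charge far above both salt levels: ideal permselectivity, so the
  # plateau must hit the analytic two-membrane EMF 272.26 mV within 2%
  u <- power_unit("KCl", volume_nl = 50, fixed_charge_mol_m3 = 1e6)
  tr <- run_transient(u, npp_config(mode = "open_circuit", t_end_s = 5,
                                    cells_per_region = 8))
  v_end <- tr$V_mV[nrow(tr)]
  expect_equal(v_end, 2 * 136.12744, tolerance = 0.02)
  # and the approach is monotone in the fixed-charge density
  v_at <- vapply(c(100, 1000, 10000), function(X) {
    uX <- power_unit("KCl", volume_nl = 50, fixed_charge_mol_m3 = X)
    tX <- run_transient(uX, npp_config(mode = "open_circuit", t_end_s = 2,
                                       cells_per_region = 6))
    tX$V_mV[nrow(tX)]
  }, numeric(1))
  expect_true(all(diff(v_at) > 0))
  expect_true(all(v_at < 2 * 136.12744))
})

test_that("short-circuit current rises to a peak and then decays", {
  u <- calibrated_kcl_unit()
  tr <- run_transient(u, npp_config(mode = "short_circuit", t_end_s = 400,
                                    cells_per_region = 8,
                                    sample_interval_s = 2))
  expect_true(all(abs(tr$V_mV) < 1e-2))       # terminal held at 0
  pk <- which.max(tr$I_uA)
  expect_gt(tr$I_uA[pk], tr$I_uA[1])
  expect_lt(tr$I_uA[nrow(tr)], 0.25 * tr$I_uA[pk])
  # face-current uniformity at a re-solved operating point mid-discharge
  sf <- iondrop:::npp_peek(attr(tr, "grid"), attr(tr, "final_state"),
                           npp_config(mode = "short_circuit",
                                      cells_per_region = 8))
  ifc <- compute_current(sf, attr(tr, "grid"))
  expect_lt(diff(range(ifc)) / abs(mean(ifc)), 0.01)
  # discharged charge stays below the stoichiometric inventory bound
  bound <- released_charge_bound(u)$transportable_charge_mC
  expect_true(all(tr$Q_mC <= bound))
})

test_that("load mode interpolates between open and short circuit", {
  u <- calibrated_kcl_unit()
  t0 <- npp_config(mode = "load", r_ext_kOhm = 78, t_end_s = 2,
                   cells_per_region = 6)
  tr <- run_transient(u, t0)
  # terminal voltage equals I * R_ext along the whole trace
  expect_equal(tr$V_mV, tr$I_uA * 78, tolerance = 1e-6)
  v_oc0 <- run_transient(u, npp_config(mode = "open_circuit", t_end_s = 2,
                                       cells_per_region = 6))$V_mV[1]
  expect_lt(tr$V_mV[1], v_oc0)
  expect_gt(tr$V_mV[1], 0)
})

test_that("grid and time-step refinement leave the outputs stable", {
  u <- calibrated_kcl_unit()
  vals <- lapply(c(10, 20), function(m) {
    oc <- run_transient(u, npp_config(mode = "open_circuit", t_end_s = 60,
                                      cells_per_region = m,
                                      sample_interval_s = 1))
    sc <- run_transient(u, npp_config(mode = "short_circuit", t_end_s = 60,
                                      cells_per_region = m,
                                      sample_interval_s = 1))
    c(plateau = mean(oc$V_mV[oc$t_s >= 10 & oc$t_s <= 60]),
      peak = max(sc$I_uA))
  })
  expect_equal(vals[[1]]["plateau"], vals[[2]]["plateau"], tolerance = 0.02)
  expect_equal(vals[[1]]["peak"], vals[[2]]["peak"], tolerance = 0.02)
})

test_that("reverse applied potential recharges the unit", {
  u <- calibrated_kcl_unit()
  cfg <- npp_config(mode = "short_circuit", t_end_s = 120,
                    cells_per_region = 8)
  tr <- run_transient(u, cfg)
  s_dis <- attr(tr, "final_state")
  g <- attr(tr, "grid")
  # current reverses under the 200-mV recharge potential, and K+ moves
  # from the low- back toward the high-salt side through the cation-
  # selective membrane
  rc <- recharge(u, s_dis, 30, applied_mV = 200, config = cfg)
  expect_true(all(rc$I_uA[-1] < 0))
  jk <- npp_flux(attr(rc, "final_state"), g, "K")
  faces_cat <- which(g$region[-g$n] == 2 & g$region[-1] == 2)
  expect_true(all(jk[faces_cat] < 0))
  # longer recharge recovers monotonically more short-circuit current
  rec <- vapply(c(20, 60, 120), function(dur) {
    s_rc <- attr(recharge(u, s_dis, dur, applied_mV = 200, config = cfg),
                 "final_state")
    iondrop:::npp_peek(g, s_rc, npp_config(mode = "short_circuit",
                                           cells_per_region = 8))$I_uA
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
  # zero applied potential on a fully relaxed chain moves nothing
  ur <- power_unit("KCl", c_high = 0.5, c_low = 0.5, volume_nl = 50,
                   fixed_charge_mol_m3 = 1e-9)
  gr <- build_grid(ur, cfg)
  rc0 <- recharge(ur, init_state(gr), 10, applied_mV = 0, config = cfg)
  expect_true(all(abs(rc0$I_uA) < 1e-3))
  sf0 <- attr(rc0, "final_state")
  expect_equal(sf0$cK, rep(500, gr$n), tolerance = 1e-9)
})

test_that("trace results integrate charge by the trapezoid rule", {
  tr <- trace_result(c(0, 1, 3), c(10, 10, 10), c(2, 4, 4))
  expect_equal(tr$Q_mC, c(0, 3, 11) / 1000)
  expect_error(trace_result(c(1, 0), c(0, 0), c(0, 0)), "invalid input")
})

test_that("solver configuration rejects inconsistent settings", {
  expect_error(npp_config(t_end_s = -1), "invalid input")
  expect_error(npp_config(cells_per_region = 1), "invalid input")
  expect_error(npp_config(mode = "load"), "invalid input")
  expect_error(npp_config(mode = "applied_potential"), "invalid input")
  expect_error(npp_config(coupling = "poisson_scaled",
                          mode = "short_circuit"), "invalid input")
  expect_error(npp_config(newton_tol = 0), "invalid input")
})
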