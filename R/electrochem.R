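# Analytic reverse-electrodialysis / equivalent-circuit model of a
# five-droplet ionic power unit and of series/parallel networks of units.
#
# Internal unit conventions (chosen to match the scales at which such
# devices are reported): voltage mV, current uA, resistance kOhm, power nW,
# droplet volume nl, concentration mol/L, charge mC. Note mV/kOhm = uA and
# mV*uA = nW, so Ohm's law and P = VI hold without conversion factors.

# limiting molar ionic conductivities at 25 C, S m^2 mol^-1
.lambda0 <- c("K" = 73.5e-4, "Na" = 50.1e-4, "Ca" = 119.0e-4,
              "Cl" = 76.3e-4)
# tracer diffusivities at 25 C, m^2 s^-1
.diff0 <- c("K" = 1.96e-9, "Na" = 1.33e-9, "Ca" = 0.79e-9,
            "Cl" = 2.03e-9)

#' Define a salt species
#'
#' Describes the dissolved salt in the high- and low-salt droplets:
#' valences, stoichiometry and ionic transport coefficients. Presets are
#' provided for the three salts used in the droplet power sources
#' (`"CaCl2"`, `"KCl"`, `"NaCl"`); calcium chloride gives the highest
#' open-circuit voltage of the three and is the default elsewhere.
#'
#' @param name `"CaCl2"`, `"KCl"` or `"NaCl"` for a preset, or any label if
#'   all other arguments are supplied.
#' @param cation_valence,anion_valence signed integer valences (anion
#'   negative).
#' @param cation_stoichiometry,anion_stoichiometry ions per formula unit.
#' @param cation_diffusivity,anion_diffusivity m^2 s^-1.
#' @param cation_molar_conductivity,anion_molar_conductivity limiting molar
#'   ionic conductivities, S m^2 mol^-1.
#' @return An object of class `salt_species`.
#' @examples
#' salt_species("CaCl2")
#' @export
salt_species <- function(name,
                         cation_valence = NULL, anion_valence = NULL,
                         cation_stoichiometry = NULL,
                         anion_stoichiometry = NULL,
                         cation_diffusivity = NULL,
                         anion_diffusivity = NULL,
                         cation_molar_conductivity = NULL,
                         anion_molar_conductivity = NULL) {
  presets <- list(
    CaCl2 = list(cat = "Ca", an = "Cl", zc = 2L, za = -1L, nc = 1L, na = 2L),
    KCl   = list(cat = "K",  an = "Cl", zc = 1L, za = -1L, nc = 1L, na = 1L),
    NaCl  = list(cat = "Na", an = "Cl", zc = 1L, za = -1L, nc = 1L, na = 1L)
  )
  if (name %in% names(presets)) {
    p <- presets[[name]]
    cation_valence <- cation_valence %||% p$zc
    anion_valence <- anion_valence %||% p$za
    cation_stoichiometry <- cation_stoichiometry %||% p$nc
    anion_stoichiometry <- anion_stoichiometry %||% p$na
    cation_diffusivity <- cation_diffusivity %||% .diff0[[p$cat]]
    anion_diffusivity <- anion_diffusivity %||% .diff0[[p$an]]
    cation_molar_conductivity <- cation_molar_conductivity %||%
      .lambda0[[p$cat]]
    anion_molar_conductivity <- anion_molar_conductivity %||% .lambda0[[p$an]]
  }
  if (is.null(cation_valence) || is.null(anion_valence) ||
      is.null(cation_stoichiometry) || is.null(anion_stoichiometry) ||
      is.null(cation_diffusivity) || is.null(anion_diffusivity))
    stop_invalid("unknown salt '", name, "' and no explicit parameters")
  if (cation_valence * cation_stoichiometry +
      anion_valence * anion_stoichiometry != 0)
    stop_invalid("formula unit is not electroneutral")
  if (cation_diffusivity <= 0 || anion_diffusivity <= 0)
    stop_invalid("diffusivities must be positive")
  structure(list(
    name = name,
    cation_valence = as.integer(cation_valence),
    anion_valence = as.integer(anion_valence),
    cation_stoichiometry = as.integer(cation_stoichiometry),
    anion_stoichiometry = as.integer(anion_stoichiometry),
    cation_diffusivity = cation_diffusivity,
    anion_diffusivity = anion_diffusivity,
    cation_molar_conductivity = cation_molar_conductivity %||% NA_real_,
    anion_molar_conductivity = anion_molar_conductivity %||% NA_real_
  ), class = "salt_species")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Define one hydrogel droplet of a power unit
#'
#' Geometry is derived from the deposited volume: the droplet is modelled
#' as a cylinder whose length (`thickness`) equals the diameter of a sphere
#' of the same volume and whose cross-section is `area_factor` times the
#' sphere's equatorial cross-section (the equilibrium contact patch between
#' gelled droplets). Either quantity can be overridden.
#'
#' @param role one of `"high_salt"`, `"cation_selective"`, `"low_salt"`,
#'   `"anion_selective"`.
#' @param volume_nl droplet volume in nanolitres.
#' @param salt_concentration_M salt concentration, mol/L (0 in selective
#'   droplets, whose mobile counter-ions come from the polyelectrolyte).
#' @param fixed_charge_Cm3 signed fixed-charge density of the
#'   polyelectrolyte network, C m^-3. Must be negative for
#'   `cation_selective`, positive for `anion_selective`, zero otherwise.
#' @param area_factor contact area as a fraction of the droplet
#'   cross-section; calibrated against the measured internal resistance via
#'   [calibrate_area_factor()].
#' @param contact_area_m2,thickness_m explicit geometry overrides.
#' @return An object of class `droplet`.
#' @export
droplet <- function(role, volume_nl, salt_concentration_M = 0,
                    fixed_charge_Cm3 = 0, area_factor = 0.7,
                    contact_area_m2 = NULL, thickness_m = NULL) {
  roles <- c("high_salt", "cation_selective", "low_salt", "anion_selective")
  role <- match.arg(role, roles)
  if (volume_nl <= 0) stop_invalid("droplet volume must be positive")
  if (role == "cation_selective" && fixed_charge_Cm3 >= 0)
    stop_invalid("cation-selective droplet needs negative fixed charge")
  if (role == "anion_selective" && fixed_charge_Cm3 <= 0)
    stop_invalid("anion-selective droplet needs positive fixed charge")
  if (role %in% c("high_salt", "low_salt") && fixed_charge_Cm3 != 0)
    stop_invalid("non-selective droplets carry no fixed charge")
  vol_m3 <- volume_nl * 1e-12
  diameter <- (6 * vol_m3 / pi)^(1 / 3)
  thickness_m <- thickness_m %||% diameter
  contact_area_m2 <- contact_area_m2 %||% (area_factor * pi * diameter^2 / 4)
  if (contact_area_m2 <= 0 || thickness_m <= 0)
    stop_invalid("degenerate droplet geometry")
  structure(list(
    role = role, volume_nl = volume_nl,
    salt_concentration_M = salt_concentration_M,
    fixed_charge_Cm3 = fixed_charge_Cm3,
    contact_area_m2 = contact_area_m2, thickness_m = thickness_m
  ), class = "droplet")
}

#' Assemble a five-droplet power unit
#'
#' Builds the ordered chain high-salt | cation-selective | low-salt |
#' anion-selective | high-salt that constitutes one reverse-electrodialysis
#' power unit. Defaults correspond to the measured 50-nl unit with a
#' 200-fold gradient (2 M / 0.01 M).
#'
#' The fixed-charge density of the selective droplets defaults to
#' 1,000 mol m^-3 of charged sites (about 9.65e7 C m^-3), the
#' ion-exchange capacity implied by a 20% w/v polystyrene-sulfonate
#' hydrogel; see the methods vignette for why a literal reading of the
#' published space-charge figure is not tenable.
#'
#' @param salt a [salt_species()] or a preset name.
#' @param c_high,c_low salt concentrations, mol/L (`c_high >= c_low > 0`).
#' @param volume_nl per-droplet volume (all five droplets equal by default).
#' @param temperature_K temperature.
#' @param permselectivity length-1 or length-2 numeric in [0, 1]: apparent
#'   permselectivity of the cation- and anion-selective droplets.
#' @param fixed_charge_mol_m3 magnitude of the fixed-site concentration in
#'   the selective droplets, mol m^-3.
#' @param area_factor contact-area fraction passed to [droplet()].
#' @return An object of class `power_unit`.
#' @examples
#' u <- power_unit()
#' unit_open_circuit_voltage(u)
#' @export
power_unit <- function(salt = "CaCl2", c_high = 2, c_low = 0.01,
                       volume_nl = 50, temperature_K = 298.15,
                       permselectivity = 1,
                       fixed_charge_mol_m3 = 1000,
                       area_factor = 0.7) {
  if (is.character(salt)) salt <- salt_species(salt)
  stopifnot(inherits(salt, "salt_species"))
  if (c_low <= 0 || c_high < c_low)
    stop_invalid("need c_high >= c_low > 0")
  if (length(permselectivity) == 1)
    permselectivity <- rep(permselectivity, 2)
  if (any(permselectivity < 0 | permselectivity > 1))
    stop_invalid("permselectivity must lie in [0, 1]")
  if (length(volume_nl) == 1) volume_nl <- rep(volume_nl, 5)
  if (length(volume_nl) != 5) stop_invalid("volume_nl must have length 1 or 5")
  qfix <- fixed_charge_mol_m3 * FARADAY
  droplets <- list(
    droplet("high_salt", volume_nl[1], c_high, 0, area_factor),
    droplet("cation_selective", volume_nl[2], 0, -qfix, area_factor),
    droplet("low_salt", volume_nl[3], c_low, 0, area_factor),
    droplet("anion_selective", volume_nl[4], 0, qfix, area_factor),
    droplet("high_salt", volume_nl[5], c_high, 0, area_factor)
  )
  structure(list(
    droplets = droplets, salt = salt, c_high = c_high, c_low = c_low,
    temperature_K = temperature_K, permselectivity = permselectivity,
    area_factor = area_factor
  ), class = "power_unit")
}

#' @export
print.power_unit <- function(x, ...) {
  cat(sprintf(
    "power_unit: %s %.3g/%.3g M (ratio %.3g), %.3g nl per droplet\n",
    x$salt$name, x$c_high, x$c_low, x$c_high / x$c_low,
    x$droplets[[1]]$volume_nl))
  cat(sprintf("  permselectivity %.3g/%.3g, T = %.5g K, area factor %.3g\n",
              x$permselectivity[1], x$permselectivity[2], x$temperature_K,
              x$area_factor))
  invisible(x)
}

#' Nernst electromotive force across one selective membrane
#'
#' EMF developed by a concentration gradient across an ideally or partially
#' permselective membrane, `alpha * (RT/|z|F) * ln(c_high/c_low)`.
#'
#' @param c_high,c_low concentrations on the two sides, mol/L.
#' @param valence counter-ion valence (non-zero integer).
#' @param temperature_K temperature.
#' @param permselectivity apparent permselectivity in [0, 1]; 1 is the
#'   ideal Nernst limit, 0 a non-selective junction.
#' @return EMF in mV.
#' @examples
#' nernst_emf(2, 0.01, 1, 298.15, 1)  # about 136 mV for a 200-fold gradient
#' @export
nernst_emf <- function(c_high, c_low, valence = 1, temperature_K = 298.15,
                       permselectivity = 1) {
  if (any(c_high <= 0) || any(c_low <= 0))
    stop_invalid("concentrations must be positive")
  if (any(valence == 0)) stop_invalid("valence must be non-zero")
  if (any(permselectivity < 0 | permselectivity > 1))
    stop_invalid("permselectivity must lie in [0, 1]")
  1000 * permselectivity * thermal_voltage(temperature_K) /
    abs(valence) * log(c_high / c_low)
}

#' Open-circuit voltage of a power unit
#'
#' Sum of the two membrane EMFs (cation-selective plus anion-selective),
#' each computed with [nernst_emf()] at that droplet's permselectivity.
#' The default `valence = 1` is the monovalent idealization also used by
#' the transport simulation; pass the salt's true valences to explore
#' bi-ionic corrections.
#'
#' @param unit a [power_unit()].
#' @param valence length-1 or length-2 counter-ion valence(s) for the
#'   cation- and anion-selective membranes.
#' @return V_OC in mV.
#' @export
unit_open_circuit_voltage <- function(unit, valence = 1) {
  stopifnot(inherits(unit, "power_unit"))
  if (length(valence) == 1) valence <- rep(valence, 2)
  nernst_emf(unit$c_high, unit$c_low, valence[1], unit$temperature_K,
             unit$permselectivity[1]) +
    nernst_emf(unit$c_high, unit$c_low, valence[2], unit$temperature_K,
               unit$permselectivity[2])
}

# conductivity of one droplet's hydrogel, S m^-1
droplet_conductivity <- function(d, salt) {
  if (d$role %in% c("high_salt", "low_salt")) {
    lam <- salt$cation_stoichiometry * salt$cation_molar_conductivity +
      salt$anion_stoichiometry * salt$anion_molar_conductivity
    sigma <- d$salt_concentration_M * 1000 * lam
  } else {
    # mobile charge comes from the polyelectrolyte counter-ions
    c_counter_eq <- abs(d$fixed_charge_Cm3) / FARADAY  # mol m^-3 of charge
    lam <- if (d$role == "cation_selective")
      salt$cation_molar_conductivity / abs(salt$cation_valence)
    else salt$anion_molar_conductivity / abs(salt$anion_valence)
    sigma <- c_counter_eq * lam
  }
  sigma
}

#' Internal resistance of a power unit
#'
#' Sums the ohmic resistance `thickness / (conductivity * contact_area)`
#' of the five droplets, with conductivities from limiting molar
#' conductivities times concentration (counter-ion concentration in the
#' selective droplets). Strictly decreasing in contact area and increasing
#' in thickness.
#'
#' @param unit a [power_unit()].
#' @return internal resistance in kOhm.
#' @export
internal_resistance <- function(unit) {
  stopifnot(inherits(unit, "power_unit"))
  r <- vapply(unit$droplets, function(d) {
    sigma <- droplet_conductivity(d, unit$salt)
    if (sigma <= 0 || d$contact_area_m2 <= 0)
      stop_invalid("zero conductivity or contact area in droplet ", d$role)
    d$thickness_m / (sigma * d$contact_area_m2)
  }, numeric(1))
  sum(r) / 1000
}

#' Equivalent-circuit state of a unit or network
#'
#' @param v_oc_mV open-circuit voltage, mV.
#' @param r_int_kOhm internal resistance, kOhm.
#' @param released_charge_mC optional total released charge, mC.
#' @return An object of class `circuit_state` with fields `v_oc_mV`,
#'   `i_sc_uA`, `r_int_kOhm`, `max_power_nW`, `matching_resistance_kOhm`,
#'   `released_charge_mC`.
#' @seealso [unit_circuit_state()] to derive the state of a physical unit.
#' @export
circuit_state <- function(v_oc_mV, r_int_kOhm, released_charge_mC = NA_real_) {
  if (r_int_kOhm <= 0) stop_invalid("internal resistance must be positive")
  structure(list(
    v_oc_mV = v_oc_mV,
    i_sc_uA = v_oc_mV / r_int_kOhm,
    r_int_kOhm = r_int_kOhm,
    max_power_nW = v_oc_mV^2 / (4 * r_int_kOhm),
    matching_resistance_kOhm = r_int_kOhm,
    released_charge_mC = released_charge_mC
  ), class = "circuit_state")
}

#' @export
print.circuit_state <- function(x, ...) {
  cat(sprintf(paste0(
    "circuit_state: V_OC %.4g mV, I_SC %.4g uA, R_int %.4g kOhm,\n",
    "  max power %.4g nW at R_ext = %.4g kOhm"),
    x$v_oc_mV, x$i_sc_uA, x$r_int_kOhm, x$max_power_nW,
    x$matching_resistance_kOhm))
  if (is.finite(x$released_charge_mC))
    cat(sprintf(", released charge %.4g mC", x$released_charge_mC))
  cat("\n")
  invisible(x)
}

#' Circuit state of a physical power unit
#'
#' Combines [unit_open_circuit_voltage()], [internal_resistance()] and
#' [released_charge_bound()] into one equivalent-circuit summary.
#'
#' @inheritParams unit_open_circuit_voltage
#' @return A [circuit_state()].
#' @export
unit_circuit_state <- function(unit, valence = 1) {
  circuit_state(unit_open_circuit_voltage(unit, valence),
                internal_resistance(unit),
                released_charge_bound(unit)$transportable_charge_mC)
}

#' Sweep the external load of a power unit
#'
#' Voltage-divider behaviour of the unit driving an external resistor:
#' `V = V_OC R_ext / (R_ext + R_int)`, `I = V_OC / (R_ext + R_int)`,
#' `P = V I`. Power is maximal at the matched load `R_ext = R_int`.
#'
#' @param state a [circuit_state()] or a [power_unit()] (converted via
#'   [unit_circuit_state()]).
#' @param r_ext_kOhm positive external resistances, kOhm.
#' @return A data.frame with columns `R_ext_kOhm`, `V_mV`, `I_uA`, `P_nW`.
#' @export
load_sweep <- function(state, r_ext_kOhm) {
  if (inherits(state, "power_unit")) state <- unit_circuit_state(state)
  stopifnot(inherits(state, "circuit_state"))
  if (length(r_ext_kOhm) == 0) stop_invalid("empty load sweep")
  if (any(r_ext_kOhm <= 0)) stop_invalid("external resistances must be > 0")
  v <- state$v_oc_mV * r_ext_kOhm / (r_ext_kOhm + state$r_int_kOhm)
  i <- state$v_oc_mV / (r_ext_kOhm + state$r_int_kOhm)
  data.frame(R_ext_kOhm = r_ext_kOhm, V_mV = v, I_uA = i, P_nW = v * i)
}

#' Compose power units in series and parallel
#'
#' Ideal network composition: series multiplies voltage, parallel
#' multiplies current and released charge, and the internal resistance
#' scales as `n_series / n_parallel`. Composition is exactly
#' multiplicative: composing (a, b) then (c, d) equals composing (ac, bd).
#'
#' @param unit_state a [circuit_state()] for the single unit.
#' @param n_series,n_parallel positive integer counts.
#' @return The composed [circuit_state()].
#' @examples
#' s <- circuit_state(127, 78)
#' compose_network(s, n_series = 20, n_parallel = 1)$v_oc_mV  # 2540 mV
#' @export
compose_network <- function(unit_state, n_series = 1, n_parallel = 1) {
  stopifnot(inherits(unit_state, "circuit_state"))
  if (n_series < 1 || n_parallel < 1 ||
      n_series != round(n_series) || n_parallel != round(n_parallel))
    stop_invalid("n_series and n_parallel must be positive integers")
  circuit_state(
    v_oc_mV = unit_state$v_oc_mV * n_series,
    r_int_kOhm = unit_state$r_int_kOhm * n_series / n_parallel,
    released_charge_mC = unit_state$released_charge_mC * n_parallel
  )
}

#' Stoichiometric bound on the charge a unit can release
#'
#' The discharge is fuelled by the finite salt inventory of the high-salt
#' droplets. One high-salt droplet holds `c_high * volume` moles of salt;
#' every formula unit carries `anion_stoichiometry * |anion_valence|`
#' transferable elementary charges through the anion-selective membrane
#' (and equivalently for the cations), so the time-integral of the
#' discharge current cannot exceed `F * c_high * volume *
#' anion_stoichiometry * |anion_valence|`.
#'
#' @param unit a [power_unit()].
#' @return A list with `salt_amount_per_high_droplet_nmol` and
#'   `transportable_charge_mC`.
#' @examples
#' # 2 M CaCl2 in a 50-nl droplet: 100 nmol of salt, 19.3 mC
#' released_charge_bound(power_unit("CaCl2", volume_nl = 50))
#' @export
released_charge_bound <- function(unit) {
  stopifnot(inherits(unit, "power_unit"))
  vol_L <- unit$droplets[[1]]$volume_nl * 1e-9
  moles_salt <- unit$c_high * vol_L
  eq <- moles_salt * unit$salt$anion_stoichiometry *
    abs(unit$salt$anion_valence)
  list(salt_amount_per_high_droplet_nmol = moles_salt * 1e9,
       transportable_charge_mC = FARADAY * eq * 1000)
}

#' Peak volumetric power density of a power unit
#'
#' Matched-load power `V_OC * I_SC / 4` divided by the device volume,
#' taken as five times the single-droplet volume (the device length is
#' five droplet diameters).
#'
#' @param state a [circuit_state()].
#' @param droplet_volume_nl single-droplet volume, nl.
#' @return power density in W m^-3.
#' @examples
#' power_density(circuit_state(87, 87 / 0.83), 1.84)   # ~1.96e3 W m^-3
#' power_density(circuit_state(136, 136 / 2.7), 1000)  # ~18.4 W m^-3
#' @export
power_density <- function(state, droplet_volume_nl) {
  stopifnot(inherits(state, "circuit_state"))
  if (droplet_volume_nl <= 0) stop_invalid("droplet volume must be positive")
  p_nW <- state$v_oc_mV * state$i_sc_uA / 4
  1000 * p_nW / (5 * droplet_volume_nl)
}

#' Calibrate an apparent permselectivity against a measured voltage
#'
#' The measured open-circuit voltage of real units falls short of the
#' ideal two-membrane Nernst stack (co-ion leakage, junction potentials).
#' This fits the single apparent permselectivity `alpha` such that the
#' ideal stack scaled by `alpha` reproduces the measurement.
#'
#' @param unit a [power_unit()].
#' @param target_mV measured open-circuit voltage, mV (default the 127 mV
#'   recorded for the 50-nl, 200-fold-gradient unit).
#' @param valence passed to [unit_open_circuit_voltage()].
#' @return the fitted permselectivity (about 0.47 at default settings).
#' @export
calibrate_permselectivity <- function(unit, target_mV = 127, valence = 1) {
  ideal <- unit
  ideal$permselectivity <- c(1, 1)
  v1 <- unit_open_circuit_voltage(ideal, valence)
  alpha <- target_mV / v1
  if (alpha < 0 || alpha > 1)
    stop_invalid("target voltage outside the ideal stack range")
  alpha
}

#' Calibrate the contact-area factor against a measured resistance
#'
#' The droplet contact geometry is not observable directly; this scales
#' the contact-area fraction so that [internal_resistance()] matches a
#' measured value (default the ~78 kOhm load-sweep resistance of the
#' 50-nl unit). Resistance is inversely proportional to the area factor,
#' so the fit is a single ratio.
#'
#' @param unit a [power_unit()].
#' @param target_kOhm measured internal resistance, kOhm.
#' @return a new `power_unit` with the calibrated geometry.
#' @export
calibrate_area_factor <- function(unit, target_kOhm = 78) {
  stopifnot(inherits(unit, "power_unit"))
  if (target_kOhm <= 0) stop_invalid("target resistance must be positive")
  r0 <- internal_resistance(unit)
  f <- unit$area_factor * r0 / target_kOhm
  power_unit(salt = unit$salt, c_high = unit$c_high, c_low = unit$c_low,
             volume_nl = vapply(unit$droplets, `[[`, numeric(1), "volume_nl"),
             temperature_K = unit$temperature_K,
             permselectivity = unit$permselectivity,
             fixed_charge_mol_m3 =
               abs(unit$droplets[[2]]$fixed_charge_Cm3) / FARADAY,
             area_factor = f)
}
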