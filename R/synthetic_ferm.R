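#' Configuration for the biphasic batch fermentation simulator
#'
#' The simulator emulates the canonical two-phase structure of solventogenic
#' clostridial batch fermentations: an acidogenic phase in which acetic and
#' butyric acid accumulate while pH falls, followed (from `switch_time_h`)
#' by a solventogenic phase in which the acids are re-assimilated into
#' butanol and solvents (butanol, isopropanol, acetone) are formed directly
#' from substrate, with transient acetone converted to isopropanol.  It is a
#' descriptive test-harness model, not a mechanistic kinetic model of any
#' organism.
#'
#' @param initial_substrates Named numeric vector, species -> initial g/L
#'   (glucose and/or glycerol for the bundled presets).
#' @param inoculum_dcw Initial dry cell weight, g/L.
#' @param mu_max Maximum specific growth rate, 1/h.
#' @param biomass_capacity Logistic biomass ceiling, g/L.
#' @param switch_time_h Onset of solventogenesis, h; must be `< t_end`.
#' @param acid_yields Named numeric vector `{acetic_acid, butyric_acid}` ->
#'   g acid per g substrate consumed during the acidogenic phase; sum <= 1.
#' @param solvent_yields Named numeric vector (e.g. `{butanol, isopropanol,
#'   acetone}`; may include `pdo_13` for glycerol cultures) -> g product per
#'   g substrate consumed during the solventogenic phase; sum <= 1.
#' @param acid_reassimilation_rate First-order re-assimilation rate of each
#'   acid during solventogenesis, 1/h.
#' @param acid_to_solvent_yield g butanol formed per g acid re-assimilated
#'   (default 1, mass-conserving hand-off).
#' @param acetone_conversion_rate First-order acetone -> isopropanol
#'   conversion rate, 1/h (applied at molar equivalence).
#' @param glycerol_preference Fraction of the instantaneous substrate draw
#'   taken from glycerol while glycerol remains; default is glycerol's mass
#'   share of the initial feed.
#' @param substrate_uptake_rate Specific uptake rate, g substrate per g DCW
#'   per h.
#' @param noise_sd Gaussian measurement noise (g/L, truncated at 0) added
#'   only to the emitted measured copy, never to the latent truth.
#' @param seed RNG seed for the measurement noise; `NULL` leaves the global
#'   RNG stream untouched.
#' @param dt Euler time step, h.
#' @param t_end Simulated duration, h.
#' @return A list of class `ib_simconfig`.
#' @seealso [simulate_batch()], [scenario()]
#' @export
sim_config <- function(initial_substrates,
                       inoculum_dcw = 0.05,
                       mu_max = 0.35,
                       biomass_capacity = 3,
                       switch_time_h = 10,
                       acid_yields = c(acetic_acid = 0.05,
                                       butyric_acid = 0.12),
                       solvent_yields = c(butanol = 0.20,
                                          isopropanol = 0.10,
                                          acetone = 0.02),
                       acid_reassimilation_rate = 0.03,
                       acid_to_solvent_yield = 1,
                       acetone_conversion_rate = 0.15,
                       glycerol_preference = NULL,
                       substrate_uptake_rate = 0.4,
                       noise_sd = 0,
                       seed = NULL,
                       dt = 0.02,
                       t_end = 28) {
  num_ok <- function(x) all(is.finite(x)) && all(x >= 0)
  if (is.null(names(initial_substrates)) ||
      !num_ok(initial_substrates)) {
    ib_validation_error("initial_substrates must be a named non-negative vector")
  }
  if (!num_ok(c(inoculum_dcw, mu_max, biomass_capacity, acid_yields,
                solvent_yields, acid_reassimilation_rate,
                acid_to_solvent_yield, acetone_conversion_rate,
                substrate_uptake_rate, noise_sd))) {
    ib_validation_error("all rates and yields must be finite and >= 0")
  }
  if (sum(acid_yields) > 1 + 1e-12 || sum(solvent_yields) > 1 + 1e-12) {
    ib_validation_error("phase yields must sum to <= 1 on a mass basis")
  }
  if (!is.finite(dt) || dt <= 0) ib_validation_error("dt must be > 0")
  if (!is.finite(t_end) || t_end <= 0) ib_validation_error("t_end must be > 0")
  if (!is.finite(switch_time_h) || switch_time_h < 0 ||
      switch_time_h >= t_end) {
    ib_validation_error("switch_time_h must lie in [0, t_end)")
  }
  if (is.null(glycerol_preference)) {
    glycerol_preference <-
      if ("glycerol" %in% names(initial_substrates) &&
          sum(initial_substrates) > 0) {
        unname(initial_substrates[["glycerol"]] / sum(initial_substrates))
      } else 0
  }
  if (!is.finite(glycerol_preference) || glycerol_preference < 0 ||
      glycerol_preference > 1) {
    ib_validation_error("glycerol_preference must lie in [0, 1]")
  }
  structure(list(
    initial_substrates = initial_substrates,
    inoculum_dcw = inoculum_dcw, mu_max = mu_max,
    biomass_capacity = biomass_capacity, switch_time_h = switch_time_h,
    acid_yields = acid_yields, solvent_yields = solvent_yields,
    acid_reassimilation_rate = acid_reassimilation_rate,
    acid_to_solvent_yield = acid_to_solvent_yield,
    acetone_conversion_rate = acetone_conversion_rate,
    glycerol_preference = glycerol_preference,
    substrate_uptake_rate = substrate_uptake_rate,
    noise_sd = noise_sd, seed = seed, dt = dt, t_end = t_end
  ), class = "ib_simconfig")
}

#' Load a simulator configuration from JSON or YAML
#'
#' @param path `.json` or `.yaml`/`.yml` file whose keys are [sim_config()]
#'   arguments; named maps become named vectors.
#' @return An `ib_simconfig`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) {
    ib_validation_error(sprintf("config file not found: '%s'", path))
  }
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    ib_validation_error(sprintf("unsupported config format '.%s'", ext))
  }
  vecs <- c("initial_substrates", "acid_yields", "solvent_yields")
  for (v in intersect(vecs, names(raw))) raw[[v]] <- unlist(raw[[v]])
  unknown <- setdiff(names(raw), names(formals(sim_config)))
  if (length(unknown)) {
    ib_validation_error(sprintf("unknown config field(s): %s",
                                paste(unknown, collapse = ", ")))
  }
  do.call(sim_config, raw)
}

# run body with a private RNG stream (restores .Random.seed afterwards)
with_private_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a biphasic batch fermentation
#'
#' Explicit-Euler integration of the model described in [sim_config()]:
#' logistic biomass growth towards the capacity; substrate drawn at
#' `substrate_uptake_rate x DCW`, split between glucose and glycerol by
#' `glycerol_preference` while glycerol lasts; acids formed at `acid_yields`
#' before `switch_time_h`; afterwards solvents formed at `solvent_yields`,
#' acids re-assimilated first-order into butanol, and acetone converted
#' first-order to isopropanol at molar equivalence.  Substrates floor at 0
#' and are withdrawn from the uptake split once exhausted.  Measurement
#' noise (if any) is applied only to the returned measured copy; the exact
#' latent trajectory is attached as `attr(, "latent")`.  Identical seeds
#' give identical output.
#'
#' @param config An `ib_simconfig`.
#' @param registry Species registry (for molar masses in the acetone
#'   conversion and downstream checks).
#' @return An `ib_timecourse` (the measured copy) with attributes `latent`
#'   (noise-free `ib_timecourse`) and `config`.
#' @examples
#' tc <- simulate_batch(scenario("glucose_20"))
#' endpoint_from_timecourse(tc)
#' @export
simulate_batch <- function(config, registry = species_registry()) {
  stopifnot(inherits(config, "ib_simconfig"))
  cf <- config
  dt <- cf$dt
  times <- seq(0, cf$t_end, by = dt)
  if (abs(times[length(times)] - cf$t_end) > 1e-9) {
    times <- c(times, cf$t_end)  # ragged final step
  }
  n <- length(times)
  sub_ids <- names(cf$initial_substrates)
  prod_ids <- unique(c(names(cf$solvent_yields), names(cf$acid_yields),
                       "butanol", "isopropanol", "acetone",
                       "acetic_acid", "butyric_acid"))
  mw_act <- get_species("acetone", registry)$molar_mass
  mw_ipa <- get_species("isopropanol", registry)$molar_mass

  S <- cf$initial_substrates
  P <- stats::setNames(numeric(length(prod_ids)), prod_ids)
  X <- cf$inoculum_dcw
  out_S <- matrix(0, n, length(sub_ids), dimnames = list(NULL, sub_ids))
  out_P <- matrix(0, n, length(prod_ids), dimnames = list(NULL, prod_ids))
  out_X <- numeric(n)
  floor_events <- stats::setNames(integer(length(sub_ids)), sub_ids)

  out_S[1, ] <- S; out_P[1, ] <- P; out_X[1] <- X
  for (k in seq_len(n - 1)) {
    h <- times[k + 1] - times[k]
    # substrate draw, split by glycerol preference among available substrates
    demand <- cf$substrate_uptake_rate * X * h
    avail <- names(S)[S > 0]
    draw <- stats::setNames(numeric(length(S)), names(S))
    if (length(avail) > 0 && demand > 0) {
      if ("glycerol" %in% avail && length(avail) > 1) {
        draw["glycerol"] <- demand * cf$glycerol_preference
        rest <- setdiff(avail, "glycerol")
        draw[rest] <- demand * (1 - cf$glycerol_preference) *
          S[rest] / sum(S[rest])
      } else {
        draw[avail] <- demand * S[avail] / sum(S[avail])
      }
      over <- draw > S
      if (any(over)) {
        floor_events[names(S)[over]] <- floor_events[names(S)[over]] + 1L
        draw[over] <- S[over]
      }
    }
    consumed <- sum(draw)
    S <- S - draw

    if (times[k] < cf$switch_time_h) {
      P[names(cf$acid_yields)] <- P[names(cf$acid_yields)] +
        cf$acid_yields * consumed
    } else {
      P[names(cf$solvent_yields)] <- P[names(cf$solvent_yields)] +
        cf$solvent_yields * consumed
      # first-order acid re-assimilation into butanol
      for (acid in names(cf$acid_yields)) {
        re <- min(P[[acid]], cf$acid_reassimilation_rate * P[[acid]] * h)
        P[[acid]] <- P[[acid]] - re
        P[["butanol"]] <- P[["butanol"]] + cf$acid_to_solvent_yield * re
      }
      # first-order acetone -> isopropanol at molar equivalence
      conv <- min(P[["acetone"]],
                  cf$acetone_conversion_rate * P[["acetone"]] * h)
      P[["acetone"]] <- P[["acetone"]] - conv
      P[["isopropanol"]] <- P[["isopropanol"]] + conv * mw_ipa / mw_act
    }
    X <- X + cf$mu_max * X * (1 - X / cf$biomass_capacity) * h
    out_S[k + 1, ] <- S; out_P[k + 1, ] <- P; out_X[k + 1] <- X
  }
  if (any(floor_events > 1L)) {
    warning(sprintf(
      "dt may be too large: repeated substrate floor events for %s",
      paste(names(floor_events)[floor_events > 1L], collapse = ", ")))
  }

  # descriptive pH proxy: falls with total acids, bounded [4.5, 6.2]
  acids_tot <- out_P[, "acetic_acid"] + out_P[, "butyric_acid"]
  ph <- pmin(6.2, pmax(4.5, 6.2 - 0.35 * acids_tot))

  series <- c(lapply(sub_ids, function(id) out_S[, id]),
              lapply(prod_ids, function(id) out_P[, id]))
  names(series) <- c(sub_ids, prod_ids)
  latent <- timecourse(times, series, biomass = out_X, ph = ph,
                       noise_tolerance = 0, registry = registry)

  measured <- latent
  if (cf$noise_sd > 0) {
    noisy <- with_private_seed(cf$seed, {
      lapply(series, function(x)
        pmax(0, x + stats::rnorm(length(x), sd = cf$noise_sd)))
    })
    measured <- timecourse(times, noisy, biomass = out_X, ph = ph,
                           noise_tolerance = 8 * cf$noise_sd,
                           registry = registry)
  }
  attr(measured, "latent") <- latent
  attr(measured, "config") <- cf
  measured
}

#' Collapse a time course to an endpoint record
#'
#' Consumed substrate is initial minus final per substrate series (clamped
#' at 0), products are the final titers, and the duration is the last
#' sampling time.
#'
#' @param tc An `ib_timecourse`.
#' @param label Label for the record.
#' @param registry Species registry.
#' @return An [endpoint_record()].
#' @export
endpoint_from_timecourse <- function(tc, label = "simulated",
                                     registry = species_registry()) {
  stopifnot(inherits(tc, "ib_timecourse"))
  last <- length(tc$times)
  if (tc$times[last] <= 0) {
    ib_validation_error("time course has zero duration")
  }
  cons <- numeric(0); prod <- numeric(0)
  for (nm in names(tc$series)) {
    sp <- get_species(nm, registry)
    x <- tc$series[[nm]]
    if (sp$role %in% c("substrate", "both")) {
      cons[nm] <- max(0, x[1] - x[last])
    } else {
      prod[nm] <- x[last]
    }
  }
  endpoint_record(label, tc$times[last], cons, prod, registry = registry)
}

# preset construction: kinetics shared, yields chosen per condition so the
# noiseless endpoint lands near the corresponding reference endpoint
ib_scenarios <- function() {
  list(
    glucose_20 = sim_config(
      initial_substrates = c(glucose = 21.85),
      inoculum_dcw = 0.1, switch_time_h = 10,
      acid_yields = c(acetic_acid = 0.36, butyric_acid = 0.48),
      solvent_yields = c(butanol = 0.175, isopropanol = 0.10,
                         acetone = 0.042),
      acid_reassimilation_rate = 0.03, acetone_conversion_rate = 0.15,
      substrate_uptake_rate = 0.4, t_end = 28),
    glucose_40 = sim_config(
      initial_substrates = c(glucose = 41.02),
      inoculum_dcw = 0.1, switch_time_h = 10, biomass_capacity = 4,
      acid_yields = c(acetic_acid = 0.22, butyric_acid = 0.42),
      solvent_yields = c(butanol = 0.20, isopropanol = 0.083,
                         acetone = 0.022),
      acid_reassimilation_rate = 0.03, acetone_conversion_rate = 0.15,
      substrate_uptake_rate = 0.62, t_end = 28),
    mix_14_8 = sim_config(
      initial_substrates = c(glucose = 13.35, glycerol = 7.01),
      inoculum_dcw = 0.1, switch_time_h = 10,
      acid_yields = c(acetic_acid = 0.16, butyric_acid = 0.66),
      solvent_yields = c(butanol = 0.25, isopropanol = 0.075,
                         acetone = 0.008),
      acid_reassimilation_rate = 0.025, acetone_conversion_rate = 0.6,
      substrate_uptake_rate = 0.38, t_end = 28),
    glycerol_only = sim_config(
      initial_substrates = c(glycerol = 18.13),
      inoculum_dcw = 0.1, switch_time_h = 12,
      acid_yields = c(acetic_acid = 0.094, butyric_acid = 0.76),
      solvent_yields = c(butanol = 0.215, pdo_13 = 0.225),
      acid_reassimilation_rate = 0.016, acetone_conversion_rate = 0,
      substrate_uptake_rate = 0.34, t_end = 28)
  )
}

#' Preset simulator scenarios
#'
#' Documented configurations whose noiseless endpoints approximate the
#' bundled reference fermentations: `"glucose_20"` (~21.85 g/L glucose,
#' solventogenic IB profile with residual acetone), `"glucose_40"`
#' (~41 g/L glucose), `"mix_14_8"` (glucose:glycerol 14:8, acetone-free and
#' 1,3-PDO-free endpoint) and `"glycerol_only"` (butanol plus
#' 1,3-propanediol route, no isopropanol).  The kinetic parameters are
#' calibrated to endpoint tables only and are not biological measurements.
#'
#' @param name Preset name.
#' @return An `ib_simconfig`.
#' @examples
#' endpoint_from_timecourse(simulate_batch(scenario("mix_14_8")))
#' @export
scenario <- function(name) {
  presets <- ib_scenarios()
  if (!name %in% names(presets)) {
    ib_validation_error(sprintf(
      "unknown scenario '%s'; available presets: %s",
      name, paste(names(presets), collapse = ", ")))
  }
  presets[[name]]
}
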