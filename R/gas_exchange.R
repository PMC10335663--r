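#' Environment conditions for solubility and gas-exchange calculations
#'
#' @param temperature_C water temperature in degrees Celsius, 0-40.
#' @param pressure_mbar ambient barometric pressure in millibar, > 0.
#' @param salinity_pct salinity in % m/v (g NaCl per 100 mL), expected 0-3.5.
#' @return Object of class \code{environment_conditions}.
#' @export
environment_conditions <- function(temperature_C = 21,
                                   pressure_mbar = 1013,
                                   salinity_pct = 0) {
  if (!is.finite(pressure_mbar) || pressure_mbar <= 0)
    stop("pressure_mbar must be positive")
  if (!is.finite(temperature_C) || temperature_C < 0 || temperature_C > 40)
    stop("temperature_C must lie within 0-40 degrees C")
  structure(list(temperature_C = temperature_C,
                 pressure_mbar = pressure_mbar,
                 salinity_pct = salinity_pct),
            class = "environment_conditions")
}

#' Reactor specification
#'
#' Named reactor geometries with whole-tube oxygen permeability. The
#' permeability \code{r} (mg per minute per bar of oxygen partial-pressure
#' difference) characterises the assembled reactor as a single system, with
#' wall area and thickness absorbed into the coefficient.
#'
#' @param reactor_type one of \code{"plastic_centrifuge_50ml"},
#'   \code{"glass_voa_40ml"}, \code{"double_ended_voa_40ml"},
#'   \code{"custom"}.
#' @param volume_L liquid volume in liters; defaults to the nominal volume
#'   of the named type.
#' @param permeability_r whole-tube permeability in mg/(min*bar); defaults
#'   to the library value for the named type.
#' @return Object of class \code{reactor_spec}.
#' @export
reactor_spec <- function(reactor_type = c("plastic_centrifuge_50ml",
                                          "glass_voa_40ml",
                                          "double_ended_voa_40ml",
                                          "custom"),
                         volume_L = NULL, permeability_r = NULL) {
  reactor_type <- match.arg(reactor_type)
  lib <- default_reactor_library()
  if (reactor_type != "custom") {
    entry <- lib[[reactor_type]]
    volume_L <- volume_L %||% entry$volume_L
    permeability_r <- permeability_r %||% entry$permeability_r
  }
  if (is.null(volume_L) || is.null(permeability_r))
    stop("custom reactors need explicit volume_L and permeability_r")
  if (!is.finite(volume_L) || volume_L <= 0) stop("volume_L must be > 0")
  if (!is.finite(permeability_r) || permeability_r < 0)
    stop("permeability_r must be >= 0")
  structure(list(reactor_type = reactor_type, volume_L = volume_L,
                 permeability_r = permeability_r),
            class = "reactor_spec")
}

#' Load a reactor library from YAML
#'
#' The bundled default library (\code{inst/extdata/reactors.yaml}) carries
#' the three measured tube types with their fitted whole-tube
#' permeabilities.
#'
#' @param path YAML path; default the bundled library.
#' @return Named list of entries with \code{volume_L} and
#'   \code{permeability_r}.
#' @export
read_reactor_library <- function(path = system.file("extdata",
                                                    "reactors.yaml",
                                                    package = "roptode")) {
  yaml::read_yaml(path)
}

default_reactor_library <- function() {
  p <- system.file("extdata", "reactors.yaml", package = "roptode")
  if (nzchar(p)) read_reactor_library(p) else
    list(plastic_centrifuge_50ml = list(volume_L = 0.050,
                                        permeability_r = 3.02e-3),
         glass_voa_40ml = list(volume_L = 0.040, permeability_r = 1.75e-3),
         double_ended_voa_40ml = list(volume_L = 0.040,
                                      permeability_r = 9.44e-4))
}

#' Oxygen solubility at 100% air saturation
#'
#' Benson-Krause equilibrium solubility of oxygen in fresh water at the
#' given temperature, scaled linearly by the ratio of ambient pressure to
#' the 1013.25 mbar standard. Salinity is handled separately by
#' \code{\link{salinity_correct}}.
#'
#' @param env an \code{\link{environment_conditions}} object.
#' @return Solubility in mg/L at 100% air saturation.
#' @export
o2_solubility <- function(env) {
  stopifnot(inherits(env, "environment_conditions"))
  TK <- env$temperature_C + 273.15
  ln_c <- -139.34411 + 1.575701e5 / TK - 6.642308e7 / TK^2 +
    1.2438e10 / TK^3 - 8.621949e11 / TK^4
  exp(ln_c) * env$pressure_mbar / 1013.25
}

#' Convert between % air saturation and mg/L
#'
#' \code{sat_to_conc} maps % air saturation to dissolved oxygen in mg/L via
#' the solubility at the stated conditions; \code{conc_to_sat} is its exact
#' inverse.
#'
#' @param pct_sat oxygen in % air saturation (vectorised, >= 0).
#' @param mg_per_L dissolved oxygen in mg/L.
#' @param env an \code{\link{environment_conditions}} object.
#' @return Converted value(s).
#' @export
sat_to_conc <- function(pct_sat, env) {
  if (any(pct_sat < 0, na.rm = TRUE)) stop("pct_sat must be >= 0")
  pct_sat / 100 * o2_solubility(env)
}

#' @rdname sat_to_conc
#' @export
conc_to_sat <- function(mg_per_L, env) {
  mg_per_L / o2_solubility(env) * 100
}

#' Salinity correction for dissolved oxygen
#'
#' Applies the empirical linear salinity correction
#' \deqn{DO_{salt} = DO - qS, \quad q = -0.1903\,t + 12.892}
#' with \eqn{t} in degrees Celsius and \eqn{S} the salinity as a mass
#' fraction (\code{salinity_pct / 100}). Calibrated over 0-3.5% m/v NaCl;
#' outside that range the correction extrapolates with a warning.
#'
#' @param do_mg_L freshwater dissolved-oxygen value(s) in mg/L.
#' @param env an \code{\link{environment_conditions}} object carrying
#'   temperature and salinity.
#' @return Salinity-corrected dissolved oxygen in mg/L.
#' @export
salinity_correct <- function(do_mg_L, env) {
  stopifnot(inherits(env, "environment_conditions"))
  S_pct <- env$salinity_pct
  if (S_pct < 0 || S_pct > 3.5)
    warning("salinity ", S_pct, "% m/v outside the calibrated 0-3.5% range; ",
            "extrapolating")
  q <- -0.1903 * env$temperature_C + 12.892
  do_mg_L - q * (S_pct / 100)
}

#' Ambient oxygen partial pressure
#'
#' Fixed atmospheric O2 mole fraction of 0.2095 applied to the ambient
#' pressure.
#'
#' @param env an \code{\link{environment_conditions}} object.
#' @return Partial pressure in bar.
#' @export
ambient_o2_partial_pressure <- function(env) {
  0.2095 * env$pressure_mbar / 1000
}

#' Henry's-law solubility coefficient
#'
#' The proportionality H between oxygen partial pressure and equilibrium
#' dissolved concentration, chosen so that 100% air saturation at the
#' stated conditions corresponds to the ambient partial pressure:
#' \code{H = o2_solubility(env) / ambient_o2_partial_pressure(env)}.
#'
#' @param env an \code{\link{environment_conditions}} object.
#' @return H in mg/(L*bar).
#' @export
henry_H <- function(env) {
  o2_solubility(env) / ambient_o2_partial_pressure(env)
}

#' Sealed-reactor reaeration curve
#'
#' Closed-form concentration inside a sealed, initially low-oxygen reactor
#' whose walls admit oxygen at a rate proportional to the partial-pressure
#' difference with the room:
#' \deqn{C(t) = p_a H - (p_a - p_0) H \exp\!\left(-\frac{r}{H V} t\right)}
#'
#' @param t elapsed time in minutes (vectorised).
#' @param pa ambient oxygen partial pressure, bar.
#' @param p0 initial internal oxygen partial pressure, bar.
#' @param H Henry's-law solubility, mg/(L*bar); > 0.
#' @param V reactor volume, L; > 0.
#' @param r whole-tube permeability, mg/(min*bar); >= 0.
#' @return Concentration(s) in mg/L.
#' @export
diffusion_model <- function(t, pa, p0, H, V, r) {
  if (!is.finite(V) || V <= 0) stop("V must be > 0")
  if (!is.finite(H) || H <= 0) stop("H must be > 0")
  if (r < 0) stop("r must be >= 0")
  pa * H - (pa - p0) * H * exp(-r * t / (H * V))
}

#' Fit whole-tube permeability from a reaeration time series
#'
#' Least-squares fit of \code{\link{diffusion_model}} to measured
#' concentrations with \code{r}, \code{p0} and \code{H} free and the tube
#' volume and ambient partial pressure fixed. Freeing \code{p0} and
#' \code{H} keeps the first data point and small temperature/pressure
#' variation from distorting the permeability estimate.
#'
#' @param times minutes since sealing, strictly increasing, length >= 4.
#' @param concs measured concentrations, mg/L.
#' @param V tube volume, L.
#' @param pa ambient oxygen partial pressure, bar.
#' @param init optional named list of starting values \code{r}, \code{p0},
#'   \code{H}; defaults are derived deterministically from the data.
#' @return Object of class \code{diffusion_fit} with fields \code{r},
#'   \code{p0}, \code{H}, \code{rmse}, \code{n_points},
#'   \code{identifiable}.
#' @export
fit_permeability <- function(times, concs, V, pa, init = NULL) {
  stopifnot(length(times) == length(concs), length(times) >= 4)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!is.finite(V) || V <= 0) stop("V must be > 0")

  H0 <- init$H %||% max(max(concs) / pa, 1e-3)
  p00 <- init$p0 %||% max(concs[1] / H0, 0)
  # crude rate-constant guess from the fractional approach to the ceiling
  ceil <- pa * H0
  gap0 <- ceil - concs[1]
  gap1 <- ceil - concs[length(concs)]
  k0 <- if (gap0 > 0 && gap1 > 0 && gap1 < gap0)
    log(gap0 / gap1) / (times[length(times)] - times[1]) else 1e-4
  r0 <- init$r %||% max(k0 * H0 * V, 1e-8)

  df <- data.frame(t = times, conc = concs)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      conc ~ pa * H - (pa - p0) * H * exp(-r * t / (H * V)), data = df,
      start = list(r = r0, p0 = p00, H = H0),
      lower = c(r = 0, p0 = 0, H = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # no curvature to fit (e.g. a flat series): report the trivial
    # equilibrium description with r flagged unidentifiable
    H_fb <- max(mean(concs) / pa, 1e-9)
    warning("permeability poorly identified: series shows no significant ",
            "approach to ambient equilibrium")
    return(structure(list(r = 0, p0 = mean(concs) / H_fb, H = H_fb,
                          rmse = sqrt(mean((concs - mean(concs))^2)),
                          n_points = length(times), identifiable = FALSE),
                     class = "diffusion_fit"))
  }
  est <- stats::coef(fit)
  res <- stats::residuals(fit)
  rmse <- sqrt(mean(res^2))
  # identifiability: with no concentration trend toward the ceiling the
  # exponential rate (hence r) carries no information
  amplitude <- abs(pa - est[["p0"]]) * est[["H"]]
  identifiable <- amplitude > max(4 * rmse, 1e-9) &&
    (max(concs) - min(concs)) > max(4 * rmse, 1e-12)
  if (!identifiable)
    warning("permeability poorly identified: series shows no significant ",
            "approach to ambient equilibrium")
  structure(list(r = est[["r"]], p0 = est[["p0"]], H = est[["H"]],
                 rmse = rmse, n_points = length(times),
                 identifiable = identifiable),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf(
    "Reactor diffusion fit (n = %d):\n  r = %.4g mg/(min*bar), p0 = %.4g bar, H = %.4g mg/(L*bar)\n  rmse = %.4g mg/L%s\n",
    x$n_points, x$r, x$p0, x$H, x$rmse,
    if (x$identifiable) "" else "  [r not identifiable]"))
  invisible(x)
}

#' Diffusive oxygen influx rate into a reactor
#'
#' Rate of concentration change from wall diffusion alone at the current
#' internal concentration:
#' \deqn{\frac{dC}{dt} = \frac{60\, r\,(p_a - p_i)}{V}, \quad
#'       p_i = C/H}
#' reported per hour. The worst case (maximum influx) is an anoxic
#' interior, \code{conc_inside = 0}.
#'
#' @param conc_inside internal oxygen concentration, mg/L (vectorised).
#' @param env an \code{\link{environment_conditions}} object.
#' @param reactor a \code{\link{reactor_spec}}.
#' @return Influx in mg/(L*hr); positive when the interior is below
#'   ambient equilibrium.
#' @export
influx_rate <- function(conc_inside, env, reactor) {
  stopifnot(inherits(reactor, "reactor_spec"))
  pa <- ambient_o2_partial_pressure(env)
  H <- henry_H(env)
  60 * reactor$permeability_r * (pa - conc_inside / H) / reactor$volume_L
}

#' Compare permeability between two groups of diffusion fits
#'
#' Welch two-sample t-test on the fitted \code{r} values, the standard
#' check for whether, for example, rolled and static tubes diffuse
#' differently.
#'
#' @param fits_a,fits_b lists of \code{diffusion_fit} objects (or numeric
#'   vectors of r values), each length >= 2.
#' @return List with \code{t_statistic}, \code{p_value}.
#' @export
compare_permeability_groups <- function(fits_a, fits_b) {
  r_of <- function(fits) {
    if (is.numeric(fits)) return(fits)
    vapply(fits, function(f) {
      stopifnot(inherits(f, "diffusion_fit")); f$r
    }, numeric(1))
  }
  ra <- r_of(fits_a); rb <- r_of(fits_b)
  if (length(ra) < 2L || length(rb) < 2L)
    stop("need at least 2 fits per group")
  if (stats::sd(ra) == 0 && stats::sd(rb) == 0 && mean(ra) == mean(rb))
    return(list(t_statistic = 0, p_value = 1))
  tt <- tryCatch(stats::t.test(ra, rb, var.equal = FALSE),
                 error = function(e) NULL)
  if (is.null(tt)) {
    warning("degenerate within-group variance; t statistic unbounded")
    return(list(t_statistic = sign(mean(ra) - mean(rb)) * Inf, p_value = 0))
  }
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value)
}
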