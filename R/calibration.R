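#' Construct a Stern-Volmer calibration curve
#'
#' Container for the per-disk response model of a ratiometric oxygen optode.
#' The response follows the modified Stern-Volmer relation
#' \deqn{R(C) = R_0 \left[\alpha + \frac{1-\alpha}{1 + K_{SV} C}\right]}
#' where \eqn{C} is dissolved oxygen in % air saturation, \eqn{R_0} the
#' luminescence ratio at zero oxygen, \eqn{K_{SV}} the quenching constant
#' (per % air saturation) and \eqn{\alpha} the nonquenchable signal fraction.
#'
#' @param disk_id character identifier (the engraved disk number).
#' @param R0 ratio at zero oxygen; must be > 0.
#' @param Ksv quenching constant per % air saturation; must be >= 0.
#' @param alpha nonquenchable fraction in [0, 1). Default 0.
#' @param ratio_def which ratio the curve was fitted on: \code{"larsen"} for
#'   (red - green)/green or \code{"simple"} for red/green.
#' @param r_squared,resid_sd optional fit diagnostics.
#' @param temperature_C calibration temperature in degrees Celsius.
#' @param created_at timestamp string; defaults to the current time.
#' @return An object of class \code{calibration_curve}.
#' @export
calibration_curve <- function(disk_id, R0, Ksv, alpha = 0,
                              ratio_def = c("larsen", "simple"),
                              r_squared = NA_real_, resid_sd = NA_real_,
                              temperature_C = NA_real_, created_at = NULL) {
  ratio_def <- match.arg(ratio_def)
  disk_id <- as.character(disk_id)
  stopifnot(length(disk_id) == 1L)
  R0 <- as.numeric(R0); Ksv <- as.numeric(Ksv); alpha <- as.numeric(alpha)
  r_squared <- as.numeric(r_squared); resid_sd <- as.numeric(resid_sd)
  temperature_C <- as.numeric(temperature_C)
  if (!is.finite(R0) || R0 <= 0) stop("R0 must be a positive finite number")
  if (!is.finite(Ksv) || Ksv < 0) stop("Ksv must be a nonnegative finite number")
  if (!is.finite(alpha) || alpha < 0 || alpha >= 1)
    stop("alpha must lie in [0, 1)")
  structure(
    list(disk_id = disk_id, R0 = R0, Ksv = Ksv, alpha = alpha,
         ratio_def = ratio_def, conc_units = "%airsat",
         r_squared = r_squared, resid_sd = resid_sd,
         temperature_C = temperature_C,
         created_at = created_at %||%
           format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "calibration_curve")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Stern-Volmer calibration for disk '", x$disk_id, "'\n", sep = "")
  cat(sprintf("  R0 = %.4f, Ksv = %.5f per %% sat, alpha = %.4f (%s ratio)\n",
              x$R0, x$Ksv, x$alpha, x$ratio_def))
  if (is.finite(x$r_squared))
    cat(sprintf("  fit: R^2 = %.4f, residual sd = %.4g\n",
                x$r_squared, x$resid_sd))
  invisible(x)
}

#' Predicted ratio at a given oxygen saturation
#'
#' Evaluates the modified Stern-Volmer response forward: oxygen quenches the
#' red (sensing) emission, so the ratio decreases monotonically from
#' \code{R0} at zero oxygen toward the nonquenchable floor
#' \code{alpha * R0} at infinite oxygen.
#'
#' @param C oxygen concentration in % air saturation (vectorised, >= 0).
#' @param cal a \code{\link{calibration_curve}}.
#' @return Predicted ratio(s), same length as \code{C}.
#' @export
stern_volmer_forward <- function(C, cal) {
  stopifnot(inherits(cal, "calibration_curve"))
  if (any(!is.finite(C)) || any(C < 0))
    stop("C must be finite and nonnegative (% air saturation)")
  cal$R0 * (cal$alpha + (1 - cal$alpha) / (1 + cal$Ksv * C))
}

#' Back-calculate oxygen saturation from a measured ratio
#'
#' Closed-form inversion of the modified Stern-Volmer response:
#' \deqn{C = \frac{1}{K_{SV}}\left[\frac{1-\alpha}{R/R_0-\alpha} - 1\right].}
#' Ratios above \code{R0} indicate apparent super-saturation relative to the
#' calibration (for example a drifted disk); these are clamped to C = 0 with
#' a warning. Ratios at or below the nonquenchable floor \code{alpha * R0}
#' carry no concentration information and raise an error.
#'
#' @param R measured ratio(s).
#' @param cal a \code{\link{calibration_curve}} with \code{Ksv > 0}.
#' @return Oxygen concentration(s) in % air saturation.
#' @export
invert_calibration <- function(R, cal) {
  stopifnot(inherits(cal, "calibration_curve"))
  if (cal$Ksv == 0)
    stop("degenerate calibration: Ksv = 0 gives a flat response")
  if (any(!is.finite(R))) stop("R must be finite")
  floor_R <- cal$alpha * cal$R0
  if (any(R <= floor_R))
    stop("ratio at or below the nonquenchable floor alpha*R0 = ",
         signif(floor_R, 6), "; out of invertible range")
  over <- R > cal$R0
  if (any(over))
    warning(sum(over), " ratio(s) above R0: super-saturated indication, ",
            "clamped to 0% saturation")
  C <- (1 / cal$Ksv) * ((1 - cal$alpha) / (R / cal$R0 - cal$alpha) - 1)
  C[over] <- 0
  C
}

#' Fit a Stern-Volmer calibration from response-curve points
#'
#' Nonlinear least squares of the modified Stern-Volmer model against
#' (known saturation, measured ratio) points, via Levenberg-Marquardt with
#' box bounds. By default the nonquenchable fraction is fixed at zero,
#' giving the two-parameter (R0, Ksv) form; set \code{fix_alpha = FALSE} to
#' free it. Initialisation is deterministic: R0 from the ratio at the lowest
#' concentration, Ksv from a two-point estimate between the lowest and
#' highest concentrations, alpha from 0.
#'
#' @param points data.frame with columns \code{true_saturation} (% air
#'   saturation) and \code{ratio}; an optional \code{replicate_id} column is
#'   carried through untouched.
#' @param fix_alpha logical; fix alpha = 0 (default TRUE).
#' @param disk_id identifier stored on the fitted curve.
#' @param ratio_def ratio definition the points were computed with.
#' @param temperature_C optional calibration temperature.
#' @return A \code{\link{calibration_curve}} with \code{r_squared} and
#'   \code{resid_sd} filled in.
#' @export
fit_calibration <- function(points, fix_alpha = TRUE, disk_id = "unknown",
                            ratio_def = c("larsen", "simple"),
                            temperature_C = NA_real_) {
  ratio_def <- match.arg(ratio_def)
  stopifnot(is.data.frame(points),
            all(c("true_saturation", "ratio") %in% names(points)))
  pts <- points[is.finite(points$true_saturation) & is.finite(points$ratio), ]
  if (any(pts$true_saturation < 0)) stop("true_saturation must be >= 0")
  n_conc <- length(unique(pts$true_saturation))
  n_par <- if (fix_alpha) 2L else 3L
  if (n_conc < n_par + 1L)
    stop("need at least ", n_par + 1L, " distinct concentrations to fit ",
         n_par, " parameters; got ", n_conc)

  o <- order(pts$true_saturation)
  C <- pts$true_saturation[o]
  R <- pts$ratio[o]
  R0_init <- max(R[1], 1e-6)
  C_hi <- C[length(C)]
  R_hi <- R[length(R)]
  Ksv_init <- if (C_hi > C[1] && R_hi > 0 && R0_init / R_hi > 1)
    (R0_init / R_hi - 1) / (C_hi - C[1]) else 1e-3
  Ksv_init <- max(Ksv_init, 1e-8)

  df <- data.frame(C = C, R = R)
  fit <- if (fix_alpha) {
    minpack.lm::nlsLM(R ~ R0 / (1 + Ksv * C), data = df,
                      start = list(R0 = R0_init, Ksv = Ksv_init),
                      lower = c(R0 = 1e-9, Ksv = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    minpack.lm::nlsLM(R ~ R0 * (alpha + (1 - alpha) / (1 + Ksv * C)),
                      data = df,
                      start = list(R0 = R0_init, Ksv = Ksv_init, alpha = 0),
                      lower = c(R0 = 1e-9, Ksv = 0, alpha = 0),
                      upper = c(R0 = Inf, Ksv = Inf, alpha = 1 - 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  est <- stats::coef(fit)
  res <- stats::residuals(fit)
  ss_tot <- sum((R - mean(R))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  calibration_curve(
    disk_id = disk_id, R0 = unname(est["R0"]), Ksv = unname(est["Ksv"]),
    alpha = if (fix_alpha) 0 else unname(est["alpha"]),
    ratio_def = ratio_def, r_squared = r2,
    resid_sd = sqrt(mean(res^2)), temperature_C = temperature_C)
}

#' Limit of detection and quantification from calibration metrology
#'
#' Implements the 3.3-sigma / 10-sigma detection-limit convention:
#' \deqn{LOD = |3.3\,\sigma/m|, \qquad LOQ = |10\,\sigma/m|}
#' where \eqn{\sigma} is the population standard deviation of repeated
#' back-calculated measurements at a single probe concentration and \eqn{m}
#' is the ordinary-least-squares slope of the response over its linear
#' dynamic range. When the replicates and linear points are back-calculated
#' concentrations (% vs true %), \eqn{m} is close to 1 and LOD/LOQ come out
#' directly in % air saturation.
#'
#' @param probe_replicates numeric vector of back-calculated saturations at
#'   one concentration, or a data.frame with columns \code{true_saturation}
#'   and \code{measured_saturation} (all rows at one true concentration).
#' @param linear_points data.frame with columns \code{true_saturation} and
#'   \code{measured_saturation} spanning the linear range.
#' @param linear_range numeric length-2, the linear dynamic range in % air
#'   saturation used to subset \code{linear_points}. Default
#'   \code{c(0.4, 40)}.
#' @return An object of class \code{detection_limits} with fields
#'   \code{sigma}, \code{slope_m}, \code{lod}, \code{loq},
#'   \code{linear_range}. \code{loq/lod} is exactly 10/3.3.
#' @export
compute_detection_limits <- function(probe_replicates, linear_points,
                                     linear_range = c(0.4, 40)) {
  if (is.data.frame(probe_replicates)) {
    if (!all(c("true_saturation", "measured_saturation") %in%
             names(probe_replicates)))
      stop("probe_replicates data.frame needs true_saturation and ",
           "measured_saturation columns")
    if (length(unique(probe_replicates$true_saturation)) > 1L)
      stop("probe replicates must all be at one true concentration")
    reps <- probe_replicates$measured_saturation
  } else {
    reps <- as.numeric(probe_replicates)
  }
  if (length(reps) < 2L) stop("need at least 2 probe replicates")
  stopifnot(is.data.frame(linear_points),
            all(c("true_saturation", "measured_saturation") %in%
                names(linear_points)),
            length(linear_range) == 2L, linear_range[1] < linear_range[2])
  lin <- linear_points[linear_points$true_saturation >= linear_range[1] &
                       linear_points$true_saturation <= linear_range[2], ]
  if (length(unique(lin$true_saturation)) < 2L)
    stop("linear_points must span the linear range with >= 2 concentrations")

  sigma <- sqrt(mean((reps - mean(reps))^2))  # population (n-divisor) sd
  m <- stats::coef(stats::lm(measured_saturation ~ true_saturation,
                             data = lin))[["true_saturation"]]
  if (!is.finite(m) || abs(m) < 1e-12)
    stop("zero or undefined response slope over the linear range")
  lod <- abs(3.3 * sigma / m)
  structure(
    list(sigma = sigma, slope_m = m, lod = lod, loq = lod * (10 / 3.3),
         linear_range = linear_range),
    class = "detection_limits")
}

#' @export
print.detection_limits <- function(x, ...) {
  cat(sprintf(
    "Detection limits (linear range %.1f-%.1f%% sat):\n  sigma = %.4g, slope m = %.4g\n  LOD = %.2f%% sat, LOQ = %.2f%% sat\n",
    x$linear_range[1], x$linear_range[2], x$sigma, x$slope_m, x$lod, x$loq))
  invisible(x)
}

#' Summarise per-disk detection limits
#'
#' Arithmetic mean and population (n-divisor) standard deviation of a set of
#' per-disk LOD (or LOQ) values, the convention used when individual-disk
#' limits are averaged into an overall system figure.
#'
#' @param per_disk_lods numeric vector, length >= 2.
#' @return Named list with \code{mean} and \code{population_sd}.
#' @export
summarize_lods <- function(per_disk_lods) {
  x <- as.numeric(per_disk_lods)
  if (length(x) < 2L) stop("need at least 2 per-disk values")
  list(mean = mean(x), population_sd = sqrt(mean((x - mean(x))^2)))
}

#' Compare two calibration-derived samples with a Kolmogorov-Smirnov test
#'
#' Two-sample KS test with a fixed decision rule: the two calibrations are
#' declared significantly different when p < \code{alpha_level}.
#'
#' @param samples_a,samples_b numeric vectors, each length >= 2.
#' @param alpha_level significance level, default 0.05.
#' @return List with \code{ks_statistic}, \code{p_value}, \code{reject}.
#' @export
compare_calibrations <- function(samples_a, samples_b, alpha_level = 0.05) {
  if (length(samples_a) < 2L || length(samples_b) < 2L)
    stop("need at least 2 values in each sample")
  kt <- suppressWarnings(stats::ks.test(samples_a, samples_b))
  list(ks_statistic = unname(kt$statistic), p_value = kt$p.value,
       reject = kt$p.value < alpha_level)
}

#' Compare two calibration curves on a shared ratio grid
#'
#' Convenience wrapper: evaluates both calibrations' back-calculated
#' concentrations on a common grid of ratio values spanning the quenchable
#' band of both curves, then applies \code{\link{compare_calibrations}} to
#' the two concentration samples.
#'
#' @param cal_a,cal_b \code{\link{calibration_curve}} objects.
#' @param n_grid number of grid points, default 50.
#' @param alpha_level significance level passed through.
#' @return As \code{\link{compare_calibrations}}.
#' @export
compare_calibration_curves <- function(cal_a, cal_b, n_grid = 50,
                                       alpha_level = 0.05) {
  lo <- max(cal_a$alpha * cal_a$R0, cal_b$alpha * cal_b$R0)
  hi <- min(cal_a$R0, cal_b$R0)
  if (hi <= lo) stop("calibrations share no common invertible ratio band")
  grid <- seq(lo + 0.02 * (hi - lo), hi, length.out = n_grid)
  compare_calibrations(invert_calibration(grid, cal_a),
                       invert_calibration(grid, cal_b),
                       alpha_level = alpha_level)
}

#' Normalise ratios to a maximum of one
#'
#' @param ratios numeric vector with a positive maximum.
#' @return \code{ratios / max(ratios)}.
#' @export
normalize_ratios <- function(ratios) {
  m <- max(ratios)
  if (!is.finite(m) || m <= 0)
    stop("cannot normalise: maximum ratio is not positive")
  ratios / m
}

#' Read and write a JSON calibration registry
#'
#' The registry is a JSON file keyed by disk_id; each entry stores every
#' calibration-curve field plus free-form provenance. Round-trips
#' losslessly.
#'
#' @param path registry file path.
#' @param registry named list of \code{\link{calibration_curve}} objects
#'   (names are disk ids).
#' @return \code{read_calibration_registry} returns a named list of
#'   \code{calibration_curve} objects; \code{write_calibration_registry}
#'   returns \code{path} invisibly.
#' @export
read_calibration_registry <- function(path) {
  if (!file.exists(path)) return(structure(list(), names = character()))
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(raw, function(e) {
    cal <- calibration_curve(
      disk_id = e$disk_id, R0 = e$R0, Ksv = e$Ksv, alpha = e$alpha,
      ratio_def = e$ratio_def,
      r_squared = e$r_squared %||% NA_real_,
      resid_sd = e$resid_sd %||% NA_real_,
      temperature_C = e$temperature_C %||% NA_real_,
      created_at = e$created_at)
    attr(cal, "provenance") <- e$provenance
    cal
  })
  names(out) <- vapply(out, function(cal) cal$disk_id, character(1))
  out
}

#' @rdname read_calibration_registry
#' @export
write_calibration_registry <- function(registry, path) {
  entries <- lapply(registry, function(cal) {
    stopifnot(inherits(cal, "calibration_curve"))
    e <- unclass(cal)
    e$provenance <- attr(cal, "provenance")
    e
  })
  names(entries) <- vapply(registry, function(cal) cal$disk_id, character(1))
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read calibration points from CSV
#'
#' Expected columns: \code{disk_id}, \code{true_saturation_pct},
#' \code{ratio}, and optionally \code{replicate_id}.
#'
#' @param path CSV file path.
#' @return data.frame with columns \code{disk_id}, \code{true_saturation},
#'   \code{ratio}, \code{replicate_id}.
#' @export
read_calibration_points <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("disk_id", "true_saturation_pct", "ratio")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("calibration points CSV missing column(s): ",
         paste(miss, collapse = ", "))
  data.frame(disk_id = as.character(df$disk_id),
             true_saturation = as.numeric(df$true_saturation_pct),
             ratio = as.numeric(df$ratio),
             replicate_id = if ("replicate_id" %in% names(df))
               df$replicate_id else seq_len(nrow(df)),
             stringsAsFactors = FALSE)
}
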