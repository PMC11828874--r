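#' Exact (Garwood) Poisson confidence limits on the dicentric yield
#'
#' Exact chi-square limits on the mean of a Poisson total `X` over `N` cells,
#' divided by `N`: lower `qchisq(a/2, 2X)/2/N` (0 when `X = 0`), upper
#' `qchisq(1 - a/2, 2X + 2)/2/N`. Preferred over the normal approximation at
#' the low counts of triage scoring.
#'
#' @param X total dicentrics observed (non-negative integer).
#' @param N number of cells scored (>= 1).
#' @param level two-sided confidence level.
#' @return `c(lower, upper)` limits on the yield (dicentrics/cell).
#' @examples
#' poisson_yield_ci(10, 100)  # c(0.04795, 0.18390)
#' @export
poisson_yield_ci <- function(X, N, level = 0.95) {
  if (N < 1) stop("'N' must be at least 1", call. = FALSE)
  if (X < 0 || abs(X - round(X)) > 1e-8)
    stop("'X' must be a non-negative integer", call. = FALSE)
  if (level <= 0 || level >= 1)
    stop("'level' must be in (0, 1)", call. = FALSE)
  a <- 1 - level
  lower <- if (X == 0) 0 else stats::qchisq(a / 2, 2 * X) / 2
  upper <- stats::qchisq(1 - a / 2, 2 * X + 2) / 2
  c(lower = lower / N, upper = upper / N)
}

#' Invert a linear-quadratic curve: yield to dose
#'
#' Returns the non-negative root of `beta*D^2 + alpha*D + (C - yield) = 0`,
#' i.e. the dose whose expected yield equals `yield`; 0 when the yield does
#' not exceed the background, and the linear solution when `beta = 0`.
#'
#' @param curve an [lq_curve()].
#' @param yield observed dicentrics per cell (>= 0).
#' @return dose in Gy.
#' @export
invert_dose <- function(curve, yield) {
  stopifnot(inherits(curve, "lq_curve"))
  if (any(yield < 0)) stop("'yield' must be non-negative", call. = FALSE)
  th <- curve$coefficients
  C <- th[["C"]]; a <- th[["alpha"]]; b <- th[["beta"]]
  vapply(yield, function(y) {
    if (y <= C) return(0)
    if (b == 0) {
      if (a == 0)
        stop("curve has alpha = beta = 0: no dose yields ", y, call. = FALSE)
      return((y - C) / a)
    }
    # numerically stable positive root
    (-a + sqrt(a^2 + 4 * b * (y - C))) / (2 * b)
  }, numeric(1))
}

#' Dose estimate with a 95% confidence interval
#'
#' Inverts a calibration curve at the observed yield `X/N` and attaches a
#' confidence interval by one of two methods:
#'
#' * `"curve_plus_yield"` (default): Merkle-style combination. Exact Poisson
#'   limits on the yield are taken at 83% confidence, the fitted curve is
#'   bracketed by its 83% envelope `Yhat(D) +/- z83 * se(D)`, and the dose
#'   limits are the crossings of the sample's yield limits with the opposite
#'   envelope bounds (found by root bisection). Combining the two 83% bands
#'   targets ~95% overall coverage; this is the convention of the standard
#'   biodosimetry software.
#' * `"yield_only"`: inversion of the exact Poisson yield limits at the full
#'   requested level, ignoring the curve error (the behaviour of software
#'   that does not propagate curve uncertainty).
#'
#' @param curve an [lq_curve()] with covariance (required for
#'   `"curve_plus_yield"`).
#' @param sample a [dicentric_dist()] (dose may be `NA`; only `N` and `X`
#'   are used).
#' @param method confidence-interval method.
#' @param conf.level overall confidence level of the reported interval.
#' @param merkle.level confidence taken for each of the two combined bands
#'   under `"curve_plus_yield"`.
#' @return An object of class `dose_estimate`: list with `dose`, `ci_low`,
#'   `ci_high` (Gy, on the curve's dose scale), `method`, `dose_definition`,
#'   `extrapolated` (point estimate beyond the curve's maximum calibration
#'   dose), `n_cells`, `n_dicentrics`.
#' @examples
#' cv <- lq_curve(0.001, 0.02, 0.06, cov = diag(c(1e-8, 1e-6, 1e-6)),
#'                max_dose = 5)
#' estimate_dose(cv, dicentric_dist(c(155, 38, 6, 1)))
#' @export
estimate_dose <- function(curve, sample,
                          method = c("curve_plus_yield", "yield_only"),
                          conf.level = 0.95, merkle.level = 0.83) {
  stopifnot(inherits(curve, "lq_curve"))
  method <- match.arg(method)
  sample <- as_dist_list(sample)[[1]]
  N <- sample$n_cells; X <- sample$dicentrics
  if (N < 1) stop("sample must contain at least one cell", call. = FALSE)

  ybar <- X / N
  dose <- invert_dose(curve, ybar)

  if (method == "yield_only") {
    yl <- poisson_yield_ci(X, N, level = conf.level)
    ci <- c(invert_dose(curve, yl[[1]]), invert_dose(curve, yl[[2]]))
  } else {
    if (is.null(curve$cov))
      stop("curve carries no coefficient covariance: use method = ",
           "\"yield_only\" or supply a covariance", call. = FALSE)
    z <- stats::qnorm(1 - (1 - merkle.level) / 2)
    yl <- poisson_yield_ci(X, N, level = merkle.level)
    se_at <- function(D) sqrt(yield_variance(curve, D))
    dmax <- 3 * curve$max_dose
    # upper dose limit: lower curve envelope meets the upper yield limit
    fU <- function(D) curve_yield(curve, D) - z * se_at(D) - yl[[2]]
    ci_high <- if (fU(dmax) < 0) {
      warning("upper confidence bound beyond 3x the maximum calibration ",
              "dose; truncated")
      dmax
    } else if (fU(0) >= 0) 0 else
      stats::uniroot(fU, c(0, dmax), tol = 1e-6)$root
    # lower dose limit: upper curve envelope meets the lower yield limit
    fL <- function(D) curve_yield(curve, D) + z * se_at(D) - yl[[1]]
    ci_low <- if (fL(0) >= 0) 0 else if (fL(dmax) < 0) {
      warning("lower confidence bound beyond 3x the maximum calibration ",
              "dose; truncated")
      dmax
    } else stats::uniroot(fL, c(0, dmax), tol = 1e-6)$root
    ci <- c(ci_low, ci_high)
  }

  structure(
    list(dose = dose, ci_low = min(ci[1], dose), ci_high = max(ci[2], dose),
         method = method, conf.level = conf.level,
         dose_definition = curve$dose_definition,
         extrapolated = dose > curve$max_dose,
         n_cells = as.integer(N), n_dicentrics = as.integer(X)),
    class = "dose_estimate")
}

#' @export
print.dose_estimate <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Dose estimate: %.*f Gy (%.0f%% CI %.*f - %.*f), %s\n",
    digits, x$dose, 100 * x$conf.level, digits, x$ci_low, digits, x$ci_high,
    gsub("_", " ", x$dose_definition)))
  cat(sprintf("  method: %s; N = %d cells, X = %d dicentrics%s\n",
              x$method, x$n_cells, x$n_dicentrics,
              if (x$extrapolated) "; EXTRAPOLATED beyond calibration range"
              else ""))
  invisible(x)
}

#' Air kerma to dose-to-blood conversion table
#'
#' Anchor pairs relating air kerma free in air to the absorbed dose to blood
#' inside the collection tube (obtained from radiation-transport
#' calculations for the irradiation geometry). Between anchors the
#' conversion factor is interpolated linearly in air kerma; outside the
#' anchor range the nearest factor is applied unchanged.
#'
#' The default table carries the three anchor pairs of a cobalt-60
#' irradiation of blood tubes in air: 2.56 -> 2.71, 3.41 -> 3.60 and
#' 4.54 -> 4.80 Gy (factors of about 1.057).
#'
#' @param air_kerma,dose_to_blood strictly increasing anchor doses (Gy); the
#'   implied factors must lie in \[1.0, 1.2\].
#' @return An object of class `dose_conversion_table`.
#' @export
dose_conversion_table <- function(air_kerma = c(2.56, 3.41, 4.54),
                                  dose_to_blood = c(2.71, 3.60, 4.80)) {
  if (length(air_kerma) != length(dose_to_blood) || length(air_kerma) < 1)
    stop("anchor vectors must be non-empty and of equal length", call. = FALSE)
  if (length(air_kerma) > 1 &&
      (is.unsorted(air_kerma, strictly = TRUE) ||
       is.unsorted(dose_to_blood, strictly = TRUE)))
    stop("anchors must be strictly increasing in both coordinates",
         call. = FALSE)
  f <- dose_to_blood / air_kerma
  if (any(f < 1) || any(f > 1.2))
    stop("conversion factors dose_to_blood/air_kerma must lie in [1.0, 1.2]",
         call. = FALSE)
  structure(list(air_kerma = air_kerma, dose_to_blood = dose_to_blood,
                 factor = f),
            class = "dose_conversion_table")
}

#' @export
print.dose_conversion_table <- function(x, ...) {
  cat("Air kerma -> dose-to-blood conversion table\n")
  print(data.frame(air_kerma = x$air_kerma, dose_to_blood = x$dose_to_blood,
                   factor = round(x$factor, 5)))
  invisible(x)
}

kerma_to_blood <- function(value, table) {
  f <- stats::approx(table$air_kerma, table$factor, xout = value,
                     rule = 2)$y  # rule 2: constant beyond the anchors
  value * f
}

#' Convert a dose between dose definitions
#'
#' Supported: identity conversions and air kerma <-> absorbed dose to blood
#' via a [dose_conversion_table()]. The blood-to-kerma direction inverts the
#' interpolated forward map numerically and round-trips to 1e-10 Gy.
#' Conversions involving dose to water are not defined here and fail loudly.
#'
#' @param value dose(s) in Gy.
#' @param from,to dose definitions: `"air_kerma"`, `"dose_to_water"`,
#'   `"dose_to_blood"`.
#' @param table a [dose_conversion_table()].
#' @return converted dose(s) in Gy.
#' @examples
#' convert_dose(2.56, "air_kerma", "dose_to_blood")  # 2.71
#' @export
convert_dose <- function(value, from, to, table = dose_conversion_table()) {
  defs <- c("air_kerma", "dose_to_water", "dose_to_blood")
  from <- match.arg(from, defs); to <- match.arg(to, defs)
  stopifnot(inherits(table, "dose_conversion_table"))
  if (any(value < 0)) stop("'value' must be non-negative", call. = FALSE)
  if (from == to) return(value)
  if (from == "air_kerma" && to == "dose_to_blood")
    return(kerma_to_blood(value, table))
  if (from == "dose_to_blood" && to == "air_kerma") {
    return(vapply(value, function(v) {
      if (v == 0) return(0)
      lo <- v / 1.2; hi <- v
      stats::uniroot(function(k) kerma_to_blood(k, table) - v,
                     c(lo * 0.999, hi * 1.001), tol = 1e-12)$root
    }, numeric(1)))
  }
  stop(sprintf("conversion %s -> %s is not supported (only air kerma <-> ",
               from, to), "dose to blood)", call. = FALSE)
}
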