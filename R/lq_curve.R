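#' Linear-quadratic dicentric dose-effect curve
#'
#' Constructs a calibration-curve object from known coefficients, e.g. when a
#' laboratory reports its published curve rather than raw calibration counts.
#' The curve describes the expected dicentric yield per cell as
#' \deqn{Y(D) = C + \alpha D + \beta D^2}
#' with `C` the background yield (dicentrics/cell), `alpha` in 1/Gy and
#' `beta` in 1/Gy^2.
#'
#' @param C,alpha,beta non-negative curve coefficients.
#' @param cov optional 3x3 symmetric covariance matrix of `(C, alpha, beta)`;
#'   `NULL` means the curve error is unknown and only yield-error-only dose
#'   confidence intervals are available.
#' @param dose_definition dose definition the curve was calibrated in:
#'   `"air_kerma"`, `"dose_to_water"` or `"dose_to_blood"`.
#' @param scoring_mode `"manual"` or `"semi_automatic"`.
#' @param max_dose maximum dose (Gy) used to establish the curve; dose
#'   estimates beyond it are flagged as extrapolated.
#' @param n_dose_points number of calibration dose points, if known.
#'
#' @return An object of class `lq_curve`.
#' @seealso [fit_lq_curve()] to estimate a curve from scored calibration data.
#' @examples
#' cv <- lq_curve(C = 0.001, alpha = 0.02, beta = 0.06, max_dose = 5)
#' curve_yield(cv, 2.56)
#' @export
lq_curve <- function(C, alpha, beta, cov = NULL,
                     dose_definition = c("air_kerma", "dose_to_water",
                                         "dose_to_blood"),
                     scoring_mode = c("manual", "semi_automatic"),
                     max_dose = 5, n_dose_points = NA_integer_) {
  dose_definition <- match.arg(dose_definition)
  scoring_mode <- match.arg(scoring_mode)
  coefs <- c(C = C, alpha = alpha, beta = beta)
  if (anyNA(coefs) || any(coefs < 0))
    stop("curve coefficients must be non-negative and non-missing",
         call. = FALSE)
  if (!is.null(cov)) {
    cov <- as.matrix(cov)
    if (!identical(dim(cov), c(3L, 3L)))
      stop("'cov' must be a 3x3 matrix over (C, alpha, beta)", call. = FALSE)
    if (max(abs(cov - t(cov))) > 1e-8 * (1 + max(abs(cov))))
      stop("'cov' must be symmetric", call. = FALSE)
    if (any(diag(cov) < -1e-12))
      stop("'cov' must have non-negative diagonal", call. = FALSE)
    dimnames(cov) <- list(names(coefs), names(coefs))
  }
  if (!is.numeric(max_dose) || max_dose <= 0)
    stop("'max_dose' must be positive", call. = FALSE)
  structure(
    list(coefficients = coefs, cov = cov,
         dose_definition = dose_definition, scoring_mode = scoring_mode,
         max_dose = max_dose, n_dose_points = n_dose_points,
         deviance = NA_real_, df = NA_integer_, fitted_from = NULL),
    class = "lq_curve"
  )
}

#' Fit a linear-quadratic dose-effect curve by Poisson maximum likelihood
#'
#' Estimates `(C, alpha, beta)` of the identity-link Poisson model
#' \eqn{X_i \sim \mathrm{Poisson}(N_i (C + \alpha D_i + \beta D_i^2))}
#' from per-dose dicentric totals, the conventional model for dicentric
#' calibration data scored under homogeneous acute exposure. Fitting uses
#' iteratively reweighted least squares on the sufficient statistics
#' \eqn{(N_i, X_i)} with an active-set projection keeping all coefficients
#' non-negative; the coefficient covariance is the inverse observed Fisher
#' information at the optimum (rows/columns of coefficients held at the
#' boundary are zero).
#'
#' @param data calibration data: a list of [dicentric_dist()] objects with
#'   doses, or a data.frame with columns `dose`, `n_cells` and either
#'   `dicentrics` (per-dose totals) or wide count columns `c0, c1, ...`.
#' @param dose_definition,scoring_mode metadata recorded on the returned
#'   curve (see [lq_curve()]).
#' @param overdispersion if `TRUE` and the fit shows lack of fit
#'   (deviance/df > 1), the covariance is inflated by the heterogeneity
#'   factor deviance/df (quasi-likelihood). Off by default.
#' @param tol relative deviance change declaring convergence.
#' @param max_iter iteration cap; non-convergence raises an error reporting
#'   the last iterate.
#'
#' @return An `lq_curve` object carrying, in addition to the fields of
#'   [lq_curve()], the `deviance`, residual `df` and the aggregated fitting
#'   data (`fitted_from`: dose, n_cells, dicentrics per dose point).
#' @examples
#' set.seed(1)
#' doses <- c(0, 0.5, 1, 2, 3, 4, 5)
#' cal <- lapply(doses, function(D)
#'   simulate_distribution(c(0.001, 0.03, 0.06), D, n_cells = 2000))
#' fit <- fit_lq_curve(cal)
#' coef(fit)
#' @export
fit_lq_curve <- function(data,
                         dose_definition = c("air_kerma", "dose_to_water",
                                             "dose_to_blood"),
                         scoring_mode = c("manual", "semi_automatic"),
                         overdispersion = FALSE,
                         tol = 1e-10, max_iter = 100L) {
  dose_definition <- match.arg(dose_definition)
  scoring_mode <- match.arg(scoring_mode)

  agg <- aggregate_calibration(data)
  D <- agg$dose; N <- agg$n_cells; X <- agg$dicentrics
  if (length(unique(D)) < 3L)
    stop("calibration design error: at least 3 distinct dose points are ",
         "needed to identify (C, alpha, beta)", call. = FALSE)

  Z <- cbind(C = N, alpha = N * D, beta = N * D^2)
  fit <- irls_nonneg_poisson(Z, X, tol = tol, max_iter = max_iter)

  theta <- fit$theta
  names(theta) <- colnames(Z)
  dev <- fit$deviance
  df <- length(X) - sum(fit$free)
  cov <- fit$cov
  dimnames(cov) <- list(names(theta), names(theta))
  if (overdispersion && df > 0 && dev / df > 1)
    cov <- cov * (dev / df)

  out <- lq_curve(theta[["C"]], theta[["alpha"]], theta[["beta"]], cov = cov,
                  dose_definition = dose_definition,
                  scoring_mode = scoring_mode,
                  max_dose = max(D), n_dose_points = length(unique(D)))
  out$deviance <- dev
  out$df <- df
  out$iterations <- fit$iterations
  out$fitted_from <- data.frame(dose = D, n_cells = N, dicentrics = X)
  out
}

aggregate_calibration <- function(data) {
  if (is.data.frame(data) && all(c("dose", "n_cells", "dicentrics") %in%
                                 names(data)) &&
      !any(grepl("^c[0-9]+$", names(data)))) {
    df <- data[, c("dose", "n_cells", "dicentrics")]
  } else {
    dists <- as_dist_list(data)
    dose <- vapply(dists, `[[`, numeric(1), "dose")
    if (anyNA(dose))
      stop("every calibration distribution needs a dose", call. = FALSE)
    df <- data.frame(dose = dose,
                     n_cells = vapply(dists, `[[`, numeric(1), "n_cells"),
                     dicentrics = vapply(dists, `[[`, numeric(1), "dicentrics"))
  }
  if (any(df$dose < 0)) stop("doses must be non-negative", call. = FALSE)
  if (any(df$n_cells < 1)) stop("each dose point needs cells", call. = FALSE)
  # pool replicate rows at the same dose: the Poisson likelihood depends
  # only on per-dose totals
  agg <- stats::aggregate(cbind(n_cells, dicentrics) ~ dose, data = df, FUN = sum)
  agg[order(agg$dose), , drop = FALSE]
}

# IRLS for X ~ Poisson(Z theta), theta >= 0, with an active-set handling of
# coefficients driven to the boundary. Returns the MLE over the non-negative
# orthant, its deviance and the inverse Fisher information (zero rows/cols
# for bound coefficients).
irls_nonneg_poisson <- function(Z, X, tol = 1e-10, max_iter = 100L) {
  p <- ncol(Z)
  free <- rep(TRUE, p)
  released <- rep(0L, p)
  mu_floor <- 1e-12

  solve_free <- function(free) {
    Zf <- Z[, free, drop = FALSE]
    # start from a weighted LS fit with working weights from mu0 = X + 0.5
    mu <- pmax(X, 0.5)
    theta_f <- rep(0, sum(free))
    dev_old <- Inf
    for (it in seq_len(max_iter)) {
      W <- 1 / pmax(mu, mu_floor)
      A <- crossprod(Zf, W * Zf)
      b <- crossprod(Zf, W * X)
      theta_new <- tryCatch(drop(solve(A, b)),
                            error = function(e) drop(qr.solve(A, b)))
      theta_new <- pmax(theta_new, 0)
      # step-halving if the deviance would increase
      for (h in 1:20) {
        mu_new <- pmax(drop(Zf %*% theta_new), mu_floor)
        dev <- poisson_deviance(X, mu_new)
        if (!is.finite(dev_old) || dev <= dev_old + 1e-12 * (abs(dev_old) + 1))
          break
        theta_new <- (theta_new + theta_f) / 2
      }
      if (is.finite(dev_old) &&
          abs(dev_old - dev) <= tol * (abs(dev) + 1)) {
        return(list(theta = theta_new, mu = mu_new, deviance = dev,
                    iterations = it, converged = TRUE))
      }
      dev_old <- dev
      mu <- mu_new
      theta_f <- theta_new
    }
    # IRLS converges only linearly when a coefficient drifts to the boundary
    # (e.g. C with no dicentrics scored at dose zero): finish with a bounded
    # quasi-Newton step on the deviance, which lands on the boundary exactly
    dev_fn <- function(th) poisson_deviance(X, pmax(drop(Zf %*% th), mu_floor))
    dev_gr <- function(th) {
      mu <- pmax(drop(Zf %*% th), mu_floor)
      2 * drop(crossprod(Zf, 1 - X / mu))
    }
    opt <- stats::optim(theta_f, dev_fn, dev_gr, method = "L-BFGS-B",
                        lower = 0, control = list(factr = 1e4, maxit = 500))
    if (opt$convergence != 0) {
      # the line search can stall at an already-optimal boundary point;
      # accept the iterate iff the projected-gradient KKT conditions hold
      g <- dev_gr(opt$par)
      kkt_tol <- 1e-6 * (sum(X) + 1)
      kkt_ok <- all(abs(g[opt$par > 0]) < kkt_tol) &&
        all(g[opt$par <= 0] > -kkt_tol)
      if (!kkt_ok)
        stop(sprintf(
          "LQ curve fit did not converge within the iteration cap; last iterate: %s",
          paste(signif(opt$par, 6), collapse = ", ")), call. = FALSE)
    }
    list(theta = opt$par, mu = pmax(drop(Zf %*% opt$par), mu_floor),
         deviance = opt$value, iterations = max_iter, converged = TRUE)
  }

  for (pass in seq_len(4L * p + 2L)) {
    res <- solve_free(free)
    theta <- numeric(p)
    theta[free] <- res$theta
    at_bound <- free & (theta <= 0)
    if (any(at_bound)) { # pin boundary coefficients and refit the rest
      free <- free & !at_bound
      if (!any(free))
        stop("degenerate calibration data: all coefficients at zero",
             call. = FALSE)
      next
    }
    # KKT check: a pinned coefficient with positive score should be released
    mu <- pmax(drop(Z %*% theta), mu_floor)
    score <- drop(crossprod(Z, X / mu - 1))
    release <- !free & score > 1e-8 * sum(X + 1) & released < 1L
    if (any(release)) {
      j <- which(release)[1L]
      released[j] <- released[j] + 1L
      free[j] <- TRUE
      next
    }
    # covariance from the Fisher information of the free block
    Zf <- Z[, free, drop = FALSE]
    info <- crossprod(Zf, (1 / mu) * Zf)
    covf <- tryCatch(solve(info), error = function(e) {
      warning("Fisher information singular; covariance unavailable")
      matrix(NA_real_, sum(free), sum(free))
    })
    cov <- matrix(0, p, p)
    cov[free, free] <- covf
    return(list(theta = theta, cov = cov, deviance = res$deviance,
                iterations = res$iterations, free = free))
  }
  stop("active-set iteration failed to settle", call. = FALSE)
}

poisson_deviance <- function(X, mu) {
  term <- ifelse(X > 0, X * log(X / mu), 0)
  2 * sum(term - (X - mu))
}

#' Expected dicentric yield of a curve at a dose
#'
#' @param curve an [lq_curve()] object.
#' @param dose dose(s) in Gy, non-negative.
#' @return `C + alpha * dose + beta * dose^2`, dicentrics per cell.
#' @export
curve_yield <- function(curve, dose) {
  stopifnot(inherits(curve, "lq_curve"))
  if (any(dose < 0)) stop("'dose' must be non-negative", call. = FALSE)
  th <- curve$coefficients
  th[["C"]] + th[["alpha"]] * dose + th[["beta"]] * dose^2
}

#' Variance of the predicted yield at a dose
#'
#' Propagates the coefficient covariance through the linear-quadratic form:
#' `g' Sigma g` with `g = (1, D, D^2)`.
#'
#' @inheritParams curve_yield
#' @return variance(s) of the predicted yield; errors if the curve carries no
#'   covariance, in which case only yield-error-only dose intervals are
#'   possible.
#' @export
yield_variance <- function(curve, dose) {
  stopifnot(inherits(curve, "lq_curve"))
  if (any(dose < 0)) stop("'dose' must be non-negative", call. = FALSE)
  if (is.null(curve$cov))
    stop("curve carries no coefficient covariance: only the yield-error-only ",
         "confidence-interval method is available", call. = FALSE)
  vapply(dose, function(D) {
    g <- c(1, D, D^2)
    max(0, drop(g %*% curve$cov %*% g))
  }, numeric(1))
}

#' @export
coef.lq_curve <- function(object, ...) object$coefficients

#' @export
vcov.lq_curve <- function(object, ...) object$cov

#' @export
fitted.lq_curve <- function(object, ...) {
  if (is.null(object$fitted_from))
    stop("curve was not fitted from data", call. = FALSE)
  with(object$fitted_from, n_cells * curve_yield(object, dose))
}

#' @export
residuals.lq_curve <- function(object, type = c("deviance", "pearson"), ...) {
  type <- match.arg(type)
  if (is.null(object$fitted_from))
    stop("curve was not fitted from data", call. = FALSE)
  X <- object$fitted_from$dicentrics
  mu <- fitted(object)
  if (type == "pearson") return((X - mu) / sqrt(mu))
  sign(X - mu) * sqrt(pmax(0, 2 * (ifelse(X > 0, X * log(X / mu), 0) - (X - mu))))
}

#' Predicted yield with optional standard error
#'
#' @param object an `lq_curve`.
#' @param dose doses (Gy) at which to predict; defaults to the calibration
#'   doses for a fitted curve.
#' @param se.fit also return the standard error of the predicted yield.
#' @param ... unused.
#' @export
predict.lq_curve <- function(object, dose = NULL, se.fit = FALSE, ...) {
  if (is.null(dose)) {
    if (is.null(object$fitted_from))
      stop("supply 'dose' for a curve not fitted from data", call. = FALSE)
    dose <- object$fitted_from$dose
  }
  y <- curve_yield(object, dose)
  if (!se.fit) return(y)
  list(fit = y, se.fit = sqrt(yield_variance(object, dose)))
}

#' @export
print.lq_curve <- function(x, digits = 4, ...) {
  cat(sprintf("Linear-quadratic dicentric dose-effect curve (%s scoring, %s)\n",
              x$scoring_mode, gsub("_", " ", x$dose_definition)))
  cat("  Y(D) = C + alpha*D + beta*D^2\n")
  se <- if (!is.null(x$cov)) sqrt(pmax(0, diag(x$cov))) else rep(NA_real_, 3)
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = se)
  print(signif(tab, digits))
  if (!is.na(x$deviance))
    cat(sprintf("  deviance %.4g on %d df; max calibration dose %g Gy\n",
                x$deviance, x$df, x$max_dose))
  else
    cat(sprintf("  max calibration dose %g Gy\n", x$max_dose))
  invisible(x)
}

#' @export
summary.lq_curve <- function(object, ...) {
  se <- if (!is.null(object$cov)) sqrt(pmax(0, diag(object$cov)))
        else rep(NA_real_, 3)
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, deviance = object$deviance, df = object$df,
              dose_definition = object$dose_definition,
              scoring_mode = object$scoring_mode, max_dose = object$max_dose)
  class(out) <- "summary.lq_curve"
  out
}

#' @export
print.summary.lq_curve <- function(x, digits = 4, ...) {
  cat("Linear-quadratic dicentric dose-effect curve\n\n")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  if (!is.na(x$deviance))
    cat(sprintf("\nDeviance: %.4g on %d residual df (deviance/df = %.3f)\n",
                x$deviance, x$df,
                if (x$df > 0) x$deviance / x$df else NA_real_))
  cat(sprintf("Scoring: %s; dose definition: %s; max calibration dose %g Gy\n",
              x$scoring_mode, gsub("_", " ", x$dose_definition), x$max_dose))
  invisible(x)
}

#' @export
plot.lq_curve <- function(x, n = 200, ...) {
  D <- seq(0, x$max_dose, length.out = n)
  y <- curve_yield(x, D)
  graphics::plot(D, y, type = "l", xlab = "Dose (Gy)",
                 ylab = "Dicentrics per cell",
                 main = "Dose-effect curve", ...)
  if (!is.null(x$cov)) {
    se <- sqrt(yield_variance(x, D))
    graphics::lines(D, y + 1.96 * se, lty = 2)
    graphics::lines(D, pmax(0, y - 1.96 * se), lty = 2)
  }
  if (!is.null(x$fitted_from))
    graphics::points(x$fitted_from$dose,
                     x$fitted_from$dicentrics / x$fitted_from$n_cells, pch = 16)
  invisible(x)
}

#' Simulate scored count distributions from a curve
#'
#' @param object an `lq_curve`.
#' @param nsim number of replicate datasets.
#' @param seed optional seed, set before simulating.
#' @param dose doses (Gy) to score at; defaults to the calibration doses of a
#'   fitted curve.
#' @param n_cells cells per dose (recycled).
#' @param dispersion variance-to-mean ratio of the per-cell counts (1 =
#'   Poisson), see [simulate_distribution()].
#' @param ... unused.
#' @return A list of `nsim` lists of [dicentric_dist()] objects.
#' @export
simulate.lq_curve <- function(object, nsim = 1, seed = NULL, dose = NULL,
                              n_cells = 200, dispersion = 1, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dose)) {
    if (is.null(object$fitted_from))
      stop("supply 'dose' for a curve not fitted from data", call. = FALSE)
    dose <- object$fitted_from$dose
    n_cells <- object$fitted_from$n_cells
  }
  n_cells <- rep_len(n_cells, length(dose))
  th <- object$coefficients
  replicate(nsim, simplify = FALSE,
            mapply(function(D, N)
              simulate_distribution(th, D, N, dispersion = dispersion),
              dose, n_cells, SIMPLIFY = FALSE))
}
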