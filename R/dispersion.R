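#' Dispersion index of a dicentric count distribution
#'
#' The variance-to-mean ratio `delta = sigma^2 / mu` of the per-cell
#' dicentric counts, with the sample variance taken over `N - 1`. Under a
#' homogeneous acute whole-body exposure the counts are Poisson and
#' `delta = 1`; `delta > 1` (overdispersion) is the signature of a
#' heterogeneous or partial-body exposure, or of semi-automatic scoring
#' artefacts.
#'
#' @param sample a [dicentric_dist()] with `N >= 2` cells and at least one
#'   dicentric (the index is undefined at mean zero).
#' @return the dispersion index (dimensionless).
#' @export
dispersion_index <- function(sample) {
  sample <- as_dist_list(sample)[[1]]
  if (sample$n_cells < 2)
    stop("dispersion index needs at least 2 cells", call. = FALSE)
  if (sample$dicentrics == 0)
    stop("dispersion index undefined: no dicentrics observed (mean zero)",
         call. = FALSE)
  cells <- cells_of(sample)
  stats::var(cells) / mean(cells)
}

#' Papworth U-test for departure from Poisson dispersion
#'
#' Tests the dispersion index against its Poisson sampling distribution:
#' \deqn{u = (\delta - 1)\sqrt{\frac{N - 1}{2(1 - 1/X)}}}
#' which is approximately standard normal under the Poisson null, so
#' `u > 1.96` signals significant overdispersion at P < 0.05 (one-sided) and
#' `|u| > 1.96` a two-sided departure.
#'
#' @param sample a [dicentric_dist()] with `N >= 2` and `X >= 2` (the factor
#'   `1 - 1/X` must be positive).
#' @param threshold significance threshold on `|u|`; the default is the
#'   two-sided 5% normal critical value, see [u_critical()].
#' @return An object of class `dispersion_result`: list with `delta`,
#'   `u_statistic`, `significant` (two-sided, `|u| > threshold`),
#'   `significant_over` (one-sided, `u > threshold`), `direction`
#'   (`"over"`, `"under"` or `"none"`), `n_cells`, `total_dicentrics`,
#'   `threshold`.
#' @examples
#' set.seed(1)
#' u_test(simulate_distribution(c(0.001, 0.03, 0.06), 3, 200))
#' @export
u_test <- function(sample, threshold = u_critical()) {
  sample <- as_dist_list(sample)[[1]]
  N <- sample$n_cells; X <- sample$dicentrics
  if (N < 2) stop("U-test needs at least 2 cells", call. = FALSE)
  if (X < 2)
    stop("U-test undefined for X < 2 dicentrics: the normalising factor ",
         "1 - 1/X is not positive and finite", call. = FALSE)
  delta <- dispersion_index(sample)
  u <- (delta - 1) * sqrt((N - 1) / (2 * (1 - 1 / X)))
  significant <- abs(u) > threshold
  structure(
    list(delta = delta, u_statistic = u,
         significant = significant,
         significant_over = u > threshold,
         direction = if (!significant) "none" else if (u > 0) "over" else "under",
         n_cells = as.integer(N), total_dicentrics = as.integer(X),
         threshold = threshold),
    class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, digits = 4, ...) {
  cat(sprintf("Dispersion: delta = %.*g, u = %.*g (N = %d, X = %d)\n",
              digits, x$delta, digits, x$u_statistic, x$n_cells,
              x$total_dicentrics))
  cat(sprintf("  |u| > %.3g: %s%s\n", x$threshold,
              if (x$significant) "significant" else "not significant",
              if (x$direction == "none") "" else paste0(" (", x$direction,
                                                        "dispersed)")))
  invisible(x)
}

#' Critical value of the U-test
#'
#' Standard-normal critical value for a two-sided test at significance
#' `alpha`; 1.96 at the conventional 5% level.
#'
#' @param alpha two-sided significance level.
#' @export
u_critical <- function(alpha = 0.05) stats::qnorm(1 - alpha / 2)

#' Mean dispersion index across laboratories
#'
#' Unweighted arithmetic mean of the dispersion indices reported by several
#' laboratories for one blind sample (each laboratory counts equally,
#' regardless of cells scored).
#'
#' @param results a non-empty list of [u_test()] / `dispersion_result`
#'   objects, or a numeric vector of dispersion indices.
#' @export
mean_dispersion <- function(results) {
  if (length(results) == 0) stop("'results' must be non-empty", call. = FALSE)
  if (is.numeric(results)) return(mean(results))
  mean(vapply(results, function(r) {
    if (inherits(r, "dispersion_result")) r$delta
    else stop("elements must be dispersion_result objects", call. = FALSE)
  }, numeric(1)))
}
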