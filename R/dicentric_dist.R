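#' Dicentric count distribution for one scored sample
#'
#' The raw unit of dicentric scoring: for a single sample (a calibration dose
#' point or a blind sample), the number of cells observed with exactly
#' 0, 1, 2, ... dicentric chromosomes.
#'
#' @param cells_by_count integer vector; element `k + 1` is the number of
#'   cells carrying exactly `k` dicentrics (so the vector starts at zero
#'   dicentrics). Trailing zero classes are kept as given.
#' @param dose irradiation dose in Gy, or `NA` for a blind sample.
#'
#' @return An object of class `dicentric_dist`: a list with elements
#'   `counts` (cells per dicentric class, starting at 0), `n_cells` (total
#'   cells scored, `N`), `dicentrics` (total dicentrics, `X`) and `dose`.
#' @examples
#' d <- dicentric_dist(c(155, 38, 6, 1), dose = 3.41)
#' d$n_cells     # 200
#' d$dicentrics  # 38 + 12 + 3 = 53
#' @export
dicentric_dist <- function(cells_by_count, dose = NA_real_) {
  if (length(cells_by_count) < 1L || anyNA(cells_by_count))
    stop("'cells_by_count' must be a non-empty vector without NA", call. = FALSE)
  if (any(cells_by_count < 0))
    stop("cell counts must be non-negative", call. = FALSE)
  if (any(abs(cells_by_count - round(cells_by_count)) > 1e-8))
    stop("cell counts must be whole numbers", call. = FALSE)
  cells_by_count <- as.numeric(round(cells_by_count))
  n <- sum(cells_by_count)
  if (n < 1)
    stop("distribution must contain at least one cell", call. = FALSE)
  if (!is.na(dose) && dose < 0)
    stop("'dose' must be non-negative", call. = FALSE)
  k <- seq_along(cells_by_count) - 1
  structure(
    list(
      counts = stats::setNames(cells_by_count, k),
      n_cells = n,
      dicentrics = sum(k * cells_by_count),
      dose = as.numeric(dose)
    ),
    class = "dicentric_dist"
  )
}

#' Tabulate per-cell dicentric counts into a distribution
#'
#' @param per_cell integer vector, one entry per scored cell giving that
#'   cell's dicentric count.
#' @param dose dose in Gy or `NA`.
#' @return A [dicentric_dist()] object.
#' @export
tabulate_cells <- function(per_cell, dose = NA_real_) {
  if (length(per_cell) < 1L)
    stop("'per_cell' must contain at least one cell", call. = FALSE)
  if (any(per_cell < 0))
    stop("per-cell counts must be non-negative", call. = FALSE)
  kmax <- max(per_cell)
  dicentric_dist(tabulate(per_cell + 1L, nbins = kmax + 1L), dose = dose)
}

#' @export
print.dicentric_dist <- function(x, ...) {
  cat("Dicentric count distribution\n")
  if (!is.na(x$dose)) cat(sprintf("  dose: %g Gy\n", x$dose))
  cat(sprintf("  cells scored (N): %d, total dicentrics (X): %d, yield: %.4f\n",
              as.integer(x$n_cells), as.integer(x$dicentrics),
              x$dicentrics / x$n_cells))
  print(x$counts)
  invisible(x)
}

#' @export
as.data.frame.dicentric_dist <- function(x, ...) {
  row <- as.list(x$counts)
  names(row) <- paste0("c", names(x$counts))
  data.frame(dose = x$dose, n_cells = x$n_cells, row, check.names = FALSE)
}

# expand a distribution back to per-cell counts (used by dispersion stats)
cells_of <- function(dist) {
  k <- as.integer(names(dist$counts))
  rep(k, times = dist$counts)
}

as_dist_list <- function(data) {
  # accept a single dicentric_dist, a list of them, or a data.frame with
  # columns dose, n_cells, c0, c1, ...
  if (inherits(data, "dicentric_dist")) return(list(data))
  if (is.data.frame(data)) {
    ccols <- grep("^c[0-9]+$", names(data), value = TRUE)
    if (length(ccols) == 0L)
      stop("data.frame input needs count columns c0, c1, ...", call. = FALSE)
    ccols <- ccols[order(as.integer(sub("^c", "", ccols)))]
    return(lapply(seq_len(nrow(data)), function(i) {
      dose <- if ("dose" %in% names(data)) data$dose[i] else NA_real_
      d <- dicentric_dist(as.numeric(data[i, ccols]), dose = dose)
      if ("n_cells" %in% names(data) && !is.na(data$n_cells[i]) &&
          d$n_cells != data$n_cells[i])
        stop(sprintf("row %d: counts sum to %d but n_cells is %d",
                     i, as.integer(d$n_cells), as.integer(data$n_cells[i])),
             call. = FALSE)
      d
    }))
  }
  if (is.list(data) && all(vapply(data, inherits, logical(1), "dicentric_dist")))
    return(data)
  stop("expected a dicentric_dist, a list of them, or a count data.frame",
       call. = FALSE)
}
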