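# shared fixtures: all data are generated in code at test time

# a representative manual-scoring curve used across tests
true_theta <- c(C = 0.001, alpha = 0.03, beta = 0.05)

# the generator's default manual calibration design
default_design <- function() {
  doses <- c(0, 0.1, 0.25, 0.5, 1, 2, 3, 4, 5)
  list(doses = doses,
       cells = round(exp(seq(log(5000), log(500), length.out = length(doses)))))
}

# exact (noise-free) calibration totals lying on a curve, for
# identifiability checks: huge N makes rounding negligible
noiseless_calibration <- function(theta = true_theta,
                                  doses = c(0, 0.5, 1, 2, 3, 4, 5),
                                  n_cells = 1e6) {
  y <- theta[[1]] + theta[[2]] * doses + theta[[3]] * doses^2
  data.frame(dose = doses, n_cells = n_cells,
             dicentrics = round(n_cells * y))
}

simulate_calibration <- function(theta = true_theta,
                                 doses = seq(0, 5, length.out = 8),
                                 cells = 2000, dispersion = 1) {
  cells <- rep_len(cells, length(doses))
  mapply(function(D, N)
    simulate_distribution(theta, D, N, dispersion = dispersion),
    doses, cells, SIMPLIFY = FALSE)
}

# a fitted curve with non-trivial covariance, deterministic given seed
fitted_test_curve <- function(seed = 42, cells = 2000) {
  set.seed(seed)
  fit_lq_curve(simulate_calibration(cells = cells))
}

# direct "spreadsheet" evaluation of dispersion and u from a count spectrum,
# written independently of the package's per-cell route
direct_dispersion_u <- function(counts) {
  k <- seq_along(counts) - 1
  N <- sum(counts)
  X <- sum(k * counts)
  mu <- X / N
  s2 <- (sum(k^2 * counts) - N * mu^2) / (N - 1)
  delta <- s2 / mu
  u <- (delta - 1) * sqrt((N - 1) / (2 * (1 - 1 / X)))
  list(delta = delta, u = u)
}
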