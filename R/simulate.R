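#' Simulate a scored dicentric count distribution
#'
#' Draws per-cell dicentric counts with mean yield
#' `y(D) = C + alpha*D + beta*D^2`. Under `dispersion = 1` cells are Poisson
#' (the homogeneous whole-body exposure model); `dispersion > 1` uses a
#' gamma-mixed Poisson (per-cell negative binomial) whose variance-to-mean
#' ratio equals `dispersion`, emulating the overdispersion typical of
#' semi-automatic scoring.
#'
#' @param curve_params either an [lq_curve()] or a numeric vector
#'   `(C, alpha, beta)`.
#' @param dose dose in Gy (>= 0).
#' @param n_cells number of cells to score (>= 1).
#' @param dispersion target variance-to-mean ratio, >= 1.
#' @return A [dicentric_dist()] whose spectrum sums to `n_cells`. Uses the
#'   session RNG; seed it for reproducibility.
#' @examples
#' set.seed(1)
#' simulate_distribution(c(0.001, 0.02, 0.06), dose = 3, n_cells = 200)
#' @export
simulate_distribution <- function(curve_params, dose, n_cells,
                                  dispersion = 1) {
  th <- if (inherits(curve_params, "lq_curve")) curve_params$coefficients
        else curve_params
  if (length(th) != 3L || anyNA(th) || any(th < 0))
    stop("'curve_params' must be three non-negative values (C, alpha, beta)",
         call. = FALSE)
  if (!is.numeric(dose) || length(dose) != 1L || dose < 0)
    stop("'dose' must be a single non-negative value", call. = FALSE)
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1)
    stop("'n_cells' must be at least 1", call. = FALSE)
  if (dispersion < 1)
    stop("'dispersion' must be >= 1 (1 = Poisson)", call. = FALSE)
  n_cells <- as.integer(round(n_cells))
  y <- th[[1]] + th[[2]] * dose + th[[3]] * dose^2
  cells <- if (y == 0) {
    integer(n_cells)
  } else if (dispersion == 1) {
    stats::rpois(n_cells, y)
  } else {
    # NB with mu = y, size = y/(d-1): variance = y + y^2/size = y*d
    stats::rnbinom(n_cells, size = y / (dispersion - 1), mu = y)
  }
  tabulate_cells(cells, dose = dose)
}

#' Configuration of a synthetic interlaboratory comparison
#'
#' Defines the study conditions a simulated ILC emulates: the blinded
#' reference doses (stated in air kerma, with per-dose conversion factors to
#' absorbed dose to blood), the number of laboratories, the heterogeneity of
#' their linear-quadratic calibration curves, the split between manual and
#' semi-automatic scoring, cell numbers and the scoring dispersion of
#' semi-automatic systems.
#'
#' Defaults mirror a high-dose cobalt-60 exercise: three blind samples at
#' 2.56, 3.41 and 4.54 Gy air kerma (2.71, 3.60 and 4.80 Gy to blood), 14
#' laboratories, manual curve coefficients drawn from alpha in
#' \[0.01, 0.069\] / Gy and beta in \[0.031, 0.097\] / Gy^2, 200 cells per
#' manual blind sample and 3500 per semi-automatic one, and mild
#' semi-automatic overdispersion (variance/mean 1.05-1.15).
#'
#' @param n_labs number of participating laboratories.
#' @param blind_doses_air_kerma blind-sample doses, air kerma free in air (Gy).
#' @param kerma_to_blood_factor per-sample ratio dose-to-blood / air kerma.
#' @param alpha_range,beta_range,background_range closed intervals the manual
#'   curve coefficients are drawn from (uniformly).
#' @param fraction_semi_automatic probability a lab scores semi-automatically.
#' @param semi_auto_alpha_range,semi_auto_beta_range coefficient intervals for
#'   semi-automatic curves.
#' @param semi_auto_dispersion_range interval (lower bound >= 1) the
#'   variance-to-mean ratio of semi-automatic scoring is drawn from; manual
#'   scoring is Poisson (dispersion 1).
#' @param cells_manual,cells_semi_automatic cells scored per blind sample.
#' @param calibration_doses calibration design doses (Gy), strictly increasing.
#' @param calibration_cells cells per calibration dose (recycled); default is
#'   a log-spaced ramp from 5000 cells at the lowest dose down to 500 at the
#'   highest, reflecting that high-dose points need fewer cells.
#' @param dose_definition_prob named probabilities over
#'   `c(air_kerma, dose_to_water, dose_to_blood)` for the definition each
#'   lab's curve is calibrated in.
#' @param bias_factors multiplicative laboratory bias on the true dose being
#'   scored (1 = unbiased); scalar or one per lab.
#' @param seed integer seed driving the whole simulation.
#' @return A list of class `ilc_config`.
#' @export
ilc_config <- function(n_labs = 14,
                       blind_doses_air_kerma = c(2.56, 3.41, 4.54),
                       kerma_to_blood_factor =
                         c(2.71, 3.60, 4.80) / c(2.56, 3.41, 4.54),
                       alpha_range = c(0.01, 0.069),
                       beta_range = c(0.031, 0.097),
                       background_range = c(5e-4, 2e-3),
                       fraction_semi_automatic = 0.3,
                       semi_auto_alpha_range = c(0.003, 0.026),
                       semi_auto_beta_range = c(0.003, 0.026),
                       semi_auto_dispersion_range = c(1.05, 1.15),
                       cells_manual = 200,
                       cells_semi_automatic = 3500,
                       calibration_doses = c(0, 0.1, 0.25, 0.5, 1, 2, 3, 4, 5),
                       calibration_cells = NULL,
                       dose_definition_prob = c(air_kerma = 9 / 14,
                                                dose_to_water = 5 / 14,
                                                dose_to_blood = 0),
                       bias_factors = 1,
                       seed = 1L) {
  if (n_labs < 1) stop("'n_labs' must be positive", call. = FALSE)
  if (length(blind_doses_air_kerma) == 0 || any(blind_doses_air_kerma <= 0))
    stop("'blind_doses_air_kerma' must be non-empty and positive",
         call. = FALSE)
  kerma_to_blood_factor <- rep_len(kerma_to_blood_factor,
                                   length(blind_doses_air_kerma))
  if (any(kerma_to_blood_factor <= 0))
    stop("'kerma_to_blood_factor' must be positive", call. = FALSE)
  for (rg in list(alpha_range, beta_range, background_range,
                  semi_auto_alpha_range, semi_auto_beta_range)) {
    if (length(rg) != 2L || rg[1] > rg[2] || any(rg < 0))
      stop("coefficient ranges must be [lower, upper] with ",
           "0 <= lower <= upper", call. = FALSE)
  }
  if (length(semi_auto_dispersion_range) != 2L ||
      semi_auto_dispersion_range[1] < 1 ||
      semi_auto_dispersion_range[1] > semi_auto_dispersion_range[2])
    stop("'semi_auto_dispersion_range' must be an interval with lower ",
         "bound >= 1", call. = FALSE)
  if (fraction_semi_automatic < 0 || fraction_semi_automatic > 1)
    stop("'fraction_semi_automatic' must lie in [0, 1]", call. = FALSE)
  if (is.unsorted(calibration_doses, strictly = TRUE) ||
      any(calibration_doses < 0))
    stop("'calibration_doses' must be strictly increasing and non-negative",
         call. = FALSE)
  if (is.null(calibration_cells))
    calibration_cells <- round(exp(seq(log(5000), log(500),
                                       length.out = length(calibration_doses))))
  calibration_cells <- rep_len(calibration_cells, length(calibration_doses))
  if (any(calibration_cells < 1))
    stop("'calibration_cells' must be positive", call. = FALSE)
  bias_factors <- rep_len(bias_factors, n_labs)
  if (any(bias_factors <= 0))
    stop("'bias_factors' must be positive (1 = unbiased)", call. = FALSE)
  defs <- c("air_kerma", "dose_to_water", "dose_to_blood")
  if (!all(names(dose_definition_prob) %in% defs) ||
      any(dose_definition_prob < 0) || sum(dose_definition_prob) <= 0)
    stop("'dose_definition_prob' must be non-negative probabilities over ",
         paste(defs, collapse = ", "), call. = FALSE)
  structure(
    list(n_labs = as.integer(n_labs),
         blind_doses_air_kerma = blind_doses_air_kerma,
         kerma_to_blood_factor = kerma_to_blood_factor,
         alpha_range = alpha_range, beta_range = beta_range,
         background_range = background_range,
         fraction_semi_automatic = fraction_semi_automatic,
         semi_auto_alpha_range = semi_auto_alpha_range,
         semi_auto_beta_range = semi_auto_beta_range,
         semi_auto_dispersion_range = semi_auto_dispersion_range,
         cells_manual = cells_manual,
         cells_semi_automatic = cells_semi_automatic,
         calibration_doses = calibration_doses,
         calibration_cells = calibration_cells,
         dose_definition_prob = dose_definition_prob,
         bias_factors = bias_factors,
         seed = as.integer(seed)),
    class = "ilc_config")
}

runif_range <- function(rg) if (rg[1] == rg[2]) rg[1] else stats::runif(1, rg[1], rg[2])

#' Draw one laboratory profile
#'
#' Samples a laboratory's true calibration curve, scoring mode, dispersion
#' and dose definition from the ranges in an [ilc_config()]. Uses the session
#' RNG.
#'
#' @param config an [ilc_config()].
#' @param lab_id identifier, e.g. `"L3"`.
#' @param bias_factor multiplicative dose bias of this lab (1 = unbiased).
#' @return A list of class `lab_profile` with the lab's true coefficients,
#'   `scoring_mode`, `dispersion`, `dose_definition`, cell numbers and
#'   calibration design.
#' @export
sample_lab_profile <- function(config, lab_id = "L1", bias_factor = 1) {
  stopifnot(inherits(config, "ilc_config"))
  semi <- stats::runif(1) < config$fraction_semi_automatic
  if (semi) {
    alpha <- runif_range(config$semi_auto_alpha_range)
    beta <- runif_range(config$semi_auto_beta_range)
  } else {
    alpha <- runif_range(config$alpha_range)
    beta <- runif_range(config$beta_range)
  }
  background <- runif_range(config$background_range)
  dispersion <- if (semi) runif_range(config$semi_auto_dispersion_range) else 1
  p <- config$dose_definition_prob
  dose_definition <- sample(names(p), 1L, prob = p)
  structure(
    list(lab_id = lab_id, alpha = alpha, beta = beta, background = background,
         dose_definition = dose_definition,
         scoring_mode = if (semi) "semi_automatic" else "manual",
         cells_per_blind_sample = if (semi) config$cells_semi_automatic
                                  else config$cells_manual,
         calibration_doses = config$calibration_doses,
         calibration_cells = config$calibration_cells,
         dispersion = dispersion, bias_factor = bias_factor),
    class = "lab_profile")
}

#' @export
print.lab_profile <- function(x, ...) {
  cat(sprintf(
    "Lab %s: %s scoring in %s\n  true curve C=%.4g alpha=%.4g beta=%.4g, dispersion %.3g, bias %.3g\n",
    x$lab_id, x$scoring_mode, gsub("_", " ", x$dose_definition),
    x$background, x$alpha, x$beta, x$dispersion, x$bias_factor))
  invisible(x)
}

#' Simulate a full blinded interlaboratory comparison
#'
#' For each laboratory, draws a profile, generates calibration count
#' distributions at its calibration doses from its true curve, and scores
#' each blind sample at the blind dose expressed in the lab's own dose
#' definition, multiplied by the lab's bias factor. Laboratory sub-streams
#' are seeded deterministically from `config$seed`, so a lab's data do not
#' depend on the ordering of labs.
#'
#' @param config an [ilc_config()].
#' @return A list of class `ilc_simulation`:
#'   * `labs`: list of [sample_lab_profile()] results;
#'   * `calibration`: per lab, a list of [dicentric_dist()] at the
#'     calibration doses;
#'   * `blind`: per lab, a list of [dicentric_dist()] per blind sample
#'     (doses stripped — the payload is blinded);
#'   * `truth`: ground truth — a data.frame of reference doses
#'     (`sample_id`, `air_kerma`, `dose_to_blood`) plus the per-lab true
#'     curves and bias factors (`lab_truth`).
#' @examples
#' sim <- simulate_ilc(ilc_config(n_labs = 3, seed = 42))
#' length(sim$blind[["L2"]])  # one distribution per blind sample
#' @export
simulate_ilc <- function(config) {
  stopifnot(inherits(config, "ilc_config"))
  set.seed(config$seed)
  lab_seeds <- sample.int(.Machine$integer.max - 1L, config$n_labs)
  lab_ids <- paste0("L", seq_len(config$n_labs))
  n_samples <- length(config$blind_doses_air_kerma)
  sample_ids <- paste0("S", seq_len(n_samples))

  labs <- calibration <- blind <- vector("list", config$n_labs)
  names(labs) <- names(calibration) <- names(blind) <- lab_ids

  for (i in seq_len(config$n_labs)) {
    set.seed(lab_seeds[i])
    prof <- sample_lab_profile(config, lab_ids[i], config$bias_factors[i])
    th <- c(prof$background, prof$alpha, prof$beta)
    calibration[[i]] <- mapply(function(D, N)
      simulate_distribution(th, D, N, dispersion = prof$dispersion),
      prof$calibration_doses, prof$calibration_cells, SIMPLIFY = FALSE)
    blind[[i]] <- lapply(seq_len(n_samples), function(s) {
      f <- if (prof$dose_definition == "air_kerma") 1
           else config$kerma_to_blood_factor[s]
      true_dose <- config$blind_doses_air_kerma[s] * f * prof$bias_factor
      d <- simulate_distribution(th, true_dose,
                                 prof$cells_per_blind_sample,
                                 dispersion = prof$dispersion)
      d$dose <- NA_real_  # blinded
      d
    })
    names(blind[[i]]) <- sample_ids
    labs[[i]] <- prof
  }

  truth <- data.frame(
    sample_id = sample_ids,
    air_kerma = config$blind_doses_air_kerma,
    dose_to_blood = config$blind_doses_air_kerma * config$kerma_to_blood_factor)
  lab_truth <- data.frame(
    lab_id = lab_ids,
    background = vapply(labs, `[[`, numeric(1), "background"),
    alpha = vapply(labs, `[[`, numeric(1), "alpha"),
    beta = vapply(labs, `[[`, numeric(1), "beta"),
    dispersion = vapply(labs, `[[`, numeric(1), "dispersion"),
    bias_factor = vapply(labs, `[[`, numeric(1), "bias_factor"),
    dose_definition = vapply(labs, `[[`, character(1), "dose_definition"),
    scoring_mode = vapply(labs, `[[`, character(1), "scoring_mode"),
    row.names = NULL)

  structure(list(labs = labs, calibration = calibration, blind = blind,
                 truth = list(references = truth, lab_truth = lab_truth),
                 config = config),
            class = "ilc_simulation")
}

#' @export
print.ilc_simulation <- function(x, ...) {
  cat(sprintf(
    "Simulated ILC: %d labs, %d blind samples (air kerma %s Gy), seed %d\n",
    x$config$n_labs, length(x$config$blind_doses_air_kerma),
    paste(x$config$blind_doses_air_kerma, collapse = " / "), x$config$seed))
  modes <- table(x$truth$lab_truth$scoring_mode)
  cat("  scoring modes:", paste(names(modes), modes, collapse = ", "), "\n")
  invisible(x)
}

#' Run the full analysis chain on a simulated ILC
#'
#' Fits each laboratory's calibration curve from its simulated calibration
#' data, estimates the dose of every blind sample on the lab's own dose
#' scale, and assembles the submission table an ILC organiser would receive.
#'
#' @param sim an [simulate_ilc()] result.
#' @param method confidence-interval method passed to [estimate_dose()].
#' @param conf.level confidence level of the reported intervals.
#' @return A list with `curves` (per-lab fitted [lq_curve()]s), `submissions`
#'   (a data.frame with one row per lab and blind sample: `lab_id`,
#'   `sample_id`, `scoring_mode`, `method`, `dose`, `ci_low`, `ci_high`,
#'   `dose_definition`, `extrapolated`, `n_cells`, `n_dicentrics`) and
#'   `references` (the ground-truth reference doses).
#' @export
run_ilc <- function(sim, method = c("curve_plus_yield", "yield_only"),
                    conf.level = 0.95) {
  stopifnot(inherits(sim, "ilc_simulation"))
  method <- match.arg(method)
  lab_ids <- names(sim$labs)
  curves <- lapply(lab_ids, function(l)
    fit_lq_curve(sim$calibration[[l]],
                 dose_definition = sim$labs[[l]]$dose_definition,
                 scoring_mode = sim$labs[[l]]$scoring_mode))
  names(curves) <- lab_ids
  rows <- lapply(lab_ids, function(l) {
    do.call(rbind, lapply(names(sim$blind[[l]]), function(s) {
      est <- estimate_dose(curves[[l]], sim$blind[[l]][[s]], method = method,
                           conf.level = conf.level)
      data.frame(lab_id = l, sample_id = s,
                 scoring_mode = sim$labs[[l]]$scoring_mode,
                 method = est$method, dose = est$dose,
                 ci_low = est$ci_low, ci_high = est$ci_high,
                 dose_definition = est$dose_definition,
                 extrapolated = est$extrapolated,
                 n_cells = est$n_cells, n_dicentrics = est$n_dicentrics)
    }))
  })
  list(curves = curves, submissions = do.call(rbind, rows),
       references = sim$truth$references)
}
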