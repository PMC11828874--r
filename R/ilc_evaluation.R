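#' Pick the reference dose a submission is judged against
#'
#' @param reference one row of a reference table: list or data.frame row with
#'   `air_kerma` and `dose_to_blood` (Gy).
#' @param dose_definition the dose definition of the submission's estimate.
#' @param mode `"air_kerma"` or `"dose_to_blood"` compare every lab to that
#'   coordinate; `"matching"` compares each lab to the coordinate matching
#'   its own dose definition (air-kerma curves to air kerma; dose-to-water
#'   and dose-to-blood curves to dose to blood, the in-medium coordinate).
#' @return reference dose in Gy.
#' @export
select_reference <- function(reference, dose_definition,
                             mode = c("matching", "air_kerma",
                                      "dose_to_blood")) {
  mode <- match.arg(mode)
  if (mode == "air_kerma") return(reference$air_kerma)
  if (mode == "dose_to_blood") return(reference$dose_to_blood)
  ifelse(dose_definition == "air_kerma",
         reference$air_kerma, reference$dose_to_blood)
}

#' Proficiency Z-score
#'
#' `z = (estimate - reference) / sigma_p`. Conventional flags: questionable
#' when `|z| > 1.96`, unsatisfactory when `|z| > 3`.
#'
#' @param estimate,reference doses in Gy.
#' @param sigma_p proficiency standard deviation (Gy, > 0); see
#'   [proficiency_sigma()].
#' @return the Z-score(s).
#' @examples
#' z_score(3.0, 2.56, 0.22)  # 2: questionable
#' @export
z_score <- function(estimate, reference, sigma_p) {
  if (any(sigma_p <= 0))
    stop("'sigma_p' must be positive; a zero spread (e.g. identical ",
         "estimates under the robust rule) leaves the Z-score undefined",
         call. = FALSE)
  (estimate - reference) / sigma_p
}

#' Proficiency standard deviation for Z-scores
#'
#' Three interchangeable rules for the denominator of the Z-score:
#' * `"robust"`: 1.4826 x the median absolute deviation of the participants'
#'   estimates for the sample (needs >= 3 submissions);
#' * `"ci"`: per lab, the half-width of its reported 95% CI divided by 1.96
#'   (returns one value per submission);
#' * `"fixed"`: `fixed_fraction` x the reference dose.
#'
#' @param estimates participants' dose estimates for one sample (Gy).
#' @param rule which rule.
#' @param ci_low,ci_high the labs' reported interval bounds (rule `"ci"`).
#' @param reference reference dose (rule `"fixed"`).
#' @param fixed_fraction fraction of the reference used by rule `"fixed"`.
#' @return a single sigma (rules `"robust"`, `"fixed"`) or one per lab
#'   (rule `"ci"`).
#' @examples
#' proficiency_sigma(c(2.0, 2.5, 3.0))  # 1.4826 * MAD = 0.7413
#' @export
proficiency_sigma <- function(estimates, rule = c("robust", "ci", "fixed"),
                              ci_low = NULL, ci_high = NULL,
                              reference = NULL, fixed_fraction = 0.1) {
  rule <- match.arg(rule)
  switch(rule,
    robust = {
      if (length(estimates) < 3)
        stop("robust sigma rule needs at least 3 submissions", call. = FALSE)
      stats::mad(estimates)  # 1.4826 * median absolute deviation
    },
    ci = {
      if (is.null(ci_low) || is.null(ci_high))
        stop("ci rule needs 'ci_low' and 'ci_high'", call. = FALSE)
      (ci_high - ci_low) / (2 * stats::qnorm(0.975))
    },
    fixed = {
      if (is.null(reference))
        stop("fixed rule needs 'reference'", call. = FALSE)
      fixed_fraction * reference
    })
}

#' Classify laboratory-specific systematic bias
#'
#' A laboratory shows systematic over-/underestimation when (1) it
#' consistently over-/underestimated every blind sample and (2) at least two
#' of its 95% confidence intervals exclude the reference dose.
#'
#' @param deviations per-sample `estimate - reference` (Gy) for one lab, in
#'   sample order; `NA` for samples the lab did not submit.
#' @param ci_excludes logical per sample: does the lab's CI exclude the
#'   reference?
#' @param n_samples number of blind samples the lab was expected to submit.
#' @return `"systematic_over"`, `"systematic_under"`, `"none"`, or
#'   `"not_classifiable"` when submissions are missing.
#' @export
classify_bias <- function(deviations, ci_excludes,
                          n_samples = length(deviations)) {
  if (length(deviations) != length(ci_excludes))
    stop("'deviations' and 'ci_excludes' must have equal length",
         call. = FALSE)
  if (length(deviations) < n_samples || anyNA(deviations) ||
      anyNA(ci_excludes))
    return("not_classifiable")
  if (all(deviations > 0) && sum(ci_excludes) >= 2) return("systematic_over")
  if (all(deviations < 0) && sum(ci_excludes) >= 2) return("systematic_under")
  "none"
}

#' Clinical triage category of a dose estimate
#'
#' Whole-body triage bands: `"low"` below 1 Gy, `"medium"` for 1-2 Gy
#' (closed interval), `"high"` above 2 Gy.
#'
#' @param dose dose(s) in Gy, non-negative.
#' @return character vector of categories.
#' @export
triage_category <- function(dose) {
  if (any(dose < 0)) stop("'dose' must be non-negative", call. = FALSE)
  ifelse(dose < 1, "low", ifelse(dose <= 2, "medium", "high"))
}

#' Is an estimate within a band of the reference dose?
#'
#' @param estimate,reference doses in Gy.
#' @param band half-width of the acceptance band in Gy (> 0); the comparison
#'   is closed (`<=`).
#' @export
within_band <- function(estimate, reference, band = 1.0) {
  if (band <= 0) stop("'band' must be positive", call. = FALSE)
  abs(estimate - reference) <= band
}

#' Did a laboratory rank the blind samples correctly?
#'
#' `TRUE` iff the lab's estimates, ordered by sample, are strictly ordered
#' the same way as the reference doses; ties in the estimates count as a
#' failed ranking.
#'
#' @param estimates the lab's estimates, in sample order.
#' @param references the reference doses, in the same sample order.
#' @export
ranking_correct <- function(estimates, references) {
  if (length(estimates) != length(references))
    stop("'estimates' and 'references' must cover the same samples",
         call. = FALSE)
  if (anyNA(estimates) || anyNA(references)) return(NA)
  if (anyDuplicated(estimates)) return(FALSE)
  identical(order(estimates), order(references))
}

#' Correlation between labs' estimates of two blind samples
#'
#' Pearson correlation (with a two-sided test) over the laboratories that
#' submitted estimates for both samples. A strong positive correlation means
#' labs that run high on one sample run high on the other — a
#' laboratory-level effect rather than sampling noise.
#'
#' @param estimates_a,estimates_b named numeric vectors (names = lab ids) of
#'   estimates for the two samples.
#' @return list with `r`, `p_value` and `n` (paired labs, >= 3 required).
#' @export
estimate_correlation <- function(estimates_a, estimates_b) {
  labs <- intersect(names(estimates_a), names(estimates_b))
  labs <- labs[!is.na(estimates_a[labs]) & !is.na(estimates_b[labs])]
  if (length(labs) < 3)
    stop("correlation needs at least 3 labs present in both samples",
         call. = FALSE)
  a <- estimates_a[labs]; b <- estimates_b[labs]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    r <- if (isTRUE(all.equal(a - mean(a), b - mean(b)))) 1 else NA_real_
    return(list(r = r, p_value = NA_real_, n = length(labs)))
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(labs))
}

#' Score an interlaboratory comparison
#'
#' Computes, for each requested reference mode, the per-lab-per-sample
#' metrics (reference used, deviation, CI coverage of the reference,
#' Z-score and flag, triage category, band check), the per-lab systematic
#' bias class and ranking check, the per-sample CI-coverage fractions, and
#' the between-sample correlations of the labs' estimates.
#'
#' @param submissions data.frame with one row per lab and sample: `lab_id`,
#'   `sample_id`, `dose`, `ci_low`, `ci_high`, `dose_definition`; optional
#'   `scoring_mode`, `n_cells`, `n_dicentrics`.
#' @param references data.frame with `sample_id`, `air_kerma`,
#'   `dose_to_blood` (Gy).
#' @param mode reference mode(s) to evaluate, see [select_reference()].
#' @param sigma_rule Z-score denominator rule, see [proficiency_sigma()].
#' @param fixed_fraction fraction for `sigma_rule = "fixed"`.
#' @param questionable,unsatisfactory `|z|` thresholds.
#' @param band acceptance band half-width (Gy).
#' @return An object of class `ilc_report`: list with `per_sample`
#'   (data.frame of per-lab-per-sample rows across modes), `per_lab`
#'   (bias class and ranking per mode), `fractions` (per sample and mode:
#'   share of labs whose CI contains the reference, share questionable),
#'   `correlations` (per sample pair) and `config`.
#' @export
evaluate_ilc <- function(submissions, references,
                         mode = c("matching", "air_kerma", "dose_to_blood"),
                         sigma_rule = c("robust", "ci", "fixed"),
                         fixed_fraction = 0.1,
                         questionable = 1.96, unsatisfactory = 3,
                         band = 1.0) {
  sigma_rule <- match.arg(sigma_rule)
  mode <- match.arg(mode, several.ok = TRUE)
  needed <- c("lab_id", "sample_id", "dose", "ci_low", "ci_high",
              "dose_definition")
  if (!all(needed %in% names(submissions)))
    stop("submissions must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (nrow(submissions) == 0) stop("no submissions", call. = FALSE)
  if (any(submissions$ci_low > submissions$dose |
          submissions$dose > submissions$ci_high))
    stop("each submission must satisfy ci_low <= dose <= ci_high",
         call. = FALSE)
  if (!all(submissions$sample_id %in% references$sample_id))
    stop("submissions refer to samples missing from the reference table",
         call. = FALSE)

  sample_ids <- references$sample_id
  per_sample <- do.call(rbind, lapply(mode, function(m) {
    df <- submissions
    ref_row <- references[match(df$sample_id, references$sample_id), ]
    df$reference <- select_reference(ref_row, df$dose_definition, m)
    df$deviation <- df$dose - df$reference
    df$ci_contains_reference <- df$ci_low <= df$reference &
      df$reference <= df$ci_high
    # Z-score denominator per sample (robust/fixed) or per lab (ci)
    df$sigma_p <- NA_real_
    for (s in sample_ids) {
      i <- df$sample_id == s
      if (!any(i)) next
      df$sigma_p[i] <- switch(sigma_rule,
        robust = proficiency_sigma(df$dose[i], "robust"),
        ci = proficiency_sigma(df$dose[i], "ci", ci_low = df$ci_low[i],
                               ci_high = df$ci_high[i]),
        fixed = proficiency_sigma(df$dose[i], "fixed",
                                  reference = df$reference[i],
                                  fixed_fraction = fixed_fraction))
    }
    df$z <- z_score(df$dose, df$reference, df$sigma_p)
    df$z_flag <- ifelse(abs(df$z) > unsatisfactory, "unsatisfactory",
                        ifelse(abs(df$z) > questionable, "questionable",
                               "satisfactory"))
    df$triage <- triage_category(df$dose)
    df$within_band <- within_band(df$dose, df$reference, band)
    df$reference_mode <- m
    df
  }))

  lab_ids <- unique(submissions$lab_id)
  per_lab <- do.call(rbind, lapply(mode, function(m) {
    rows <- per_sample[per_sample$reference_mode == m, ]
    do.call(rbind, lapply(lab_ids, function(l) {
      li <- rows[rows$lab_id == l, ]
      li <- li[match(sample_ids, li$sample_id), ]
      data.frame(
        lab_id = l, reference_mode = m,
        bias_class = classify_bias(li$deviation, !li$ci_contains_reference,
                                   n_samples = length(sample_ids)),
        ranking_correct = ranking_correct(li$dose, li$reference),
        n_questionable = sum(li$z_flag != "satisfactory", na.rm = TRUE))
    }))
  }))

  fractions <- do.call(rbind, lapply(mode, function(m) {
    rows <- per_sample[per_sample$reference_mode == m, ]
    do.call(rbind, lapply(sample_ids, function(s) {
      si <- rows[rows$sample_id == s, ]
      data.frame(sample_id = s, reference_mode = m, n_labs = nrow(si),
                 frac_ci_contains_reference =
                   mean(si$ci_contains_reference),
                 frac_questionable = mean(si$z_flag != "satisfactory"),
                 frac_within_band = mean(si$within_band),
                 mean_deviation = mean(si$deviation))
    }))
  }))

  correlations <- NULL
  if (length(sample_ids) >= 2) {
    est_by_sample <- lapply(sample_ids, function(s) {
      si <- submissions[submissions$sample_id == s, ]
      stats::setNames(si$dose, si$lab_id)
    })
    names(est_by_sample) <- sample_ids
    pairs <- utils::combn(sample_ids, 2, simplify = FALSE)
    correlations <- do.call(rbind, lapply(pairs, function(p) {
      ec <- tryCatch(estimate_correlation(est_by_sample[[p[1]]],
                                          est_by_sample[[p[2]]]),
                     error = function(e) list(r = NA_real_,
                                              p_value = NA_real_, n = NA))
      data.frame(sample_a = p[1], sample_b = p[2], r = ec$r,
                 p_value = ec$p_value, n = ec$n)
    }))
  }

  structure(
    list(per_sample = per_sample, per_lab = per_lab, fractions = fractions,
         correlations = correlations,
         config = list(mode = mode, sigma_rule = sigma_rule,
                       fixed_fraction = fixed_fraction,
                       questionable = questionable,
                       unsatisfactory = unsatisfactory, band = band)),
    class = "ilc_report")
}

#' @export
print.ilc_report <- function(x, digits = 3, ...) {
  cat(sprintf(
    "ILC evaluation: %d labs, %d blind samples; sigma rule '%s', modes: %s\n\n",
    length(unique(x$per_sample$lab_id)),
    length(unique(x$per_sample$sample_id)),
    x$config$sigma_rule, paste(x$config$mode, collapse = ", ")))
  cat("Per-sample summary:\n")
  fr <- x$fractions
  fr[] <- lapply(fr, function(col) if (is.numeric(col)) round(col, digits)
                 else col)
  print(fr, row.names = FALSE)
  biased <- x$per_lab[x$per_lab$bias_class %in%
                        c("systematic_over", "systematic_under"), ]
  if (nrow(biased)) {
    cat("\nLabs flagged for systematic bias:\n")
    print(biased[, c("lab_id", "reference_mode", "bias_class")],
          row.names = FALSE)
  } else cat("\nNo lab flagged for systematic bias.\n")
  if (!is.null(x$correlations)) {
    cat("\nBetween-sample correlation of lab estimates:\n")
    cr <- x$correlations
    cr$r <- round(cr$r, digits); cr$p_value <- signif(cr$p_value, digits)
    print(cr, row.names = FALSE)
  }
  invisible(x)
}
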