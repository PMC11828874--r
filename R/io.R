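#' Read a dicentric count table
#'
#' Count tables are plain CSV in wide format: one row per scored sample with
#' columns `n_cells`, `c0, c1, ...` (cells with 0, 1, ... dicentrics) and
#' optionally `sample_id`, `lab_id` and `dose` (Gy, empty for blind
#' samples). Each row must satisfy `sum(c_k) == n_cells`; violations are
#' reported with their row number.
#'
#' @param path file path.
#' @return A list of [dicentric_dist()] objects; `sample_id`/`lab_id`
#'   columns, when present, are attached as attributes of each element.
#'   An empty file yields an empty list with a warning.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0) {
    warning("count table ", path, " is empty")
    return(list())
  }
  ccols <- grep("^c[0-9]+$", names(df), value = TRUE)
  if (length(ccols) == 0 || !"n_cells" %in% names(df))
    stop("count table needs columns n_cells and c0, c1, ...", call. = FALSE)
  ccols <- ccols[order(as.integer(sub("^c", "", ccols)))]
  lapply(seq_len(nrow(df)), function(i) {
    counts <- as.numeric(df[i, ccols])
    if (any(is.na(counts) | counts < 0))
      stop(sprintf("row %d: negative or missing cell counts", i),
           call. = FALSE)
    if (sum(counts) != df$n_cells[i])
      stop(sprintf("row %d: counts sum to %d but n_cells is %d", i,
                   as.integer(sum(counts)), as.integer(df$n_cells[i])),
           call. = FALSE)
    dose <- if ("dose" %in% names(df)) df$dose[i] else NA_real_
    d <- dicentric_dist(counts, dose = if (is.na(dose)) NA_real_ else dose)
    if ("sample_id" %in% names(df)) attr(d, "sample_id") <- df$sample_id[i]
    if ("lab_id" %in% names(df)) attr(d, "lab_id") <- df$lab_id[i]
    d
  })
}

#' Write a dicentric count table
#'
#' Inverse of [read_count_table()]; rows are right-padded with zero classes
#' to a common maximum dicentric count.
#'
#' @param dists a list of [dicentric_dist()] objects (possibly carrying
#'   `sample_id`/`lab_id` attributes).
#' @param path output CSV path.
#' @export
write_count_table <- function(dists, path) {
  dists <- as_dist_list(dists)
  kmax <- max(vapply(dists, function(d) length(d$counts), integer(1))) - 1L
  rows <- lapply(dists, function(d) {
    counts <- c(d$counts, rep(0, kmax + 1L - length(d$counts)))
    row <- data.frame(dose = d$dose, n_cells = d$n_cells,
                      as.list(counts), check.names = FALSE)
    names(row)[-(1:2)] <- paste0("c", 0:kmax)
    sid <- attr(d, "sample_id"); lid <- attr(d, "lab_id")
    if (!is.null(sid)) row <- cbind(sample_id = sid, row)
    if (!is.null(lid)) row <- cbind(lab_id = lid, row)
    row
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Write / read a calibration curve as JSON
#'
#' Curve files store the coefficients, the covariance in row-major order,
#' the dose definition, scoring mode, maximum calibration dose and fit
#' diagnostics; `read_curve(write_curve(x))` reproduces the curve.
#'
#' @param curve an [lq_curve()].
#' @param path file path.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "lq_curve"))
  obj <- list(
    coefficients = as.list(curve$coefficients),
    covariance_row_major = if (is.null(curve$cov)) NULL
                           else as.vector(t(curve$cov)),
    dose_definition = curve$dose_definition,
    scoring_mode = curve$scoring_mode,
    max_dose = curve$max_dose,
    n_dose_points = curve$n_dose_points,
    deviance = curve$deviance, df = curve$df)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cov <- if (is.null(obj$covariance_row_major)) NULL
         else matrix(obj$covariance_row_major, 3, 3, byrow = TRUE)
  cv <- lq_curve(obj$coefficients$C, obj$coefficients$alpha,
                 obj$coefficients$beta, cov = cov,
                 dose_definition = obj$dose_definition,
                 scoring_mode = obj$scoring_mode,
                 max_dose = obj$max_dose,
                 n_dose_points = if (is.null(obj$n_dose_points)) NA_integer_
                                 else obj$n_dose_points)
  if (!is.null(obj$deviance) && !is.na(obj$deviance)) {
    cv$deviance <- obj$deviance
    cv$df <- obj$df
  }
  cv
}

#' Write an ILC report to JSON or CSV
#'
#' JSON keeps the full report and round-trips through [read_report()]; CSV
#' flattens to the per-lab-per-sample rows.
#'
#' @param report an [evaluate_ilc()] result.
#' @param path output path.
#' @param format `"json"` or `"csv"`.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  stopifnot(inherits(report, "ilc_report"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(report$per_sample, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, null = "null", dataframe = "rows",
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$config$mode <- as.character(obj$config$mode)
  structure(obj, class = "ilc_report")
}

#' Write / read the reference-dose table as JSON
#'
#' @param references data.frame with `sample_id`, `air_kerma`,
#'   `dose_to_blood`.
#' @param path file path.
#' @export
write_references <- function(references, path) {
  jsonlite::write_json(references, path, auto_unbox = FALSE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_references
#' @export
read_references <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as.data.frame(obj)
}

#' Write a run manifest
#'
#' Records the inputs, resolved configuration (with an md5 of the config
#' file when one was used), seed and package version of a run, so results
#' stay attributable.
#'
#' @param path output JSON path.
#' @param inputs named list or character vector of input paths.
#' @param config resolved configuration (list).
#' @param config_file optional path of the config file actually read.
#' @param seed seed used.
#' @export
write_manifest <- function(path, inputs = list(), config = list(),
                           config_file = NULL, seed = NA_integer_) {
  manifest <- list(
    package = "biodoseilc",
    version = as.character(utils::packageVersion("biodoseilc")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    inputs = inputs,
    config = config,
    config_md5 = if (!is.null(config_file) && file.exists(config_file))
      unname(tools::md5sum(config_file)) else NULL)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
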