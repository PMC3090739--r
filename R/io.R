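# File interfaces: tab-delimited expression matrices (genes as rows,
# microarray convention), two-column label files, scenario config files,
# JSON reports with a TSV decomposition alongside.

REPORT_SCHEMA_VERSION <- "1.0"

#' Read an expression matrix plus class labels
#'
#' The matrix file is tab-delimited with a header row of sample
#' identifiers and a first column of gene identifiers; values are numeric
#' log-scale expression.  The label file has two tab-separated columns:
#' sample identifier and class label, with exactly two distinct labels
#' covering every sample in the matrix.  Class 1 is the lexicographically
#' smaller label unless `positive_class` names it explicitly.
#'
#' @param matrix_path Path to the expression matrix.
#' @param labels_path Path to the label file.
#' @param transpose If `TRUE` the matrix file stores samples as rows.
#' @param positive_class Optional label to treat as class 1.
#' @return An `"expression_dataset"` with samples ordered as in the matrix
#'   header.
#' @export
read_expression <- function(matrix_path, labels_path, transpose = FALSE,
                            positive_class = NULL) {
  raw <- utils::read.delim(matrix_path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L) stop("expression matrix must have gene ids plus at least one sample")
  gene_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifier in matrix header: ",
         sample_ids[duplicated(sample_ids)][1])
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifier in matrix: ", gene_ids[duplicated(gene_ids)][1])
  }
  mat <- matrix(NA_real_, nrow(raw), length(sample_ids),
                dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(v) & !is.na(raw[[j + 1L]]))
    if (length(bad) || anyNA(raw[[j + 1L]])) {
      row <- if (length(bad)) bad[1] else which(is.na(raw[[j + 1L]]))[1]
      stop(sprintf("non-numeric or missing value at gene '%s', sample '%s'",
                   gene_ids[row], sample_ids[j]))
    }
    mat[, j] <- v
  }
  if (transpose) mat <- t(mat)

  lab <- utils::read.delim(labels_path, header = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(lab) != 2L) stop("label file must have exactly two tab-separated columns")
  # tolerate a header line
  if (identical(tolower(lab[1, 1]), "sample") || identical(tolower(lab[1, 2]), "class")) {
    lab <- lab[-1L, , drop = FALSE]
  }
  if (anyDuplicated(lab[[1L]])) {
    stop("duplicate sample identifier in label file: ",
         lab[[1L]][duplicated(lab[[1L]])][1])
  }
  missing <- setdiff(colnames(mat), lab[[1L]])
  if (length(missing)) stop("no class label for sample '", missing[1], "'")
  cls <- lab[[2L]][match(colnames(mat), lab[[1L]])]
  ulev <- sort(unique(cls))
  if (length(ulev) != 2L) {
    stop("exactly two distinct class labels are required (found ", length(ulev), ")")
  }
  if (!is.null(positive_class)) {
    if (!positive_class %in% ulev) stop("'positive_class' not among the labels")
    ulev <- c(positive_class, setdiff(ulev, positive_class))
  }
  expression_dataset(mat, factor(cls, levels = ulev))
}

#' Write an expression dataset to matrix and label files
#'
#' @param dataset An `"expression_dataset"`.
#' @param matrix_path Output path for the tab-delimited matrix.
#' @param labels_path Output path for the two-column label file.
#' @return `matrix_path`, invisibly.
#' @export
write_expression <- function(dataset, matrix_path, labels_path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  df <- data.frame(gene_id = rownames(dataset$expr),
                   dataset$expr, check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(dataset$expr),
               class = as.character(dataset$labels)),
    labels_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(matrix_path)
}

#' Read a scenario configuration file
#'
#' Flat `key: value` (or `key = value`) text format with keys `n`, `p`,
#' `m`, `effect`, `prevalence`, `covariance` (`identity` or `block`),
#' `rho`, `sigma` and optionally `seed`.  Lines starting with `#` are
#' comments.
#'
#' @param path Config file path.
#' @return A [simulation_scenario()]; any `seed` key is attached as the
#'   `"seed"` attribute.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("scenario config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*[:=]\\s*(.+)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) stop("cannot parse config line: '", lines[bad][1], "'")
  keys <- vapply(kv, `[[`, character(1), 2L)
  vals <- vapply(kv, `[[`, character(1), 3L)
  cfg <- stats::setNames(as.list(vals), keys)
  num <- function(key, default = NULL) {
    if (is.null(cfg[[key]])) return(default)
    v <- suppressWarnings(as.numeric(cfg[[key]]))
    if (is.na(v)) stop("config key '", key, "' is not numeric")
    v
  }
  for (key in c("n", "p", "m", "effect")) {
    if (is.null(cfg[[key]])) stop("config is missing required key '", key, "'")
  }
  covariance <- if (is.null(cfg$covariance) || cfg$covariance == "identity") {
    "identity"
  } else if (cfg$covariance == "block") {
    cov_block(num("rho", 0))
  } else {
    stop("config covariance must be 'identity' or 'block'")
  }
  sc <- simulation_scenario(
    n = num("n"), p = num("p"), m = num("m"), effect = num("effect"),
    prevalence = num("prevalence", 0.5), covariance = covariance,
    sigma = num("sigma", 1)
  )
  attr(sc, "seed") <- num("seed")
  sc
}

.report_payload <- function(x) {
  if (inherits(x, "split_analysis")) {
    .report_payload_nonparam(x)
  } else if (inherits(x, "scenario_result")) {
    .report_payload_parametric(x)
  } else {
    stop("'x' must be a split_analysis or scenario_result")
  }
}

.report_payload_nonparam <- function(x) {
  rec <- x$recommendation
  list(
    schema_version = REPORT_SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("optsplit")),
    method = "nonparametric_resampling",
    classifier = x$classifier,
    n = rec$n,
    grid = x$decomposition$grid,
    w = x$learning_curve$mean_error,
    fitted_w = predict(x$learning_curve$fit, x$decomposition$grid),
    av_estimate = x$variance_curve$av_estimate,
    B = x$decomposition$B,
    mse = x$decomposition$mse,
    rmse = x$decomposition$rmse,
    t_opt = rec$t_opt,
    plateau = rec$plateau,
    excess_half = rec$excess_half,
    excess_twothirds = rec$excess_twothirds,
    full_data_accuracy = rec$full_data_accuracy
  )
}

.report_payload_parametric <- function(x) {
  rec <- x$recommendation
  sc <- x$config$scenario
  list(
    schema_version = REPORT_SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("optsplit")),
    method = "parametric_simulation",
    scenario = list(n = sc$n, p = sc$p, m = sc$m, effect = sc$effect,
                    prevalence = sc$prevalence,
                    covariance = sc$covariance$kind, sigma = sc$sigma),
    n = rec$n,
    grid = x$decomposition$grid,
    mean_true_accuracy = x$mean_true_accuracy,
    mean_holdout_accuracy = x$mean_holdout_accuracy,
    A = x$decomposition$A,
    V = x$decomposition$V,
    B = x$decomposition$B,
    mse = x$decomposition$mse,
    rmse = x$decomposition$rmse,
    t_opt = rec$t_opt,
    plateau = rec$plateau,
    excess_half = rec$excess_half,
    excess_twothirds = rec$excess_twothirds,
    full_data_accuracy = rec$full_data_accuracy
  )
}

#' Write an analysis report to JSON (plus a TSV decomposition)
#'
#' Serializes a [recommend_split()] or [run_scenario()] result as a
#' versioned JSON report; the MSE decomposition table is additionally
#' written as tab-delimited text next to the report (same path with a
#' `.tsv` extension, or `decomposition_path`).
#'
#' @param x A `"split_analysis"` or `"scenario_result"`.
#' @param path Output path for the JSON report.
#' @param decomposition_path Optional path for the TSV decomposition.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, decomposition_path = NULL) {
  payload <- .report_payload(x)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (is.null(decomposition_path)) {
    decomposition_path <- paste0(sub("\\.json$", "", path), ".tsv")
  }
  write_decomposition(x$decomposition, decomposition_path)
  invisible(path)
}

#' Read a JSON analysis report
#'
#' @param path Report path written by [write_report()].
#' @return The report as a list.
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(rep$schema_version)) stop("not an analysis report: missing schema_version")
  rep
}
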