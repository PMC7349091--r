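#' Survey dataset container for the hierarchical logit model
#'
#' Bundles a binary outcome vector, a numeric covariate matrix and a
#' group index (here: school grade) after validating the structure the
#' model relies on: a 0/1 outcome, no missing values anywhere, and a
#' contiguous `1..J` group coding with every group represented.
#'
#' @param y binary outcome vector (1 = intends to quit smoking).
#' @param X numeric covariate matrix, one row per respondent.
#' @param group integer group index per row, values `1..J`.
#' @param covariate_names optional character vector of `ncol(X)` unique
#'   labels; defaults to `colnames(X)`.
#' @param group_labels optional character vector of `J` labels.
#' @return An object of class `hl_dataset` with elements `y`, `X`,
#'   `group`, `covariate_names`, `group_labels`, `N`, `K`, `J`.
#' @export
hl_dataset <- function(y, X, group, covariate_names = NULL,
                       group_labels = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  group <- as.integer(group)

  if (anyNA(y) || anyNA(X) || anyNA(group))
    stop("hl_dataset: missing values are not allowed; drop incomplete rows first",
         call. = FALSE)
  if (!all(y %in% c(0, 1)))
    stop("hl_dataset: outcome must be coded 0/1", call. = FALSE)
  N <- length(y)
  if (nrow(X) != N || length(group) != N)
    stop("hl_dataset: y, X and group must have matching lengths", call. = FALSE)
  J <- max(group)
  if (min(group) < 1L || !setequal(unique(group), seq_len(J)))
    stop("hl_dataset: group must cover a contiguous 1..J with every group non-empty",
         call. = FALSE)
  if (N < J) stop("hl_dataset: need at least one row per group", call. = FALSE)
  K <- ncol(X)
  if (K < 1L) stop("hl_dataset: need at least one covariate", call. = FALSE)

  if (is.null(covariate_names)) covariate_names <- colnames(X)
  if (is.null(covariate_names)) covariate_names <- paste0("x", seq_len(K))
  covariate_names <- as.character(covariate_names)
  if (length(covariate_names) != K || anyDuplicated(covariate_names))
    stop("hl_dataset: covariate_names must be ", K, " unique labels",
         call. = FALSE)
  colnames(X) <- covariate_names
  if (is.null(group_labels)) group_labels <- paste0("grp", seq_len(J))
  if (length(group_labels) != J)
    stop("hl_dataset: group_labels must have one entry per group", call. = FALSE)

  structure(
    list(y = y, X = X, group = group,
         covariate_names = covariate_names,
         group_labels = as.character(group_labels),
         N = N, K = K, J = J),
    class = "hl_dataset")
}

#' @export
print.hl_dataset <- function(x, ...) {
  cat("<hl_dataset> ", x$N, " rows, ", x$K, " covariates, ",
      x$J, " groups (", paste(x$group_labels, collapse = ", "), ")\n",
      "outcome prevalence: ", signif(mean(x$y), 4), "\n", sep = "")
  invisible(x)
}

#' Read a survey CSV into an `hl_dataset`
#'
#' The CSV must have a header; the outcome, group and covariate columns
#' are named explicitly (column roles), everything must parse as numeric
#' and rows with any missing value are rejected rather than dropped
#' silently.
#'
#' @param path CSV file path.
#' @param outcome name of the 0/1 outcome column.
#' @param group name of the group (grade) column; values must already be
#'   coded `1..J`.
#' @param covariates character vector of covariate column names; default
#'   uses every remaining column.
#' @return An `hl_dataset`.
#' @export
read_survey_csv <- function(path, outcome, group, covariates = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (is.null(covariates))
    covariates <- setdiff(names(df), c(outcome, group))
  missing_cols <- setdiff(c(outcome, group, covariates), names(df))
  if (length(missing_cols))
    stop("read_survey_csv: columns not found: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  num <- df[c(outcome, group, covariates)]
  bad <- !vapply(num, is.numeric, logical(1))
  if (any(bad))
    stop("read_survey_csv: non-numeric columns: ",
         paste(names(num)[bad], collapse = ", "), call. = FALSE)
  hl_dataset(y = df[[outcome]], X = as.matrix(df[covariates]),
             group = df[[group]], covariate_names = covariates)
}

#' Write an `hl_dataset` back to CSV
#'
#' Inverse of [read_survey_csv()]; the outcome column is written as
#' `outcome`, the group column as `group`, followed by the covariates.
#'
#' @param data an `hl_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(data, path) {
  stopifnot(inherits(data, "hl_dataset"))
  df <- data.frame(outcome = data$y, group = data$group, check.names = FALSE)
  df <- cbind(df, as.data.frame(data$X, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
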