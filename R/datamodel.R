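#' Standardize a methylation matrix per site
#'
#' Each site (row) is centred and scaled to sample standard deviation one
#' (denominator `n - 1`), so that downstream regression coefficients are in
#' per-site SD units.  Standardization is idempotent and equivariant under
#' permutation of individuals.
#'
#' @param methylation Numeric matrix, sites in rows (rownames are site IDs),
#'   individuals in columns.  No missing values are allowed: the package
#'   models covariate missingness only.
#' @return The standardized matrix with attribute `standardized = TRUE`.
#' @export
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 6, 8), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("cg1", "cg2"), c("s1", "s2", "s3")))
#' standardize_methylation(m)
standardize_methylation <- function(methylation) {
  methylation <- as_methylation_matrix(methylation)
  n <- ncol(methylation)
  if (n < 2L) stop("need at least 2 individuals to standardize", call. = FALSE)
  mu <- rowMeans(methylation)
  centred <- methylation - mu
  sds <- sqrt(rowSums(centred^2) / (n - 1))
  if (any(sds <= 0)) {
    bad <- rownames(methylation)[which(sds <= 0)]
    stop("zero variance at site(s): ", paste(head(bad, 5L), collapse = ", "),
         call. = FALSE)
  }
  out <- centred / sds
  attr(out, "standardized") <- TRUE
  out
}

# coerce matrix or site_id-keyed data frame to the internal matrix form and
# validate the container invariants
as_methylation_matrix <- function(x) {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1L]])
    vals <- as.matrix(x[, -1L, drop = FALSE])
    if (!is.numeric(vals)) stop("non-numeric methylation values", call. = FALSE)
    rownames(vals) <- ids
    x <- vals
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("methylation must be a numeric matrix or a site_id-keyed data frame",
         call. = FALSE)
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("site", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x))) stop("duplicated site IDs", call. = FALSE)
  if (!is.null(colnames(x)) && anyDuplicated(colnames(x)))
    stop("duplicated sample IDs", call. = FALSE)
  if (anyNA(x)) stop("missing values in methylation matrix: only covariate ",
                     "missingness is modelled", call. = FALSE)
  x
}

#' Declare the type of each covariate column
#'
#' A schema types each covariate as `continuous`, `binary` or `categorical`;
#' categorical (and binary) variables carry an explicit level list whose
#' first element is the reference level.  The default schema describes the
#' smoking-EWAS covariates: age in years, sex (female reference) and
#' three-level smoking status with reference `"never"`.
#'
#' @param ... Named specifications, each `list(type = , levels = )`.
#' @return A `covariate_schema` object (a named list).
#' @export
#' @examples
#' covariate_schema(
#'   age = list(type = "continuous"),
#'   sex = list(type = "binary", levels = c("female", "male")),
#'   smoking = list(type = "categorical",
#'                  levels = c("never", "former", "current"))
#' )
covariate_schema <- function(...) {
  spec <- list(...)
  if (length(spec) == 1L && is.null(names(spec)) && is.list(spec[[1L]]))
    spec <- spec[[1L]]
  for (nm in names(spec)) {
    s <- spec[[nm]]
    s$type <- match.arg(s$type, c("continuous", "binary", "categorical"))
    if (s$type != "continuous") {
      if (is.null(s$levels) || length(s$levels) < 2L)
        stop("variable '", nm, "' needs >= 2 levels", call. = FALSE)
      s$reference <- s$reference %||% s$levels[[1L]]
      if (!s$reference %in% s$levels)
        stop("reference level of '", nm, "' not among its levels", call. = FALSE)
    }
    spec[[nm]] <- s
  }
  structure(spec, class = "covariate_schema")
}

#' @rdname covariate_schema
#' @export
default_schema <- function() {
  covariate_schema(
    age = list(type = "continuous"),
    sex = list(type = "binary", levels = c("female", "male")),
    smoking = list(type = "categorical",
                   levels = c("never", "former", "current"))
  )
}

#' Read and write covariate schemas (YAML)
#' @param schema A [covariate_schema()].
#' @param path File path.
#' @return `read_schema()` returns a `covariate_schema`.
#' @export
write_schema <- function(schema, path) {
  yaml::write_yaml(lapply(unclass(schema), function(s) s), path)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  covariate_schema(yaml::read_yaml(path))
}

#' Read a methylation matrix from TSV
#'
#' The format is one row per site: a `site_id` column followed by one
#' numeric column per sample.  Missing values are an error — methylation
#' here is the fully observed outcome.
#'
#' @param path TSV path.
#' @return Numeric matrix, sites x individuals.
#' @export
read_methylation <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(tbl)[1L] != "site_id")
    stop("first column of a methylation file must be 'site_id'", call. = FALSE)
  for (nm in names(tbl)[-1L]) {
    if (!is.numeric(tbl[[nm]]))
      stop("non-numeric methylation cell in column '", nm, "'", call. = FALSE)
  }
  as_methylation_matrix(tbl)
}

#' @rdname read_methylation
#' @param methylation Sites x individuals numeric matrix.
#' @export
write_methylation <- function(methylation, path) {
  methylation <- as_methylation_matrix(methylation)
  tbl <- tibble::as_tibble(methylation, .name_repair = "minimal")
  tbl <- dplyr::bind_cols(tibble::tibble(site_id = rownames(methylation)), tbl)
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Read a covariate table against a schema
#'
#' CSV with a header and a leading `sample_id` column; missing cells hold
#' the literal token `NA`.  Categorical values outside the schema's level
#' list raise an error naming the row and offending level.
#'
#' @param path CSV path.
#' @param schema A [covariate_schema()] describing every non-ID column.
#' @return A tibble with `sample_id` plus typed covariate columns (factors
#'   carry the schema's levels with the reference first).
#' @export
read_covariates <- function(path, schema = default_schema()) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = "NA", col_types = readr::cols(.default = "c"))
  if (names(tbl)[1L] != "sample_id")
    stop("first column of a covariate file must be 'sample_id'", call. = FALSE)
  if (anyDuplicated(tbl$sample_id)) stop("duplicated sample IDs", call. = FALSE)
  for (nm in names(tbl)[-1L]) {
    if (!nm %in% names(schema))
      stop("column '", nm, "' not declared in the schema", call. = FALSE)
    s <- schema[[nm]]
    x <- tbl[[nm]]
    if (s$type == "continuous") {
      val <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & is.na(val))
      if (length(bad))
        stop("non-numeric value '", x[bad[1L]], "' in '", nm, "' at row ",
             bad[1L], call. = FALSE)
      tbl[[nm]] <- val
    } else {
      bad <- which(!is.na(x) & !x %in% s$levels)
      if (length(bad))
        stop("unknown level '", x[bad[1L]], "' for '", nm, "' at row ",
             bad[1L], call. = FALSE)
      lev <- c(s$reference, setdiff(s$levels, s$reference))
      tbl[[nm]] <- factor(x, levels = lev)
    }
  }
  tbl
}

#' @rdname read_covariates
#' @param covariates Covariate tibble (first column `sample_id`).
#' @export
write_covariates <- function(covariates, path) {
  readr::write_csv(covariates, path, na = "NA")
  invisible(path)
}

#' Write / read an EWAS results table (TSV)
#'
#' Columns: `site_id, beta_former, se_former, p_former, beta_current,
#' se_current, p_current, df, significant`.  When a results tibble carries
#' per-coefficient degrees of freedom (`df_former`, `df_current`) the
#' written `df` is their per-site minimum.
#'
#' @param results A pooled EWAS tibble (see [run_strategy()]).
#' @param path TSV path.
#' @export
write_results <- function(results, path) {
  df <- if ("df" %in% names(results)) results$df else
    pmin(results$df_former, results$df_current)
  out <- tibble::tibble(
    site_id = results$site_id,
    beta_former = results$beta_former, se_former = results$se_former,
    p_former = results$p_former,
    beta_current = results$beta_current, se_current = results$se_current,
    p_current = results$p_current,
    df = df, significant = results$significant
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
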