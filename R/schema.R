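#' Variable schema for a post-COVID pain cohort
#'
#' The cohort data model is a fixed set of 12 variables: two exogenous
#' (BMI and Sex) and ten endogenous patient-reported outcomes. Each
#' variable carries its role in the path model, its measurement kind,
#' the instrument bounds, and the raw-scale generating mean/SD used by
#' the synthetic cohort generator. The binary Sex variable additionally
#' carries the cohort female fraction (Sex is coded female = 0,
#' male = 1).
#'
#' @return A data frame of class `painpath_schema` with one row per
#'   variable and columns `name`, `role`, `kind`, `scale_min`,
#'   `scale_max`, `gen_mean`, `gen_sd`, `female_fraction`.
#' @examples
#' sch <- default_schema()
#' sch$name
#' @export
default_schema <- function() {
  sch <- data.frame(
    name = c("BMI", "Sex", "Pain", "Anx", "Dep", "Sleep", "PainDETECT",
             "S-LANSS", "CSI", "Catastrop", "Fear", "EQ-5D"),
    role = c("exogenous", "exogenous", rep("endogenous", 10)),
    kind = c("continuous", "binary", rep("continuous", 10)),
    scale_min = c(10, 0, 0, 0, 0, 0, -1, 0, 0, 0, 11, 0),
    scale_max = c(60, 1, 10, 21, 21, 21, 38, 24, 100, 52, 44, 1),
    gen_mean = c(29.25, NA, 5.6, 5.2, 4.9, 8.0, 7.0, 7.5, 33.9, 12.3, 24.0, 0.8),
    gen_sd = c(5.2, NA, 1.7, 4.2, 4.3, 4.2, 6.2, 8.5, 17.2, 12.0, 8.6, 0.2),
    female_fraction = c(NA, 0.545, rep(NA, 10)),
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
  validate_schema(sch)
}

validate_schema <- function(sch) {
  stopifnot(is.data.frame(sch))
  required <- c("name", "role", "kind", "scale_min", "scale_max",
                "gen_mean", "gen_sd")
  missing_cols <- setdiff(required, names(sch))
  if (length(missing_cols) > 0) {
    stop("schema is missing fields: ", paste(missing_cols, collapse = ", "))
  }
  if (!"female_fraction" %in% names(sch)) sch$female_fraction <- NA_real_
  if (anyDuplicated(sch$name)) stop("schema variable names must be unique")
  if (!all(sch$role %in% c("exogenous", "endogenous"))) {
    stop("schema roles must be 'exogenous' or 'endogenous'")
  }
  if (!all(sch$kind %in% c("continuous", "binary"))) {
    stop("schema kinds must be 'continuous' or 'binary'")
  }
  cont <- sch$kind == "continuous"
  if (any(sch$scale_min[cont] >= sch$scale_max[cont])) {
    stop("scale_min must be < scale_max for continuous variables")
  }
  if (any(!is.na(sch$gen_sd[cont]) & sch$gen_sd[cont] <= 0)) {
    stop("gen_sd must be > 0 for continuous variables")
  }
  class(sch) <- c("painpath_schema", "data.frame")
  sch
}

#' Read a variable schema from a JSON or YAML config file
#'
#' The file holds a list of variable records, each with the fields of
#' [default_schema()] (`female_fraction` may be omitted except for
#' binary variables).
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `painpath_schema` data frame.
#' @export
read_schema <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    do.call(rbind, lapply(yaml::read_yaml(path), function(rec) {
      as.data.frame(rec[c("name", "role", "kind", "scale_min", "scale_max",
                          "gen_mean", "gen_sd",
                          if ("female_fraction" %in% names(rec)) "female_fraction")],
                    check.names = FALSE)
    }))
  }
  if (!"female_fraction" %in% names(raw)) raw$female_fraction <- NA_real_
  for (col in c("gen_mean", "gen_sd", "female_fraction")) {
    raw[[col]] <- as.numeric(raw[[col]])
  }
  validate_schema(raw)
}

#' Construct a cohort table
#'
#' A `cohort_table` binds a numeric subjects-by-variables data frame to a
#' [default_schema()]-style variable schema. Missing cells are `NA`.
#' Schema columns come first, in schema order; extra columns are kept as
#' passthrough.
#'
#' @param data A data frame containing at least all schema variables.
#' @param schema A `painpath_schema`; defaults to [default_schema()].
#' @return An object of class `cohort_table`: a list with elements
#'   `data` (data frame) and `schema`.
#' @export
cohort_table <- function(data, schema = default_schema()) {
  schema <- validate_schema(schema)
  missing_vars <- setdiff(schema$name, names(data))
  if (length(missing_vars) > 0) {
    stop("cohort is missing required column(s): ",
         paste(missing_vars, collapse = ", "))
  }
  extra <- setdiff(names(data), schema$name)
  data <- data[, c(schema$name, extra), drop = FALSE]
  for (v in schema$name) {
    if (!is.numeric(data[[v]])) {
      stop("column '", v, "' is not numeric")
    }
  }
  binary <- schema$name[schema$kind == "binary"]
  for (v in binary) {
    vals <- data[[v]][!is.na(data[[v]])]
    if (!all(vals %in% c(0, 1))) {
      stop("binary column '", v, "' contains values other than 0/1")
    }
  }
  structure(list(data = data, schema = schema), class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table:", nrow(x$data), "subjects,",
      nrow(x$schema), "schema variables")
  extra <- setdiff(names(x$data), x$schema$name)
  if (length(extra) > 0) cat(",", length(extra), "passthrough columns")
  miss <- missingness_report(x)
  cat(sprintf(", %.1f%% missing\n", 100 * miss$overall))
  invisible(x)
}

#' @export
as.data.frame.cohort_table <- function(x, ...) x$data

#' Number of subjects in a cohort table
#' @param table A `cohort_table`.
#' @return Integer row count.
#' @export
n_subjects <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  nrow(table$data)
}

#' Load a cohort from CSV
#'
#' Reads an RFC-4180-style CSV with a header row. Empty cells and the
#' tokens `NA`/`NaN` denote missing values. All schema columns must be
#' present and numeric; extra columns are preserved.
#'
#' @param path CSV file path.
#' @param schema Variable schema; defaults to [default_schema()].
#' @return A `cohort_table`.
#' @export
load_cohort <- function(path, schema = default_schema()) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         na.strings = c("", "NA", "NaN"),
                         colClasses = "character")
  schema <- validate_schema(schema)
  missing_vars <- setdiff(schema$name, names(raw))
  if (length(missing_vars) > 0) {
    stop("cohort file is missing required column(s): ",
         paste(missing_vars, collapse = ", "))
  }
  for (v in names(raw)) {
    col <- raw[[v]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(num))
    if (length(bad) > 0 && v %in% schema$name) {
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   col[bad[1]], bad[1], v))
    }
    if (length(bad) == 0) raw[[v]] <- num
  }
  cohort_table(raw, schema)
}

#' Write a cohort to CSV
#'
#' Missing cells are written as empty fields so that
#' `load_cohort(write_cohort(x))` round-trips values and the missing
#' mask exactly.
#'
#' @param table A `cohort_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  stopifnot(inherits(table, "cohort_table"))
  utils::write.csv(table$data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Standardize a cohort table
#'
#' Centres and scales every continuous schema variable to sample mean 0
#' and sample standard deviation 1 (n - 1 denominator). Binary
#' variables keep their 0/1 coding (centre 0, spread 1 in the returned
#' scaling parameters); a fully standardized reporting solution is
#' produced downstream by the path-model fit. Requires complete data.
#'
#' @param table A `cohort_table` with no missing cells in schema columns.
#' @return A list with `table` (the standardized `cohort_table`) and
#'   `scaling` (a data frame of per-variable `center` and `spread`
#'   allowing exact inversion via [unstandardize()]).
#' @export
standardize <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  sch <- table$schema
  dat <- table$data
  if (anyNA(dat[, sch$name])) {
    stop("standardize requires complete data; impute first")
  }
  center <- stats::setNames(rep(0, nrow(sch)), sch$name)
  spread <- stats::setNames(rep(1, nrow(sch)), sch$name)
  for (v in sch$name[sch$kind == "continuous"]) {
    s <- stats::sd(dat[[v]])
    if (!is.finite(s) || s < 1e-12) {
      stop("column '", v, "' has zero variance; cannot standardize")
    }
    center[v] <- mean(dat[[v]])
    spread[v] <- s
    dat[[v]] <- (dat[[v]] - center[v]) / s
  }
  scaling <- data.frame(name = sch$name, center = unname(center),
                        spread = unname(spread), stringsAsFactors = FALSE)
  list(table = cohort_table(dat, sch), scaling = scaling)
}

#' Invert a standardization
#'
#' @param table A standardized `cohort_table`.
#' @param scaling The `scaling` data frame returned by [standardize()].
#' @return The `cohort_table` on its original scales.
#' @export
unstandardize <- function(table, scaling) {
  stopifnot(inherits(table, "cohort_table"))
  if (any(scaling$spread <= 0)) stop("scaling spreads must be > 0")
  dat <- table$data
  for (i in seq_len(nrow(scaling))) {
    v <- scaling$name[i]
    dat[[v]] <- dat[[v]] * scaling$spread[i] + scaling$center[i]
  }
  cohort_table(dat, table$schema)
}

#' Report per-variable and overall missingness
#'
#' @param table A `cohort_table`.
#' @return A list with `per_variable` (named fraction vector over schema
#'   variables) and `overall` (total missing cells / total cells).
#' @export
missingness_report <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  vars <- table$schema$name
  m <- vapply(vars, function(v) mean(is.na(table$data[[v]])), numeric(1))
  if (nrow(table$data) == 0) m[] <- 0
  total <- nrow(table$data) * length(vars)
  overall <- if (total == 0) 0 else sum(is.na(table$data[, vars])) / total
  list(per_variable = m, overall = overall)
}
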