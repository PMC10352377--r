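#' Variable schema for harmonized survey tables
#'
#' A schema is a list of variable definitions, one per column of a
#' harmonized survey table. Each definition records the variable name, its
#' kind (`"categorical"`, `"ordinal"` or `"continuous"`), the ordered level
#' labels (empty for continuous variables), the numeric code attached to
#' each level for ordinal variables, and whether missing values are allowed.
#'
#' @param name Variable name (a syntactic identifier).
#' @param kind One of `"categorical"`, `"ordinal"`, `"continuous"`.
#' @param levels Character vector of level labels, ordered; must be empty
#'   for continuous variables and unique otherwise.
#' @param codes Numeric codes per level for ordinal variables; defaults to
#'   `seq_along(levels)`.
#' @param missing_allowed Logical; whether cells may be missing.
#' @return An object of class `variable_schema`.
#' @export
variable_schema <- function(name, kind = c("categorical", "ordinal", "continuous"),
                            levels = character(), codes = NULL,
                            missing_allowed = FALSE) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  levels <- as.character(levels)
  if (kind == "continuous" && length(levels) > 0L)
    stop("continuous variable '", name, "' must not have levels")
  if (kind != "continuous") {
    if (length(levels) < 1L)
      stop("variable '", name, "' needs at least one level")
    if (anyDuplicated(levels))
      stop("duplicate level labels for variable '", name, "'")
  }
  if (is.null(codes)) codes <- if (kind == "ordinal") seq_along(levels) else NULL
  if (kind == "ordinal" && length(codes) != length(levels))
    stop("ordinal variable '", name, "' needs one numeric code per level")
  structure(
    list(name = name, kind = kind, levels = levels, codes = codes,
         missing_allowed = isTRUE(missing_allowed)),
    class = "variable_schema"
  )
}

#' Default twelve-variable harmonized survey schema
#'
#' The harmonized variable set used throughout the package: country, sex,
#' 7-level age group, BMI-under-25 indicator, hypertension, diabetes,
#' smoking, marital status, household size, education, household income and
#' immigrant status. An optional continuous BMI column (`bmi`) can be added
#' to exercise the continuous synthesis path.
#'
#' @param continuous_bmi Logical; include a continuous `bmi` column.
#' @return A named list of [variable_schema()] entries (class `survey_schema`).
#' @export
survey_schema <- function(continuous_bmi = FALSE) {
  yn <- c("no", "yes")
  defs <- list(
    variable_schema("country", "categorical", c("CA", "AT")),
    variable_schema("sex", "categorical", c("male", "female")),
    variable_schema("age_group", "ordinal",
                    c("<20", "20-29", "30-39", "40-49", "50-59", "60-69", ">=70"),
                    codes = 1:7, missing_allowed = TRUE),
    variable_schema("bmi_lt25", "categorical", yn, missing_allowed = TRUE),
    variable_schema("hypertension", "categorical", yn, missing_allowed = TRUE),
    variable_schema("diabetes", "categorical", yn, missing_allowed = TRUE),
    variable_schema("smoking", "categorical", yn, missing_allowed = TRUE),
    variable_schema("marital_status", "categorical",
                    c("single", "divorced/widowed", "common-law/married"),
                    missing_allowed = TRUE),
    variable_schema("household_size", "ordinal",
                    c("1", "2", "3", "4", "5+"), codes = 1:5,
                    missing_allowed = TRUE),
    variable_schema("education", "ordinal",
                    c("<secondary", "secondary", "post-secondary", ">post-secondary"),
                    codes = 1:4, missing_allowed = TRUE),
    variable_schema("household_income", "ordinal",
                    c("low", "medium", "high"), codes = 1:3,
                    missing_allowed = TRUE),
    variable_schema("immigrant", "categorical", yn, missing_allowed = TRUE)
  )
  if (continuous_bmi)
    defs <- c(defs, list(variable_schema("bmi", "continuous",
                                         missing_allowed = TRUE)))
  names(defs) <- vapply(defs, `[[`, character(1), "name")
  structure(defs, class = "survey_schema")
}

schema_names <- function(schema) vapply(schema, `[[`, character(1), "name")

#' Validate a harmonized survey table against a schema
#'
#' Checks that every column matches exactly one schema entry, that every
#' non-missing cell is a valid level (or finite number for continuous
#' variables), that the table is non-empty, and that missing cells occur
#' only where the schema allows them.
#'
#' @param table A data.frame of respondent records.
#' @param schema A `survey_schema` (or list of [variable_schema()]).
#' @return Invisibly `table`; stops with an informative error otherwise.
#' @export
validate_table <- function(table, schema) {
  stopifnot(is.data.frame(table))
  if (nrow(table) < 1L) stop("table has no rows")
  for (v in schema) {
    if (!v$name %in% names(table))
      stop("column '", v$name, "' missing from table")
    x <- table[[v$name]]
    miss <- is.na(x)
    if (any(miss) && !v$missing_allowed)
      stop("missing values in '", v$name, "' but schema forbids them")
    if (v$kind == "continuous") {
      if (!is.numeric(x)) stop("column '", v$name, "' must be numeric")
      if (any(!is.finite(x[!miss])))
        stop("non-finite values in continuous column '", v$name, "'")
    } else {
      bad <- !miss & !(as.character(x) %in% v$levels)
      if (any(bad))
        stop("invalid level(s) in '", v$name, "': ",
             paste(unique(as.character(x)[bad]), collapse = ", "))
    }
  }
  extra <- setdiff(names(table), schema_names(schema))
  if (length(extra))
    stop("columns not in schema: ", paste(extra, collapse = ", "))
  invisible(table)
}

#' Read / write harmonized survey tables as delimited text
#'
#' Tables are comma-separated UTF-8 text with a header row; the empty
#' string encodes a missing value. The schema can be stored alongside the
#' data as a JSON sidecar.
#'
#' @param table A data.frame.
#' @param path File path.
#' @param schema A `survey_schema`; for reading, column types and level
#'   sets are taken from it.
#' @return `read_survey_csv` returns a validated data.frame.
#' @export
write_survey_csv <- function(table, path) {
  out <- table
  for (j in seq_along(out)) {
    x <- out[[j]]
    x <- if (is.numeric(x)) as.character(x) else as.character(x)
    x[is.na(x)] <- ""
    out[[j]] <- x
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path, schema) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  for (v in schema) {
    x <- raw[[v$name]]
    x[x == ""] <- NA
    raw[[v$name]] <- if (v$kind == "continuous") as.numeric(x) else x
  }
  validate_table(raw, schema)
  raw
}

#' @rdname write_survey_csv
#' @export
write_schema_json <- function(schema, path) {
  obj <- lapply(unclass(schema), function(v) {
    v <- unclass(v)
    v["codes"] <- list(v$codes)  # keep NULL explicit
    v
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_schema_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  defs <- lapply(obj, function(v)
    variable_schema(v$name, v$kind, levels = unlist(v$levels),
                    codes = if (is.null(v$codes) || !length(v$codes)) NULL
                            else as.numeric(unlist(v$codes)),
                    missing_allowed = isTRUE(v$missing_allowed)))
  names(defs) <- vapply(defs, `[[`, character(1), "name")
  structure(defs, class = "survey_schema")
}
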