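#' Variable schema for a BCRL cohort
#'
#' A schema is a tibble with one row per clinical variable giving its name,
#' type (`continuous`, `ordinal`, `categorical` or `binary`), the number of
#' admissible levels and the ordered integer codes with human-readable
#' labels. The default schema transcribes the 23-variable roster used for
#' BCRL risk stratification: 9 ordinal/categorical variables, continuous
#' AGE and BMI (binned to AGE GROUP and BMI GROUP during preparation), and
#' 12 binary variables, plus the binary BCRL outcome.
#'
#' Level counts for RT TYPE, HR DRUG, HISTOTYPE and MOLECULAR SUBTYPE are
#' not uniquely determined by the published variable table; the defaults
#' here are documented guesses (4, 7, 4 and 4 levels) chosen to be
#' consistent with the printed modal values, and can be overridden by
#' supplying a custom schema JSON.
#'
#' @param name Character vector of variable names.
#' @param vtype Character vector of types, one of `"continuous"`,
#'   `"ordinal"`, `"categorical"`, `"binary"`.
#' @param levels Integer count of distinct admissible values (`NA` for
#'   continuous variables).
#' @param codes List of integer code vectors (NULL for continuous).
#' @param labels List of character label vectors parallel to `codes`.
#' @return A `bcrl_schema` tibble.
#' @export
bcrl_schema <- function(name, vtype, levels, codes, labels = NULL) {
  vtype <- match.arg(vtype, c("continuous", "ordinal", "categorical", "binary"),
                     several.ok = TRUE)
  if (anyDuplicated(name)) {
    abort("Variable names must be unique within a schema.")
  }
  if (is.null(labels)) labels <- purrr::map(codes, ~ if (is.null(.x)) NULL else as.character(.x))
  sch <- tibble(
    name = as.character(name),
    vtype = vtype,
    levels = as.integer(levels),
    codes = purrr::map(codes, ~ if (is.null(.x)) NULL else as.integer(.x)),
    labels = labels
  )
  validate_schema(sch)
  structure(sch, class = c("bcrl_schema", class(tibble())))
}

validate_schema <- function(sch) {
  for (i in seq_len(nrow(sch))) {
    vt <- sch$vtype[i]; lv <- sch$levels[i]; cd <- sch$codes[[i]]
    if (vt == "continuous") next
    if (vt == "binary" && lv != 2L) {
      abort(sprintf("Binary variable '%s' must have exactly 2 levels.", sch$name[i]))
    }
    if (lv < 2L) {
      abort(sprintf("Variable '%s' must have at least 2 levels.", sch$name[i]))
    }
    if (length(cd) != lv) {
      abort(sprintf("Variable '%s': %d codes listed but levels = %d.",
                    sch$name[i], length(cd), lv))
    }
  }
  invisible(sch)
}

# Names of the published variable blocks, in schema order.
ORDINAL_VARS <- c("NR METASTATIC LN", "TOTAL NR DISSECTED LN", "RT TYPE",
                  "HR DRUG", "HISTOTYPE", "G", "T", "N", "MOLECULAR SUBTYPE")
BINARY_VARS <- c("BREAST SURGERY", "SIDE", "Ki67", "TAXANE BASED CT", "HT",
                 "TTZ", "LVI", "ECE", "ER", "HER2", "NCD", "PR")
GROUP_VARS <- c("AGE GROUP", "BMI GROUP")
OUTCOME_VAR <- "BCRL"

#' @rdname bcrl_schema
#' @export
default_bcrl_schema <- function() {
  spec <- list(
    list("NR METASTATIC LN", "ordinal", 0:9),
    list("TOTAL NR DISSECTED LN", "ordinal", 0:9),
    list("RT TYPE", "categorical", 0:3),
    list("HR DRUG", "categorical", 0:6),
    list("HISTOTYPE", "categorical", 0:3),
    list("G", "ordinal", 1:3),
    list("T", "ordinal", 1:4),
    list("N", "ordinal", 0:3),
    list("MOLECULAR SUBTYPE", "categorical", 0:3),
    list("AGE", "continuous", NULL),
    list("BMI", "continuous", NULL),
    list("BREAST SURGERY", "binary", 0:1),
    list("SIDE", "binary", 1:2),
    list("Ki67", "binary", 0:1),
    list("TAXANE BASED CT", "binary", 0:1),
    list("HT", "binary", 0:1),
    list("TTZ", "binary", 0:1),
    list("LVI", "binary", 0:1),
    list("ECE", "binary", 0:1),
    list("ER", "binary", 0:1),
    list("HER2", "binary", 0:1),
    list("NCD", "binary", 0:1),
    list("PR", "binary", 0:1)
  )
  bcrl_schema(
    name = purrr::map_chr(spec, 1),
    vtype = purrr::map_chr(spec, 2),
    levels = purrr::map_int(spec, ~ if (is.null(.x[[3]])) NA_integer_ else length(.x[[3]])),
    codes = purrr::map(spec, 3)
  )
}

#' Read or write a schema as JSON
#'
#' @param path Path to a JSON file: an array of objects with fields
#'   `name`, `vtype`, `levels` and `codes` (codes absent for continuous
#'   variables).
#' @return `read_schema()` returns a `bcrl_schema`; `write_schema()`
#'   invisibly returns `path`.
#' @export
read_schema <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  bcrl_schema(
    name = purrr::map_chr(raw, "name"),
    vtype = purrr::map_chr(raw, "vtype"),
    levels = purrr::map_int(raw, ~ if (is.null(.x$levels)) NA_integer_ else as.integer(.x$levels)),
    codes = purrr::map(raw, ~ if (is.null(.x$codes)) NULL else unlist(.x$codes)),
    labels = purrr::map(raw, ~ if (is.null(.x$labels)) NULL else as.character(unlist(.x$labels)))
  )
}

#' @rdname read_schema
#' @param schema A `bcrl_schema`.
#' @export
write_schema <- function(schema, path) {
  out <- purrr::pmap(schema, function(name, vtype, levels, codes, labels) {
    x <- list(name = name, vtype = vtype)
    if (!is.na(levels)) {
      x$levels <- levels
      x$codes <- codes
      x$labels <- labels
    }
    x
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

schema_of <- function(cohort) {
  sch <- attr(cohort, "schema")
  if (is.null(sch)) abort("Cohort carries no schema; build it with read_cohort() or simulate_cohort().")
  sch
}

new_bcrl_cohort <- function(data, schema) {
  structure(as_tibble(data), schema = schema,
            class = c("bcrl_cohort", class(tibble())))
}

#' Read and validate a cohort CSV
#'
#' The CSV has one row per patient and a header holding the schema's
#' variable names plus the `BCRL` outcome column (and optionally
#' `patient_id`). Every coded cell is checked against the schema's
#' admissible codes; violations are reported with the variable and row.
#'
#' @param path Path to the cohort CSV.
#' @param schema A `bcrl_schema`, or a path to a schema JSON file.
#'   Defaults to the packaged 23-variable schema.
#' @return A `bcrl_cohort` tibble (with the schema attached as an
#'   attribute) containing `patient_id`, one column per variable, and the
#'   binary `BCRL` outcome.
#' @export
read_cohort <- function(path, schema = default_bcrl_schema()) {
  if (is.character(schema)) schema <- read_schema(schema)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_cohort(df, schema)
}

#' @rdname read_cohort
#' @param data A data frame to validate against the schema.
#' @export
validate_cohort <- function(data, schema = default_bcrl_schema()) {
  df <- as_tibble(data)
  missing_cols <- setdiff(c(schema$name, OUTCOME_VAR), names(df))
  if (length(missing_cols)) {
    abort(sprintf("Cohort is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0) abort("Cohort must contain at least one patient.")
  if (!"patient_id" %in% names(df)) {
    df$patient_id <- sprintf("P%04d", seq_len(nrow(df)))
  }
  df$patient_id <- as.character(df$patient_id)
  out <- df[[OUTCOME_VAR]]
  bad <- which(is.na(out) | !(out %in% c(0, 1)))
  if (length(bad)) {
    abort(sprintf("Outcome '%s' must be 0/1 with no missing values (first bad row: %d).",
                  OUTCOME_VAR, bad[1]))
  }
  df[[OUTCOME_VAR]] <- as.integer(out)
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    x <- df[[nm]]
    if (schema$vtype[i] == "continuous") {
      if (!is.numeric(x) || any(!is.finite(x))) {
        bad <- if (is.numeric(x)) which(!is.finite(x))[1] else 1L
        abort(sprintf("Variable '%s' must be finite numeric (row %d).", nm, bad))
      }
    } else {
      codes <- schema$codes[[i]]
      xv <- suppressWarnings(as.integer(x))
      bad <- which(is.na(xv) | !(xv %in% codes))
      if (length(bad)) {
        abort(sprintf("Variable '%s' has value '%s' outside its %d admissible codes (row %d).",
                      nm, as.character(x[bad[1]]), schema$levels[i], bad[1]))
      }
      df[[nm]] <- xv
    }
  }
  keep <- c("patient_id", intersect(names(df), c(schema$name, OUTCOME_VAR)),
            intersect(names(df), ".stratum"))
  new_bcrl_cohort(df[, unique(keep)], schema)
}

#' @rdname read_cohort
#' @param cohort A `bcrl_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
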