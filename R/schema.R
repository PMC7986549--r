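# Questionnaire schema, cause list, record ingestion and validation.

DAYS_PER_YEAR <- 365.25

# Columns of a record table that are not symptom endorsements.
RESERVED_COLUMNS <- c(
  "death_id", "age_value", "age_unit", "sex", "module_id",
  "medical_records_available", "narrative_confident", "records_confident",
  "respondent_is_family", "true_cause"
)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Symptom schema for one questionnaire module
#'
#' A verbal autopsy questionnaire is split into age-specific modules
#' (neonate, child, adult), each with its own ordered list of binary
#' symptom questions. The schema fixes the symptom universe against which
#' records are parsed, validated and scored.
#'
#' @param module_id One of `"neonate"`, `"child"`, `"adult"`.
#' @param symptoms Character vector of unique symptom ids, non-empty.
#' @return An object of class `va_schema`.
#' @examples
#' va_schema("adult", c("chest_pain", "cough", "fever"))
#' @export
va_schema <- function(module_id, symptoms) {
  module_id <- match.arg(module_id, c("neonate", "child", "adult"))
  symptoms <- as.character(symptoms)
  if (length(symptoms) == 0L) {
    stop("schema must contain at least one symptom", call. = FALSE)
  }
  if (anyDuplicated(symptoms)) {
    stop("symptom ids must be unique within a module: ",
         paste(unique(symptoms[duplicated(symptoms)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(module_id = module_id, symptoms = symptoms),
            class = "va_schema")
}

#' @export
print.va_schema <- function(x, ...) {
  cat("VA symptom schema:", x$module_id, "module,",
      length(x$symptoms), "symptoms\n")
  invisible(x)
}

#' Cause list with ill-defined codes and category map
#'
#' @param causes Character vector of unique cause ids, in presentation order.
#' @param ill_defined Codes counted as ill-defined / garbage causes. The
#'   default covers ICD-10 R99 (other ill-defined and unspecified causes of
#'   mortality), I46 (cardiac arrest) and R54 (senility). Codes need not be
#'   members of `causes`: physicians may free-enter them.
#' @param category_map Named character vector mapping cause ids (including
#'   physician free-entry strings) to aggregate category labels, or `NULL`.
#' @return An object of class `va_cause_list`.
#' @export
va_cause_list <- function(causes,
                          ill_defined = c("R99", "I46", "R54"),
                          category_map = NULL) {
  causes <- as.character(causes)
  if (length(causes) == 0L) stop("cause list is empty", call. = FALSE)
  if (anyDuplicated(causes)) {
    stop("cause ids must be unique", call. = FALSE)
  }
  if (!is.null(category_map)) {
    if (is.null(names(category_map)) || any(names(category_map) == "")) {
      stop("category_map must be a fully named character vector", call. = FALSE)
    }
    category_map <- vapply(category_map, as.character, character(1))
  }
  structure(list(causes = causes,
                 ill_defined = as.character(ill_defined),
                 category_map = category_map),
            class = "va_cause_list")
}

#' @export
print.va_cause_list <- function(x, ...) {
  cat("VA cause list:", length(x$causes), "causes;",
      length(x$ill_defined), "ill-defined codes\n")
  invisible(x)
}

#' Assign the questionnaire module from age
#'
#' Routes a death to the neonate (0 to 27 completed days), child (28 days to
#' 11 years) or adolescent-and-adult (12 years and above) questionnaire
#' module. The bands are implemented half-open -- \[0, 28) days,
#' \[28 days, 12 years), \[12 years, Inf) -- so they are exhaustive and
#' disjoint; ages in years are converted at 365.25 days per year.
#'
#' @param age_value Non-negative numeric age(s).
#' @param age_unit `"days"` or `"years"`; recycled against `age_value`.
#' @return Character vector of module ids.
#' @examples
#' assign_age_module(10, "days")   # neonate
#' assign_age_module(28, "days")   # child
#' assign_age_module(12, "years")  # adult
#' @export
assign_age_module <- function(age_value, age_unit) {
  age_value <- as.numeric(age_value)
  age_unit <- as.character(age_unit)
  if (length(age_unit) == 1L) age_unit <- rep(age_unit, length(age_value))
  if (length(age_unit) != length(age_value)) {
    stop("age_value and age_unit lengths differ", call. = FALSE)
  }
  bad_unit <- !age_unit %in% c("days", "years")
  if (any(bad_unit, na.rm = TRUE) || anyNA(age_unit)) {
    stop("unknown age unit: ",
         paste(unique(age_unit[bad_unit | is.na(age_unit)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(age_value)) stop("age is missing", call. = FALSE)
  if (any(age_value < 0)) stop("age must be non-negative", call. = FALSE)
  days <- ifelse(age_unit == "years", age_value * DAYS_PER_YEAR, age_value)
  ifelse(days < 28, "neonate",
         ifelse(days < 12 * DAYS_PER_YEAR, "child", "adult"))
}

# Parse {0,1,true,false,yes,no} (case-insensitive) to logical; "" -> NA.
parse_flag <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "yes")] <- TRUE
  out[x %in% c("0", "false", "no")] <- FALSE
  out[is.na(x) | x == ""] <- NA
  bad <- !is.na(x) & x != "" & !x %in% c("0", "1", "true", "false", "yes", "no")
  attr(out, "bad") <- bad
  out
}

#' Parse field verbal-autopsy records from CSV
#'
#' Reads an ODK-style flat export: one row per death, a header row, required
#' columns `death_id`, `age_value`, `age_unit`, `sex`,
#' `medical_records_available`, optional pathway flags
#' (`narrative_confident`, `records_confident`, `respondent_is_family`), an
#' optional `true_cause` column (synthetic cohorts), and one column per
#' symptom id in the schema. Booleans are accepted as 0/1/true/false/yes/no
#' case-insensitively; blank symptom cells become missing (`NA`). Rows that
#' fail to parse (for example an unparseable age) are skipped and reported in
#' the `parse_errors` attribute rather than aborting the batch; field data is
#' dirty and a single bad row must not block a week's export.
#'
#' @param source Path to a CSV file, or a data.frame already read.
#' @param schema A [va_schema()].
#' @return A data.frame of class `va_records` with one row per successfully
#'   parsed record, `module_id` filled in via [assign_age_module()], symptom
#'   columns coded 0/1/NA, and attribute `parse_errors` (a data.frame with
#'   columns `row`, `death_id`, `message`).
#' @export
parse_va_records <- function(source, schema) {
  stopifnot(inherits(schema, "va_schema"))
  raw <- if (is.data.frame(source)) {
    as.data.frame(lapply(source, as.character), stringsAsFactors = FALSE,
                  check.names = FALSE)
  } else {
    utils::read.csv(source, colClasses = "character", check.names = FALSE)
  }
  required <- c("death_id", "age_value", "age_unit", "sex",
                "medical_records_available")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("records file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(raw$death_id)) {
    stop("duplicate death_id: ",
         paste(unique(raw$death_id[duplicated(raw$death_id)]), collapse = ", "),
         call. = FALSE)
  }

  symptom_cols <- intersect(schema$symptoms, names(raw))
  flag_cols <- intersect(c("medical_records_available", "narrative_confident",
                           "records_confident", "respondent_is_family"),
                         names(raw))

  n <- nrow(raw)
  keep <- rep(TRUE, n)
  errors <- list()
  note_error <- function(i, msg) {
    errors[[length(errors) + 1L]] <<- data.frame(
      row = i, death_id = raw$death_id[i], message = msg,
      stringsAsFactors = FALSE)
    keep[i] <<- FALSE
  }

  age_value <- suppressWarnings(as.numeric(raw$age_value))
  age_unit <- trimws(raw$age_unit)
  sex <- tolower(trimws(raw$sex))
  for (i in seq_len(n)) {
    if (is.na(age_value[i])) {
      note_error(i, sprintf("unparseable age_value '%s'", raw$age_value[i]))
    } else if (age_value[i] < 0) {
      note_error(i, "negative age_value")
    } else if (!age_unit[i] %in% c("days", "years")) {
      note_error(i, sprintf("unknown age_unit '%s'", raw$age_unit[i]))
    } else if (!sex[i] %in% c("male", "female")) {
      note_error(i, sprintf("invalid sex '%s'", raw$sex[i]))
    }
  }

  flags <- lapply(raw[flag_cols], parse_flag)
  for (col in flag_cols) {
    bad <- attr(flags[[col]], "bad")
    for (i in which(bad & keep)) {
      note_error(i, sprintf("unparseable boolean in '%s': '%s'", col,
                            raw[[col]][i]))
    }
  }

  out <- data.frame(death_id = raw$death_id, stringsAsFactors = FALSE)
  out$age_value <- age_value
  out$age_unit <- age_unit
  out$sex <- sex
  out$module_id <- rep(NA_character_, n)
  if (any(keep)) {
    out$module_id[keep] <- assign_age_module(age_value[keep], age_unit[keep])
  }
  for (col in flag_cols) out[[col]] <- as.logical(flags[[col]])
  if (!"narrative_confident" %in% names(out)) {
    out$narrative_confident <- rep(FALSE, n)
  }
  out$narrative_confident[is.na(out$narrative_confident)] <- FALSE
  if ("true_cause" %in% names(raw)) {
    out$true_cause <- ifelse(raw$true_cause == "", NA_character_,
                             raw$true_cause)
  }
  for (s in symptom_cols) {
    v <- parse_flag(raw[[s]])
    for (i in which(attr(v, "bad") & keep)) {
      note_error(i, sprintf("unparseable endorsement in '%s': '%s'", s,
                            raw[[s]][i]))
    }
    out[[s]] <- as.integer(as.logical(v))
  }
  for (s in setdiff(schema$symptoms, symptom_cols)) {
    out[[s]] <- rep(NA_integer_, n)
  }

  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  err <- if (length(errors)) do.call(rbind, errors) else
    data.frame(row = integer(), death_id = character(), message = character(),
               stringsAsFactors = FALSE)
  structure(out, parse_errors = err, module_id = schema$module_id,
            class = c("va_records", "data.frame"))
}

#' Write VA records back to CSV
#'
#' Inverse of [parse_va_records()]: field values and row order survive a
#' write/parse round trip exactly.
#'
#' @param records A `va_records` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_va_records <- function(records, path) {
  df <- as.data.frame(records)
  for (col in names(df)) {
    if (is.logical(df[[col]])) df[[col]] <- ifelse(df[[col]], "true", "false")
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate parsed records against the schema
#'
#' Issues are data, not exceptions: each one names the death, the offending
#' field and a description, so a whole export can be screened in one pass.
#' Checks per record: non-negative age, known sex, `module_id` consistent
#' with age, endorsement columns within the schema, endorsement values in
#' \{0, 1, missing\}.
#'
#' @param records A `va_records` data.frame (or compatible data.frame).
#' @param schema A [va_schema()].
#' @return A data.frame with columns `death_id`, `field`, `description`;
#'   zero rows when every record is valid.
#' @export
validate_records <- function(records, schema) {
  stopifnot(inherits(schema, "va_schema"))
  issues <- list()
  add <- function(id, field, description) {
    issues[[length(issues) + 1L]] <<- data.frame(
      death_id = id, field = field, description = description,
      stringsAsFactors = FALSE)
  }
  extra <- setdiff(names(records), c(RESERVED_COLUMNS, schema$symptoms))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    id <- as.character(r$death_id)
    if (is.na(r$age_value) || r$age_value < 0) {
      add(id, "age_value", "age missing or negative")
    } else if (!r$age_unit %in% c("days", "years")) {
      add(id, "age_unit", sprintf("unknown unit '%s'", r$age_unit))
    } else {
      expected <- assign_age_module(r$age_value, r$age_unit)
      if (is.na(r$module_id) || r$module_id != expected) {
        add(id, "module_id",
            sprintf("module '%s' inconsistent with age (expected '%s')",
                    r$module_id, expected))
      }
    }
    if (!r$sex %in% c("male", "female")) {
      add(id, "sex", sprintf("invalid sex '%s'", r$sex))
    }
    for (col in extra) {
      add(id, col, "endorsement key not in schema")
    }
    for (s in intersect(schema$symptoms, names(records))) {
      v <- r[[s]]
      if (!is.na(v) && !v %in% c(0L, 1L)) {
        add(id, s, sprintf("endorsement value '%s' not in {0,1,missing}", v))
      }
    }
  }
  if (length(issues)) do.call(rbind, issues) else
    data.frame(death_id = character(), field = character(),
               description = character(), stringsAsFactors = FALSE)
}

#' Read a symptom schema from YAML or JSON
#'
#' Expected keys: `module` (or `module_id`) and `symptoms`.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return A [va_schema()].
#' @export
read_schema_config <- function(path) {
  cfg <- read_config(path)
  va_schema(cfg$module %||% cfg$module_id, unlist(cfg$symptoms))
}

#' Read a cause list from YAML or JSON
#'
#' Expected keys: `causes`; optional `ill_defined` and `categories` (a
#' cause-to-category mapping).
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return A [va_cause_list()].
#' @export
read_cause_config <- function(path) {
  cfg <- read_config(path)
  cm <- cfg$categories
  if (!is.null(cm)) cm <- unlist(cm)
  va_cause_list(unlist(cfg$causes),
                ill_defined = unlist(cfg$ill_defined) %||%
                  c("R99", "I46", "R54"),
                category_map = cm)
}

read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
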