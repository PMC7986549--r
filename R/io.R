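# Serialization of fitted models, decision reports and outcome tables.

#' Write a fitted tariff model to JSON
#'
#' Serializes the endorsement matrix, tariff matrix, rank reference and all
#' options/seeds, so a trained model can be shipped to the field and
#' reloaded byte-identically.
#'
#' @param model A [va_tariff()] model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "va_tariff"))
  payload <- list(
    module_id = model$module_id,
    causes = model$causes$causes,
    ill_defined = model$causes$ill_defined,
    category_map = as.list(model$causes$category_map),
    symptoms = rownames(model$tariff),
    endorsement = apply(model$endorsement, 2L, identity, simplify = FALSE),
    tariff = apply(model$tariff, 2L, identity, simplify = FALSE),
    ref_scores = model$ref$scores,
    ref_per_cause_n = model$ref$per_cause_n,
    ref_seed = model$ref$seed,
    n_training = model$n_training,
    options = model$options)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted tariff model from JSON
#'
#' @param path Path written by [write_model_json()].
#' @return A [va_tariff()] model.
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  symptoms <- p$symptoms
  to_matrix <- function(lst) {
    m <- do.call(cbind, lst)
    rownames(m) <- symptoms
    m[, p$causes, drop = FALSE]
  }
  cm <- unlist(p$category_map)
  structure(list(
    endorsement = to_matrix(p$endorsement),
    tariff = to_matrix(p$tariff),
    ref = structure(list(scores = lapply(p$ref_scores[p$causes], as.numeric),
                         per_cause_n = as.integer(p$ref_per_cause_n),
                         seed = as.integer(p$ref_seed)),
                    class = "va_rank_reference"),
    causes = va_cause_list(p$causes, ill_defined = p$ill_defined,
                           category_map = if (length(cm)) cm else NULL),
    schema = va_schema(p$module_id, symptoms),
    module_id = p$module_id,
    n_training = p$n_training,
    options = p$options,
    call = NULL), class = "va_tariff")
}

#' Write decision reports as JSON lines
#'
#' One JSON object per death: death id, endorsed symptoms, ranked causes
#' with likelihood labels, undetermined flag.
#'
#' @param reports A `va_reports` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reports_jsonl <- function(reports, path) {
  lines <- vapply(reports, function(r) {
    jsonlite::toJSON(list(death_id = r$death_id,
                          endorsed_symptoms = r$endorsed_symptoms,
                          ranked_causes = r$ranked_causes,
                          undetermined = r$undetermined),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read certification outcomes CSV
#'
#' The weekly-export shape: `death_id`, `pathway`, `cause_1..3`,
#' `likelihood_1..3`, `physician_cause`, `used_tool_diagnosis`,
#' `agreement_top1` (plus `undetermined` and, for synthetic cohorts,
#' `true_cause`).
#'
#' @param outcomes Outcome data.frame from [record_certification()] /
#'   [simulate_certification()].
#' @param path CSV path.
#' @return `path` (write) or the outcomes data.frame (read).
#' @export
write_outcomes_csv <- function(outcomes, path) {
  utils::write.csv(outcomes, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_outcomes_csv
#' @export
read_outcomes_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  for (col in c("undetermined", "used_tool_diagnosis", "agreement_top1")) {
    if (col %in% names(df)) df[[col]] <- as.logical(parse_flag(df[[col]]))
  }
  for (col in intersect(c("cause_1", "cause_2", "cause_3", "likelihood_1",
                          "likelihood_2", "likelihood_3", "true_cause"),
                        names(df))) {
    df[[col]][df[[col]] == ""] <- NA_character_
  }
  df
}
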