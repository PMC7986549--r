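# Physician-facing decision support: demographic restrictions, threshold
# qualification, likelihood categories, top-3 reports, SOP routing and
# certification outcomes.

#' Qualification thresholds
#'
#' A cause is presented to the physician only if its absolute tariff score
#' and its percentile rank against the training reference both clear these
#' cutoffs; if no cause does, the report is "undetermined". The engine this
#' package models publishes no numeric thresholds, so these defaults are
#' artifact defaults, conservative and fully configurable.
#'
#' @param min_score Minimum absolute tariff score (default 0).
#' @param min_rank Minimum percentile rank in \[0, 1\] (default 0.5: at or
#'   above the median of the cause's own training reference).
#' @return An object of class `va_thresholds`.
#' @export
va_thresholds <- function(min_score = 0, min_rank = 0.5) {
  if (min_rank < 0 || min_rank > 1) {
    stop("min_rank must lie in [0, 1]", call. = FALSE)
  }
  structure(list(min_score = min_score, min_rank = min_rank),
            class = "va_thresholds")
}

#' Likelihood bins over percentile rank
#'
#' Maps a qualifying cause's percentile rank to one of four ordered
#' likelihood categories shown to the physician. Default cut-points
#' (artifact defaults; the categories are standard, the cut-points are
#' configuration): \[0.50, 0.65\] possible, (0.65, 0.80\] somewhat likely,
#' (0.80, 0.95\] likely, (0.95, 1.00\] very likely.
#'
#' @param edges Strictly increasing numeric vector of bin edges; the first
#'   edge is the qualification floor, the last must be 1.
#' @param labels Category labels, one fewer than edges, ordered from least
#'   to most likely.
#' @return An object of class `va_likelihood_bins`.
#' @export
va_likelihood_bins <- function(edges = c(0.50, 0.65, 0.80, 0.95, 1.00),
                               labels = c("possible", "somewhat likely",
                                          "likely", "very likely")) {
  if (any(diff(edges) <= 0)) {
    stop("bin edges must be strictly increasing", call. = FALSE)
  }
  if (edges[length(edges)] != 1) {
    stop("last bin edge must be 1", call. = FALSE)
  }
  if (length(labels) != length(edges) - 1L) {
    stop("need one label per bin", call. = FALSE)
  }
  structure(list(edges = edges, labels = as.character(labels)),
            class = "va_likelihood_bins")
}

#' Demographic restriction table
#'
#' Demographic-plausibility censoring: a cause may be restricted to one sex
#' and/or an age interval (in days, inclusive bounds); restricted causes are
#' removed from candidacy before thresholding, with scores retained for
#' audit.
#'
#' @param rules A data.frame with columns `cause`, `sexes` (`"male"`,
#'   `"female"` or `"any"`), `age_min_days`, `age_max_days` (`NA` for
#'   unbounded).
#' @return An object of class `va_restrictions`.
#' @export
restriction_table <- function(rules) {
  rules <- as.data.frame(rules, stringsAsFactors = FALSE)
  needed <- c("cause", "sexes", "age_min_days", "age_max_days")
  missing_cols <- setdiff(needed, names(rules))
  if (length(missing_cols)) {
    stop("restriction table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!rules$sexes %in% c("male", "female", "any"))) {
    stop("sexes must be one of male/female/any", call. = FALSE)
  }
  bad <- !is.na(rules$age_min_days) & !is.na(rules$age_max_days) &
    rules$age_min_days > rules$age_max_days
  if (any(bad)) stop("malformed age interval in restriction table",
                     call. = FALSE)
  structure(list(rules = rules), class = "va_restrictions")
}

#' Apply demographic restrictions to per-cause scores
#'
#' @param scores Named per-cause score vector for one death.
#' @param record One-row record (needs `sex`, `age_value`, `age_unit`), or
#'   `NULL` (no censoring possible).
#' @param table A [restriction_table()] or `NULL` for no restrictions.
#' @return A logical eligibility vector named by cause; scores themselves
#'   are untouched (retained for audit).
#' @export
apply_demographic_restrictions <- function(scores, record, table = NULL) {
  eligible <- stats::setNames(rep(TRUE, length(scores)), names(scores))
  if (is.null(table) || is.null(record) || nrow(table$rules) == 0L) {
    return(eligible)
  }
  age_days <- if (record$age_unit == "years") {
    record$age_value * DAYS_PER_YEAR
  } else {
    record$age_value
  }
  for (k in seq_len(nrow(table$rules))) {
    rule <- table$rules[k, ]
    if (!rule$cause %in% names(eligible)) next
    ok <- TRUE
    if (rule$sexes != "any" && !is.na(record$sex) && record$sex != rule$sexes) {
      ok <- FALSE
    }
    if (ok && !is.na(rule$age_min_days) && age_days < rule$age_min_days) {
      ok <- FALSE
    }
    if (ok && !is.na(rule$age_max_days) && age_days > rule$age_max_days) {
      ok <- FALSE
    }
    if (!ok) eligible[rule$cause] <- FALSE
  }
  eligible
}

#' Causes that clear the thresholds
#'
#' Returns the eligible causes whose score and percentile rank both meet
#' the thresholds, sorted by score descending with ties broken by higher
#' rank then lexicographic cause id (deterministic output for audit). An
#' empty result signals an undetermined death.
#'
#' @param scores Named per-cause scores for one death.
#' @param ranks Named per-cause percentile ranks.
#' @param thresholds A [va_thresholds()].
#' @param eligible Optional named logical vector (from
#'   [apply_demographic_restrictions()]).
#' @return Character vector of qualifying cause ids, best first.
#' @export
qualify_causes <- function(scores, ranks, thresholds = va_thresholds(),
                           eligible = NULL) {
  if (is.null(eligible)) {
    eligible <- stats::setNames(rep(TRUE, length(scores)), names(scores))
  }
  ok <- eligible[names(scores)] &
    scores >= thresholds$min_score &
    ranks[names(scores)] >= thresholds$min_rank
  qual <- names(scores)[ok]
  qual[order(-scores[qual], -ranks[qual], qual)]
}

#' Likelihood category for a qualifying rank
#'
#' @param rank_percentile Percentile rank(s), each at or above the bottom
#'   bin edge (the cause has already qualified).
#' @param bins A [va_likelihood_bins()].
#' @return Character vector of categories, monotone non-decreasing in rank.
#' @export
assign_likelihood <- function(rank_percentile, bins = va_likelihood_bins()) {
  if (any(rank_percentile < bins$edges[1] | rank_percentile > 1)) {
    stop("rank percentile outside the qualifying range [",
         bins$edges[1], ", 1]", call. = FALSE)
  }
  idx <- findInterval(rank_percentile, bins$edges, left.open = TRUE,
                      rightmost.closed = FALSE)
  idx[idx == 0L] <- 1L  # rank exactly at the qualification floor
  bins$labels[idx]
}

decision_report_from_scores <- function(scores, ranks, record, model,
                                        thresholds, bins, restrictions) {
  eligible <- apply_demographic_restrictions(scores, record, restrictions)
  qual <- qualify_causes(scores, ranks, thresholds, eligible)
  top <- utils::head(qual, 3L)
  ranked <- data.frame(cause = top,
                       score = unname(scores[top]),
                       rank = unname(ranks[top]),
                       likelihood = if (length(top)) {
                         # thresholds looser than the bins extend the
                         # bottom category down to the qualification floor
                         assign_likelihood(pmax(ranks[top], bins$edges[1]),
                                           bins)
                       } else character(0),
                       stringsAsFactors = FALSE)
  symptoms <- if (!is.null(model$schema)) model$schema$symptoms else
    rownames(model$tariff)
  endorsed <- character(0)
  death_id <- NA_character_
  if (!is.null(record)) {
    death_id <- as.character(record$death_id %||% NA_character_)
    present <- intersect(symptoms, names(record))
    vals <- unlist(record[present])
    endorsed <- present[!is.na(vals) & vals == 1]
  }
  structure(list(death_id = death_id,
                 endorsed_symptoms = endorsed,
                 ranked_causes = ranked,
                 undetermined = nrow(ranked) == 0L,
                 scores = scores, ranks = ranks, eligible = eligible),
            class = "va_report")
}

#' Build the physician-facing decision report for one death
#'
#' Composes the full decision-support output: the list of endorsed symptoms
#' (in schema order, a convenient interview summary for the physician), and
#' up to three ranked causes with likelihood categories -- or an
#' undetermined report when no cause clears the thresholds.
#'
#' @param record One-row `va_records` data.frame (or compatible list).
#' @param model A fitted [va_tariff()] model.
#' @param thresholds A [va_thresholds()].
#' @param bins A [va_likelihood_bins()].
#' @param restrictions A [restriction_table()] or `NULL`.
#' @return An object of class `va_report`: `death_id`,
#'   `endorsed_symptoms`, `ranked_causes` (data.frame with cause, score,
#'   rank, likelihood; best first), `undetermined`, plus the full per-cause
#'   `scores`, `ranks` and `eligible` vectors for audit.
#' @export
build_decision_report <- function(record, model,
                                  thresholds = va_thresholds(),
                                  bins = va_likelihood_bins(),
                                  restrictions = NULL) {
  scores <- score_deaths(record, model$tariff)
  if (!is.null(dim(scores))) scores <- scores[1L, ]
  ranks <- vapply(names(scores), function(j) {
    percentile_rank(scores[[j]], j, model$ref)
  }, numeric(1))
  decision_report_from_scores(scores, ranks, record, model, thresholds,
                              bins, restrictions)
}

#' @export
print.va_report <- function(x, ...) {
  cat("Decision report for death", x$death_id, "\n")
  cat("Endorsed symptoms:",
      if (length(x$endorsed_symptoms)) {
        paste(x$endorsed_symptoms, collapse = ", ")
      } else "(none)", "\n")
  if (x$undetermined) {
    cat("Cause: UNDETERMINED (no cause met the score and rank thresholds)\n")
  } else {
    cat("Top causes:\n")
    print(x$ranked_causes, row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.va_reports <- function(x, ...) {
  cat("List of", length(x), "decision reports;",
      sum(vapply(x, `[[`, logical(1), "undetermined")), "undetermined\n")
  invisible(x)
}

#' Route a death through the certification SOP
#'
#' Standard operating procedure: the physician certifies directly from
#' medical records when records are available and sufficient (`RECORDS`);
#' otherwise from the open narrative interview alone when confident
#' (`NARRATIVE`); otherwise the full structured verbal autopsy with decision
#' support is administered (`FULL_VA`). The open-ended narrative always
#' precedes the structured questions, so decision support is the fallback,
#' not the first resort.
#'
#' @param records A `va_records` data.frame. Uses
#'   `medical_records_available`, `records_confident` (whether the records
#'   sufficed to certify; defaults to `medical_records_available` when the
#'   column is absent) and `narrative_confident`.
#' @return Character vector of pathways, one per record, in
#'   `c("RECORDS", "NARRATIVE", "FULL_VA")`.
#' @export
route_certification <- function(records) {
  mra <- records$medical_records_available
  rc <- records$records_confident %||% mra
  rc[is.na(rc)] <- FALSE
  nc <- records$narrative_confident %||% rep(FALSE, length(mra))
  nc[is.na(nc)] <- FALSE
  ifelse(mra & rc, "RECORDS", ifelse(nc, "NARRATIVE", "FULL_VA"))
}

#' Record a certification outcome
#'
#' Combines the pathway, the (FULL_VA-only) decision report and the
#' physician's certified cause into the weekly-export row shape:
#' `used_tool_diagnosis` is true when the physician's cause appears
#' anywhere in the report's top 3, `agreement_top1` when it equals the top
#' cause; both are false for undetermined reports and non-FULL_VA pathways.
#'
#' @param pathway `"RECORDS"`, `"NARRATIVE"` or `"FULL_VA"`.
#' @param report A `va_report`, required iff `pathway == "FULL_VA"`.
#' @param physician_cause Non-empty cause string (free entry allowed, e.g. a
#'   refined cancer site).
#' @param true_cause Optional true cause (synthetic cohorts), carried
#'   through for evaluation.
#' @param death_id Optional death id; defaults to the report's (`NA` on
#'   pathways without a report).
#' @return One-row data.frame with columns `death_id`, `pathway`,
#'   `cause_1..cause_3`, `likelihood_1..likelihood_3`, `undetermined`,
#'   `physician_cause`, `used_tool_diagnosis`, `agreement_top1`
#'   (and `true_cause` if given).
#' @export
record_certification <- function(pathway, report = NULL, physician_cause,
                                 true_cause = NA_character_,
                                 death_id = NULL) {
  pathway <- match.arg(pathway, c("RECORDS", "NARRATIVE", "FULL_VA"))
  if (missing(physician_cause) || is.na(physician_cause) ||
      !nzchar(physician_cause)) {
    stop("physician cause must be provided", call. = FALSE)
  }
  if (pathway == "FULL_VA" && is.null(report)) {
    stop("a decision report is required on the FULL_VA pathway",
         call. = FALSE)
  }
  if (pathway != "FULL_VA" && !is.null(report)) {
    stop("a decision report must not be supplied on the ", pathway,
         " pathway", call. = FALSE)
  }
  top <- if (is.null(report)) character(0) else report$ranked_causes$cause
  lik <- if (is.null(report)) character(0) else
    report$ranked_causes$likelihood
  pad <- function(v) c(v, rep(NA_character_, 3L - length(v)))[1:3]
  undet <- !is.null(report) && report$undetermined
  data.frame(
    death_id = death_id %||%
      (if (is.null(report)) NA_character_ else report$death_id),
    pathway = pathway,
    cause_1 = pad(top)[1], cause_2 = pad(top)[2], cause_3 = pad(top)[3],
    likelihood_1 = pad(lik)[1], likelihood_2 = pad(lik)[2],
    likelihood_3 = pad(lik)[3],
    undetermined = undet,
    physician_cause = physician_cause,
    used_tool_diagnosis = !undet && physician_cause %in% top,
    agreement_top1 = !undet && length(top) > 0 && physician_cause == top[1],
    true_cause = true_cause,
    stringsAsFactors = FALSE)
}
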