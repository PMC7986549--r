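# Tariff engine: endorsement rates -> tariff matrix -> scores -> percentile
# ranks against a resampled training reference.

#' Training library of gold-standard deaths
#'
#' Bundles deaths with a known true cause and binary symptom endorsements,
#' the raw material from which tariffs are derived. Missing endorsements are
#' treated as not endorsed (0) on load, matching the binary checkbox
#' semantics of the instrument.
#'
#' @param death_id Character vector of unique ids.
#' @param cause Character vector of true cause ids, parallel to `death_id`.
#' @param endorsements Numeric 0/1 matrix, one row per death, columns named
#'   by symptom id; `NA` entries are coerced to 0.
#' @param module_id Questionnaire module the library belongs to.
#' @return An object of class `va_training`.
#' @export
va_training <- function(death_id, cause, endorsements, module_id = "adult") {
  endorsements <- as.matrix(endorsements)
  if (length(death_id) != length(cause) ||
      length(cause) != nrow(endorsements)) {
    stop("death_id, cause and endorsement rows must align", call. = FALSE)
  }
  if (length(death_id) == 0L) stop("training library is empty", call. = FALSE)
  if (is.null(colnames(endorsements))) {
    stop("endorsement matrix must have symptom column names", call. = FALSE)
  }
  endorsements[is.na(endorsements)] <- 0
  if (!all(endorsements %in% c(0, 1))) {
    stop("endorsements must be binary", call. = FALSE)
  }
  storage.mode(endorsements) <- "double"
  structure(list(death_id = as.character(death_id),
                 cause = as.character(cause),
                 endorsements = endorsements,
                 module_id = module_id),
            class = "va_training")
}

#' @export
print.va_training <- function(x, ...) {
  cat("VA training library:", length(x$death_id), "deaths,",
      length(unique(x$cause)), "causes,", ncol(x$endorsements), "symptoms (",
      x$module_id, "module )\n")
  invisible(x)
}

#' Read a training library from CSV
#'
#' Expects columns `death_id`, `cause`, and one 0/1 column per symptom in
#' the schema; blanks are treated as not endorsed.
#'
#' @param source CSV path or data.frame.
#' @param schema A [va_schema()].
#' @return A [va_training()] object.
#' @export
read_training_csv <- function(source, schema) {
  df <- if (is.data.frame(source)) source else
    utils::read.csv(source, check.names = FALSE)
  for (col in c("death_id", "cause")) {
    if (!col %in% names(df)) {
      stop("training file is missing required column: ", col, call. = FALSE)
    }
  }
  symptoms <- intersect(schema$symptoms, names(df))
  m <- as.matrix(df[symptoms])
  storage.mode(m) <- "double"
  va_training(df$death_id, df$cause, m, module_id = schema$module_id)
}

#' Endorsement-rate matrix
#'
#' `x[i, j]` is the fraction of training deaths of cause `j` that endorsed
#' symptom `i` -- the empirical conditional endorsement probability the
#' tariff transform is built on.
#'
#' @param training A [va_training()] library.
#' @param causes A [va_cause_list()]; every cause must have at least one
#'   training death.
#' @param schema Optional [va_schema()] fixing symptom order; defaults to
#'   the training matrix's columns.
#' @return Numeric matrix, symptoms x causes, entries in \[0, 1\].
#' @export
compute_endorsement_matrix <- function(training, causes, schema = NULL) {
  stopifnot(inherits(training, "va_training"),
            inherits(causes, "va_cause_list"))
  symptoms <- if (is.null(schema)) colnames(training$endorsements) else
    schema$symptoms
  missing_sym <- setdiff(symptoms, colnames(training$endorsements))
  if (length(missing_sym)) {
    stop("training library lacks symptom column(s): ",
         paste(missing_sym, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(causes$causes, training$cause)
  if (length(absent)) {
    stop("cause(s) with zero training deaths: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  x <- vapply(causes$causes, function(j) {
    colMeans(training$endorsements[training$cause == j, symptoms,
                                   drop = FALSE])
  }, numeric(length(symptoms)))
  matrix(x, nrow = length(symptoms),
         dimnames = list(symptoms, causes$causes))
}

# Round half away from zero at the given granularity; granularity 0 or NULL
# disables rounding.
round_to_granularity <- function(v, granularity) {
  if (is.null(granularity) || granularity <= 0) return(v)
  sign(v) * floor(abs(v) / granularity + 0.5) * granularity
}

#' Tariff matrix from endorsement rates
#'
#' A tariff measures how distinctively a symptom's endorsement rate for one
#' cause departs from its rate across all causes, as a robust z-score:
#' `t[i, j] = (x[i, j] - median_j'(x[i, j'])) / max(IQR_j'(x[i, j']), iqr_floor)`,
#' with quantiles computed by linear interpolation between order statistics
#' (type 7). Tariffs are then rounded to `granularity` (half away from
#' zero), and optionally truncated per cause to the `truncate_k` largest
#' absolute tariffs, zeroing the rest, so each cause is driven by its most
#' discriminating symptoms. A symptom endorsed at the same rate by every
#' cause carries no signal and gets tariff 0 throughout.
#'
#' @param x Endorsement matrix from [compute_endorsement_matrix()].
#' @param granularity Rounding step; default 0.5. `0` disables rounding.
#' @param iqr_floor Lower bound on the IQR to avoid division by zero;
#'   default 0.001.
#' @param truncate_k Per-cause truncation; `NULL` (default here) keeps all
#'   tariffs.
#' @return Numeric tariff matrix, symptoms x causes.
#' @export
compute_tariff_matrix <- function(x, granularity = 0.5, iqr_floor = 0.001,
                                  truncate_k = NULL) {
  x <- as.matrix(x)
  t_raw <- t(apply(x, 1L, function(row) {
    med <- stats::median(row)
    q <- stats::quantile(row, c(0.25, 0.75), type = 7, names = FALSE)
    (row - med) / max(q[2] - q[1], iqr_floor)
  }))
  dimnames(t_raw) <- dimnames(x)
  tm <- round_to_granularity(t_raw, granularity)
  if (!is.null(truncate_k) && truncate_k < nrow(tm)) {
    for (j in seq_len(ncol(tm))) {
      # ties broken by symptom order for a deterministic truncation
      keep <- order(-abs(tm[, j]), seq_len(nrow(tm)))[seq_len(truncate_k)]
      tm[-keep, j] <- 0
    }
  }
  tm
}

#' Tariff scores for one or more deaths
#'
#' The score of a death for cause `j` is the sum of the tariffs of its
#' endorsed symptoms: missing and non-endorsed symptoms contribute nothing,
#' so scoring is additive over disjoint endorsement sets.
#'
#' @param endorsements Named 0/1 vector for one death, or a matrix / record
#'   data.frame with one row per death; `NA` counts as not endorsed.
#' @param tariff Tariff matrix (symptoms x causes).
#' @return Named numeric vector of per-cause scores (one death) or a matrix
#'   (deaths x causes).
#' @export
score_deaths <- function(endorsements, tariff) {
  single <- is.null(dim(endorsements))
  e <- endorsement_matrix_of(endorsements, rownames(tariff))
  s <- e %*% tariff
  if (single) s[1L, ] else s
}

# Coerce records / vectors to a deaths x symptoms 0/1 matrix aligned to the
# tariff's symptom rows; NA -> 0.
endorsement_matrix_of <- function(endorsements, symptoms) {
  if (is.null(dim(endorsements))) {
    endorsements <- matrix(endorsements, nrow = 1L,
                           dimnames = list(NULL, names(endorsements)))
  }
  if (is.data.frame(endorsements)) {
    cols <- intersect(symptoms, names(endorsements))
    m <- as.matrix(as.data.frame(endorsements)[cols])
  } else {
    cols <- intersect(symptoms, colnames(endorsements))
    m <- endorsements[, cols, drop = FALSE]
  }
  missing_sym <- setdiff(symptoms, cols)
  if (length(missing_sym)) {
    m <- cbind(m, matrix(0, nrow(m), length(missing_sym),
                         dimnames = list(NULL, missing_sym)))
  }
  m <- m[, symptoms, drop = FALSE]
  storage.mode(m) <- "double"
  m[is.na(m)] <- 0
  m
}

#' Resampled per-cause rank reference
#'
#' For each cause, draws `per_cause_n` training deaths of that cause with
#' replacement, scores each against that cause, and stores the sorted
#' scores. Resampling to a common size equalises cause prevalence in the
#' reference, so percentile ranks are comparable across causes regardless of
#' how many training deaths each cause has.
#'
#' PRNG contract: `set.seed(seed)` is called once (R's default Mersenne
#' Twister with the current default `sample.kind`), then causes are
#' processed in cause-list order and the indices for cause `j` are drawn as
#' `sample.int(n_j, per_cause_n, replace = TRUE)`. An independent
#' implementation replaying that stream reproduces the reference exactly.
#'
#' @param training A [va_training()] library.
#' @param tariff Tariff matrix.
#' @param per_cause_n Resample size per cause (default 100).
#' @param seed Integer seed.
#' @return An object of class `va_rank_reference`: a list with `scores`
#'   (per-cause sorted numeric vectors), `per_cause_n` and `seed`.
#' @export
build_rank_reference <- function(training, tariff, per_cause_n = 100,
                                 seed = 1L) {
  stopifnot(inherits(training, "va_training"))
  if (per_cause_n < 1) stop("per_cause_n must be >= 1", call. = FALSE)
  causes <- colnames(tariff)
  all_scores <- score_deaths(training$endorsements, tariff)
  set.seed(seed)
  ref <- lapply(causes, function(j) {
    rows <- which(training$cause == j)
    if (!length(rows)) {
      stop("no training deaths for cause ", j, call. = FALSE)
    }
    idx <- sample.int(length(rows), per_cause_n, replace = TRUE)
    sort(all_scores[rows[idx], j])
  })
  names(ref) <- causes
  structure(list(scores = ref, per_cause_n = as.integer(per_cause_n),
                 seed = as.integer(seed)),
            class = "va_rank_reference")
}

#' Percentile rank of a score against a cause's reference
#'
#' Mid-rank convention: `(# reference scores strictly below + 0.5 x # equal)
#' / reference size`, giving a value in \[0, 1\] that is non-decreasing in
#' the score.
#'
#' @param score Numeric score(s).
#' @param cause Cause id present in the reference.
#' @param ref A [build_rank_reference()] object.
#' @return Numeric vector of ranks in \[0, 1\].
#' @export
percentile_rank <- function(score, cause, ref) {
  stopifnot(inherits(ref, "va_rank_reference"))
  r <- ref$scores[[cause]]
  if (is.null(r)) stop("unknown cause: ", cause, call. = FALSE)
  vapply(score, function(s) (sum(r < s) + 0.5 * sum(r == s)) / length(r),
         numeric(1))
}

#' Fit a tariff cause-of-death model
#'
#' The central estimator: derives the endorsement matrix and tariff matrix
#' from a gold-standard training library and builds the resampled rank
#' reference used to convert field scores into percentile ranks. The fitted
#' object is the engine behind [predict.va_tariff()] decision reports.
#'
#' @param training A [va_training()] library.
#' @param causes A [va_cause_list()].
#' @param schema Optional [va_schema()] fixing symptom order.
#' @param granularity Tariff rounding step (default 0.5).
#' @param iqr_floor IQR floor in the tariff denominator (default 0.001).
#' @param truncate_k Keep the `truncate_k` largest-absolute tariffs per
#'   cause, zeroing the rest (default 40; `NULL` disables).
#' @param ref_size Rank-reference resample size per cause (default 100).
#' @param seed Seed for the rank-reference resampling.
#' @return An object of class `va_tariff` with components `endorsement`,
#'   `tariff`, `ref`, `causes`, `schema`, `module_id` and `options`.
#' @examples
#' prof <- generate_cause_profiles(3, 9, sharpness = 1, seed = 1)
#' train <- generate_training_library(prof, deaths_per_cause = 20, seed = 2)
#' fit <- va_tariff(train, va_cause_list(prof$causes))
#' coef(fit)[1:3, ]
#' @export
va_tariff <- function(training, causes, schema = NULL,
                      granularity = 0.5, iqr_floor = 0.001, truncate_k = 40,
                      ref_size = 100, seed = 1L) {
  x <- compute_endorsement_matrix(training, causes, schema)
  tm <- compute_tariff_matrix(x, granularity = granularity,
                              iqr_floor = iqr_floor, truncate_k = truncate_k)
  ref <- build_rank_reference(training, tm, per_cause_n = ref_size,
                              seed = seed)
  structure(list(endorsement = x, tariff = tm, ref = ref,
                 causes = causes,
                 schema = schema,
                 module_id = training$module_id,
                 n_training = length(training$death_id),
                 options = list(granularity = granularity,
                                iqr_floor = iqr_floor,
                                truncate_k = truncate_k,
                                ref_size = ref_size, seed = seed),
                 call = match.call()),
            class = "va_tariff")
}

#' @export
print.va_tariff <- function(x, ...) {
  cat("Tariff verbal-autopsy model (", x$module_id, " module)\n", sep = "")
  cat("  causes:  ", ncol(x$tariff), "\n", sep = "")
  cat("  symptoms:", nrow(x$tariff), "\n")
  cat("  training deaths:", x$n_training, "\n")
  cat("  rank reference: ", x$options$ref_size, " resamples/cause (seed ",
      x$options$seed, ")\n", sep = "")
  invisible(x)
}

#' @export
#' @method coef va_tariff
coef.va_tariff <- function(object, ...) object$tariff

#' @export
summary.va_tariff <- function(object, top = 3L, ...) {
  tm <- object$tariff
  top_sym <- lapply(colnames(tm), function(j) {
    o <- order(-tm[, j], seq_len(nrow(tm)))[seq_len(min(top, nrow(tm)))]
    data.frame(cause = j, symptom = rownames(tm)[o], tariff = tm[o, j],
               stringsAsFactors = FALSE)
  })
  structure(list(model = object, top_symptoms = do.call(rbind, top_sym)),
            class = "summary.va_tariff")
}

#' @export
print.summary.va_tariff <- function(x, ...) {
  print(x$model)
  cat("\nMost indicative symptoms per cause (largest tariffs):\n")
  print(x$top_symptoms, row.names = FALSE)
  invisible(x)
}

#' Heatmap of the tariff matrix
#'
#' @param x A `va_tariff` model.
#' @param ... Passed to [graphics::image()].
#' @export
plot.va_tariff <- function(x, ...) {
  tm <- x$tariff
  graphics::image(seq_len(nrow(tm)), seq_len(ncol(tm)), tm,
                  xlab = "symptom", ylab = "cause", axes = FALSE,
                  main = "Tariff matrix", ...)
  graphics::axis(1, at = seq_len(nrow(tm)), labels = rownames(tm), las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, at = seq_len(ncol(tm)), labels = colnames(tm), las = 1,
                 cex.axis = 0.7)
  invisible(x)
}

#' Predict causes for field deaths
#'
#' @param object A fitted [va_tariff()] model.
#' @param newdata A `va_records` data.frame, an endorsement matrix, or a
#'   single named 0/1 vector.
#' @param type `"score"` for raw tariff scores, `"rank"` for percentile
#'   ranks, `"report"` for full physician-facing decision reports (see
#'   [build_decision_report()]), or `"top1"` for the unthresholded
#'   top-scoring cause per death (population-level assignment, no
#'   abstention; ties broken by rank then cause id).
#' @param thresholds,bins,restrictions Decision configuration for
#'   `type = "report"`; see [va_thresholds()], [va_likelihood_bins()],
#'   [restriction_table()].
#' @param ... Unused.
#' @return A matrix (score/rank), character vector (top1), or a
#'   `va_reports` list of decision reports.
#' @export
predict.va_tariff <- function(object, newdata,
                              type = c("report", "score", "rank", "top1"),
                              thresholds = va_thresholds(),
                              bins = va_likelihood_bins(),
                              restrictions = NULL, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "va_records") &&
      !is.null(attr(newdata, "module_id")) &&
      attr(newdata, "module_id") != object$module_id) {
    stop("record module '", attr(newdata, "module_id"),
         "' does not match model module '", object$module_id, "'",
         call. = FALSE)
  }
  scores <- score_deaths(newdata, object$tariff)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L,
                                             dimnames = list(NULL, names(scores)))
  if (type == "score") return(scores)
  ranks <- scores
  for (j in colnames(scores)) {
    ranks[, j] <- percentile_rank(scores[, j], j, object$ref)
  }
  if (type == "rank") return(ranks)
  if (type == "top1") {
    return(vapply(seq_len(nrow(scores)), function(i) {
      o <- order(-scores[i, ], -ranks[i, ], colnames(scores))
      colnames(scores)[o[1L]]
    }, character(1)))
  }
  records <- if (is.data.frame(newdata)) newdata else NULL
  reports <- lapply(seq_len(nrow(scores)), function(i) {
    rec <- if (is.null(records)) NULL else records[i, ]
    decision_report_from_scores(scores[i, ], ranks[i, ], rec, object,
                                thresholds, bins, restrictions)
  })
  class(reports) <- "va_reports"
  reports
}

#' Simulate deaths from a fitted tariff model
#'
#' Draws synthetic deaths whose endorsements follow the model's empirical
#' cause-conditional endorsement rates, with true causes drawn from `csmf`
#' (uniform by default) -- a parametric-bootstrap style generator useful for
#' sensitivity checks on a fitted engine.
#'
#' @param object A `va_tariff` model.
#' @param nsim Number of deaths.
#' @param seed Integer seed.
#' @param csmf Named cause-fraction vector over the model's causes.
#' @param ... Unused.
#' @return A `va_records` data.frame with `true_cause` set.
#' @export
#' @method simulate va_tariff
simulate.va_tariff <- function(object, nsim = 1, seed = NULL, csmf = NULL,
                               ...) {
  profiles <- structure(list(causes = colnames(object$endorsement),
                             symptoms = rownames(object$endorsement),
                             prob = object$endorsement),
                        class = "va_cause_profiles")
  if (is.null(csmf)) {
    csmf <- stats::setNames(rep(1 / ncol(object$endorsement),
                                ncol(object$endorsement)),
                            colnames(object$endorsement))
  }
  generate_field_cohort(profiles, true_csmf = csmf, n = nsim,
                        seed = seed %||% 1L)
}
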