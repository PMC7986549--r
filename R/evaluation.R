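# Evaluation surface: CSMF tables, usage/agreement statistics,
# reclassification matrices, ill-defined fractions, category mapping and
# CSMF accuracy.

#' Cause-specific mortality fractions
#'
#' Tabulates cause assignments into a normalised fraction table. Missing
#' assignments (and the engine's abstentions) are counted under an explicit
#' `undetermined` entry rather than dropped: for mortality statistics the
#' undetermined share is itself a headline quantity.
#'
#' @param assignments Character vector of cause ids, one per death; `NA`
#'   counts as `undetermined_label`.
#' @param causes Optional [va_cause_list()]; listed causes appear in the
#'   table (with fraction 0 if unobserved) in list order.
#' @param undetermined_label Label for abstentions (default
#'   `"undetermined"`).
#' @return An object of class `va_csmf`: a named numeric vector of
#'   fractions summing to 1, with attribute `n` (total deaths).
#' @export
compute_csmf <- function(assignments, causes = NULL,
                         undetermined_label = "undetermined") {
  if (length(assignments) == 0L) {
    stop("cannot compute a CSMF from zero deaths", call. = FALSE)
  }
  assignments <- as.character(assignments)
  assignments[is.na(assignments)] <- undetermined_label
  universe <- unique(c(if (!is.null(causes)) causes$causes,
                       unique(assignments)))
  counts <- table(factor(assignments, levels = universe))
  frac <- as.numeric(counts) / length(assignments)
  structure(stats::setNames(frac, universe), n = length(assignments),
            class = "va_csmf")
}

#' @export
print.va_csmf <- function(x, digits = 3, ...) {
  cat("CSMF over", length(x), "causes, n =", attr(x, "n"), "deaths\n")
  v <- sort(unclass(x), decreasing = TRUE)
  for (nm in names(v)) {
    cat(sprintf("  %-28s %5.1f%%\n", nm, 100 * v[[nm]]))
  }
  invisible(x)
}

#' Tool-usage and agreement statistics
#'
#' Summarises a cohort of certification outcomes: how often the full
#' verbal autopsy with decision support was used at all
#' (`usage_fraction`), and -- among those FULL_VA deaths -- how often the
#' physician certified one of the tool's top-3 causes
#' (`used_tool_fraction`) and its top-1 cause exactly
#' (`agreement_top1_fraction`). Whether "used the tool's diagnosis" means
#' top-1 or any-of-top-3 is ambiguous in routine reporting, so both are
#' always computed. Rounded integer percentages accompany the exact
#' fractions (printed reports round; machine output keeps full precision).
#'
#' @param outcomes Data.frame of [record_certification()] rows.
#' @return An object of class `va_agreement`: a list with `n_total`,
#'   `n_full_va`, `usage_fraction`, `used_tool_fraction`,
#'   `agreement_top1_fraction`, `n_disagreements` (FULL_VA deaths whose
#'   physician cause differs from top-1) and `percent` (rounded
#'   percentages).
#' @export
agreement_stats <- function(outcomes) {
  if (nrow(outcomes) == 0L) {
    stop("cannot summarise zero outcomes", call. = FALSE)
  }
  full <- outcomes[outcomes$pathway == "FULL_VA", , drop = FALSE]
  n_total <- nrow(outcomes)
  n_full <- nrow(full)
  used <- sum(full$used_tool_diagnosis)
  top1 <- sum(full$agreement_top1)
  res <- list(
    n_total = n_total,
    n_full_va = n_full,
    usage_fraction = n_full / n_total,
    used_tool_fraction = if (n_full) used / n_full else NA_real_,
    agreement_top1_fraction = if (n_full) top1 / n_full else NA_real_,
    n_disagreements = n_full - top1)
  res$percent <- lapply(res[c("usage_fraction", "used_tool_fraction",
                              "agreement_top1_fraction")],
                        function(f) round(100 * f))
  structure(res, class = "va_agreement")
}

#' @export
print.va_agreement <- function(x, ...) {
  cat("Certification summary over", x$n_total, "deaths\n")
  cat(sprintf("  full VA with decision support: %d (%d%%)\n",
              x$n_full_va, x$percent$usage_fraction))
  cat(sprintf("  physician used a top-3 cause:  %d%% of FULL_VA deaths\n",
              x$percent$used_tool_fraction))
  cat(sprintf("  physician used the top-1 cause: %d%% of FULL_VA deaths\n",
              x$percent$agreement_top1_fraction))
  cat(sprintf("  disagreements with top-1:      %d\n", x$n_disagreements))
  invisible(x)
}

#' Reclassification matrix: algorithm top-1 vs physician cause
#'
#' Cross-tabulates the algorithm's top-1 cause against the physician's
#' certified cause over FULL_VA deaths with a determinate report,
#' optionally restricted to disagreements -- the deaths where the physician
#' overrode the top-1 suggestion. Row percentages show, for each algorithm
#' cause, where those deaths were reclassified to.
#'
#' @param outcomes Data.frame of certification outcomes.
#' @param restrict_to_disagreements If `TRUE` (default), keep only rows
#'   with `agreement_top1 == FALSE`.
#' @return An object of class `va_reclassification`: list with `counts`
#'   (matrix, algorithm cause x physician cause), `row_percent`, and `n`.
#' @export
reclassification_matrix <- function(outcomes,
                                    restrict_to_disagreements = TRUE) {
  keep <- outcomes$pathway == "FULL_VA" & !outcomes$undetermined &
    !is.na(outcomes$cause_1)
  if (restrict_to_disagreements) keep <- keep & !outcomes$agreement_top1
  sub <- outcomes[keep, , drop = FALSE]
  counts <- if (nrow(sub)) {
    as.matrix(table(algorithm = sub$cause_1, physician = sub$physician_cause))
  } else {
    matrix(0L, 0L, 0L)
  }
  rp <- counts
  if (nrow(counts)) {
    rs <- rowSums(counts)
    rp <- sweep(counts, 1L, pmax(rs, 1L), "/") * 100
    rp[rs == 0L, ] <- NA_real_
  }
  structure(list(counts = counts, row_percent = rp, n = nrow(sub)),
            class = "va_reclassification")
}

#' @export
print.va_reclassification <- function(x, ...) {
  cat("Reclassification matrix over", x$n, "deaths\n")
  if (x$n) print(round(x$row_percent, 1))
  invisible(x)
}

#' Fraction of ill-defined causes
#'
#' The share of certified causes that are unusable as an underlying cause
#' for policy: by default ICD-10 R99 (ill-defined), I46 (cardiac arrest)
#' and R54 (senility), plus the engine's undetermined label.
#'
#' @param causes Character vector of certified causes (free entry allowed).
#' @param ill_defined Ill-defined code set.
#' @param undetermined_label Abstention label, also counted.
#' @return Fraction in \[0, 1\]; 0 for an empty input.
#' @export
ill_defined_fraction <- function(causes,
                                 ill_defined = c("R99", "I46", "R54"),
                                 undetermined_label = "undetermined") {
  if (length(causes) == 0L) return(0)
  causes <- as.character(causes)
  mean(is.na(causes) | causes %in% c(ill_defined, undetermined_label))
}

#' Map causes to aggregate categories
#'
#' Collapses specific causes (including physician free-entry strings such
#' as refined cancer sites) into aggregate cause categories for
#' side-by-side tabulation with external sources; unmapped causes fall into
#' a residual category.
#'
#' @param causes Character vector of cause ids.
#' @param category_map Named character vector, cause -> category (e.g. from
#'   [va_cause_list()]`$category_map`).
#' @param residual Residual category label (default `"other"`).
#' @return Character vector of categories, same length as `causes`.
#' @export
map_cause_categories <- function(causes, category_map, residual = "other") {
  causes <- as.character(causes)
  out <- unname(category_map[causes])
  out[is.na(out)] <- residual
  out
}

#' CSMF accuracy
#'
#' The standard population-level recovery metric for verbal autopsy:
#' `1 - sum_j |true_j - est_j| / (2 (1 - min_j true_j))`. It is 1 iff the
#' two distributions are identical and 0 when the estimate puts all mass on
#' the cause with the smallest true fraction (the worst possible estimate).
#' The two tables are aligned on the union of their causes, absent causes
#' counting as 0.
#'
#' @param true_csmf,est_csmf `va_csmf` tables or named fraction vectors.
#' @return A number in \[0, 1\].
#' @export
csmf_accuracy <- function(true_csmf, est_csmf) {
  true_csmf <- unclass(true_csmf)
  est_csmf <- unclass(est_csmf)
  universe <- union(names(true_csmf), names(est_csmf))
  tr <- stats::setNames(rep(0, length(universe)), universe)
  es <- tr
  tr[names(true_csmf)] <- true_csmf
  es[names(est_csmf)] <- est_csmf
  if (any(tr == 1)) {  # degenerate single-cause truth
    if (isTRUE(all.equal(tr, es))) return(1)
    stop("CSMF accuracy undefined for a degenerate true distribution ",
         "unless the estimate matches it", call. = FALSE)
  }
  1 - sum(abs(tr - es)) / (2 * (1 - min(tr)))
}
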