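# Synthetic-data generators: cause-conditional endorsement profiles,
# training libraries, field cohorts with known truth, and simulated
# physician behaviour. All generators are bit-reproducible for a fixed seed
# (set.seed(seed) once at entry, draws in documented order).

#' Cause-conditional symptom endorsement profiles
#'
#' Each cause receives a signature subset of `signature_size` symptoms
#' endorsed with probability `0.5 + 0.5 * sharpness`; all other symptoms are
#' background, endorsed with probability `0.5 * (1 - sharpness)`. At
#' `sharpness = 1` the profiles are perfectly separable (signature 1,
#' background 0); at `sharpness = 0` every symptom is an uninformative coin
#' flip. Signatures are disjoint consecutive blocks whenever
#' `n_symptoms >= n_causes * signature_size`; otherwise overlapping
#' signatures are drawn at random (seeded) and a message notes the overlap.
#'
#' @param n_causes Number of causes (>= 2).
#' @param n_symptoms Number of symptoms (>= `n_causes`).
#' @param sharpness Profile separability in \[0, 1\].
#' @param seed Integer seed (only consumed when signatures must overlap).
#' @param signature_size Signature symptoms per cause (default 3).
#' @return An object of class `va_cause_profiles`: `causes`, `symptoms`,
#'   `prob` (symptoms x causes probability matrix), `signatures`.
#' @export
generate_cause_profiles <- function(n_causes, n_symptoms, sharpness,
                                    seed = 1L, signature_size = 3L) {
  if (n_causes < 2) stop("need at least 2 causes", call. = FALSE)
  if (n_symptoms < n_causes) {
    stop("need at least as many symptoms as causes", call. = FALSE)
  }
  if (sharpness < 0 || sharpness > 1) {
    stop("sharpness must lie in [0, 1]", call. = FALSE)
  }
  signature_size <- max(1L, as.integer(signature_size))
  causes <- sprintf("C%02d", seq_len(n_causes))
  symptoms <- sprintf("S%02d", seq_len(n_symptoms))
  p_sig <- 0.5 + 0.5 * sharpness
  p_bg <- 0.5 * (1 - sharpness)
  if (n_symptoms >= n_causes * signature_size) {
    sig <- lapply(seq_len(n_causes), function(j) {
      symptoms[((j - 1L) * signature_size + 1L):(j * signature_size)]
    })
  } else {
    set.seed(seed)
    sig <- lapply(seq_len(n_causes), function(j) {
      sample(symptoms, signature_size)
    })
    message("signature subsets overlap: n_symptoms < n_causes * ",
            "signature_size")
  }
  names(sig) <- causes
  prob <- matrix(p_bg, n_symptoms, n_causes,
                 dimnames = list(symptoms, causes))
  for (j in causes) prob[sig[[j]], j] <- p_sig
  structure(list(causes = causes, symptoms = symptoms, prob = prob,
                 signatures = sig, sharpness = sharpness),
            class = "va_cause_profiles")
}

#' @export
print.va_cause_profiles <- function(x, ...) {
  cat("Synthetic cause profiles:", length(x$causes), "causes x",
      length(x$symptoms), "symptoms, sharpness",
      x$sharpness %||% NA, "\n")
  invisible(x)
}

#' Generate a gold-standard training library
#'
#' Draws `deaths_per_cause` deaths per cause, each endorsing every symptom
#' independently with its cause-conditional profile probability, so
#' empirical endorsement rates converge to the profiles as the library
#' grows.
#'
#' @param profiles A [generate_cause_profiles()] object.
#' @param deaths_per_cause Deaths per cause (>= 1).
#' @param seed Integer seed.
#' @param module_id Questionnaire module label (default `"adult"`).
#' @return A [va_training()] library.
#' @export
generate_training_library <- function(profiles, deaths_per_cause,
                                      seed = 1L, module_id = "adult") {
  stopifnot(inherits(profiles, "va_cause_profiles"))
  if (deaths_per_cause < 1) {
    stop("deaths_per_cause must be >= 1", call. = FALSE)
  }
  set.seed(seed)
  n_sym <- length(profiles$symptoms)
  blocks <- lapply(profiles$causes, function(j) {
    matrix(stats::rbinom(deaths_per_cause * n_sym, 1L,
                         rep(profiles$prob[, j], each = deaths_per_cause)),
           nrow = deaths_per_cause, ncol = n_sym,
           dimnames = list(NULL, profiles$symptoms))
  })
  endorsements <- do.call(rbind, blocks)
  cause <- rep(profiles$causes, each = deaths_per_cause)
  va_training(sprintf("T%05d", seq_along(cause)), cause, endorsements,
              module_id = module_id)
}

#' Generate a field cohort with known true causes
#'
#' Emulates a pilot cohort of out-of-facility adult deaths: true causes
#' drawn from a target CSMF, endorsements from the cause profiles, and the
#' pathway flags a certification SOP consumes. Demographic defaults are an
#' adult-module cohort (ages uniform on 20-90 years, 55% male). Pathway
#' defaults emulate a pilot where records exist for about a third of
#' deaths, records certify only a minority of those directly, and the open
#' narrative rarely suffices alone, so the full VA carries about four
#' deaths in five.
#'
#' Draw order (one `set.seed(seed)` at entry): true causes, endorsements
#' (death-major), ages, sexes, records-available, records-confident,
#' narrative-confident.
#'
#' @param profiles A [generate_cause_profiles()] object.
#' @param true_csmf Named fraction vector over `profiles$causes`, summing
#'   to 1.
#' @param n Cohort size (>= 1).
#' @param p_records_available Probability medical records exist (default
#'   0.334).
#' @param p_certify_from_records Probability that, given records, the
#'   physician certifies from them directly (default 0.31).
#' @param p_narrative_confident Probability the open narrative alone
#'   suffices (default 0.096).
#' @param seed Integer seed.
#' @param age_range Age bounds in years (default `c(20, 90)`).
#' @param p_male Probability of male sex (default 0.55).
#' @return A `va_records` data.frame with `true_cause` set.
#' @export
generate_field_cohort <- function(profiles, true_csmf, n,
                                  p_records_available = 0.334,
                                  p_certify_from_records = 0.31,
                                  p_narrative_confident = 0.096,
                                  seed = 1L,
                                  age_range = c(20, 90), p_male = 0.55) {
  stopifnot(inherits(profiles, "va_cause_profiles"))
  if (n < 1) stop("cohort size must be >= 1", call. = FALSE)
  true_csmf <- true_csmf[profiles$causes]
  if (anyNA(true_csmf) || abs(sum(true_csmf) - 1) > 1e-9 ||
      any(true_csmf < 0)) {
    stop("true_csmf must be a non-negative vector over the profile causes ",
         "summing to 1", call. = FALSE)
  }
  set.seed(seed)
  true_cause <- sample(profiles$causes, n, replace = TRUE, prob = true_csmf)
  p <- profiles$prob[, true_cause, drop = FALSE]  # symptoms x deaths
  endorsements <- matrix(stats::rbinom(length(p), 1L, as.vector(p)),
                         nrow = ncol(p), byrow = TRUE,
                         dimnames = list(NULL, profiles$symptoms))
  age <- stats::runif(n, age_range[1], age_range[2])
  sex <- ifelse(stats::runif(n) < p_male, "male", "female")
  mra <- stats::runif(n) < p_records_available
  rc <- mra & (stats::runif(n) < p_certify_from_records)
  nc <- stats::runif(n) < p_narrative_confident
  out <- data.frame(death_id = sprintf("D%05d", seq_len(n)),
                    age_value = age, age_unit = "years", sex = sex,
                    module_id = assign_age_module(age, "years"),
                    medical_records_available = mra,
                    records_confident = rc,
                    narrative_confident = nc,
                    respondent_is_family = TRUE,
                    true_cause = true_cause,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(endorsements))
  structure(out,
            parse_errors = data.frame(row = integer(), death_id = character(),
                                      message = character(),
                                      stringsAsFactors = FALSE),
            module_id = "adult",
            class = c("va_records", "data.frame"))
}

#' Physician behaviour parameters
#'
#' Governs the simulated certifying physician: accept the tool's top cause
#' with probability `p_accept_top1`; failing that, accept rank 2 or 3
#' (uniformly) with probability `p_accept_top23`; otherwise certify a cause
#' from the override distribution. An accepted cause is replaced by a
#' free-entry refinement of itself (e.g. a specific cancer site) with
#' probability `p_refine`. Undetermined reports always draw from the
#' override distribution: a certificate must carry some cause.
#'
#' @param p_accept_top1,p_accept_top23,p_refine Probabilities in \[0, 1\].
#' @param override Named probability vector over causes for overrides, or
#'   `NULL` for uniform over the report's scored causes.
#' @return An object of class `va_physician_behaviour`.
#' @export
physician_behaviour <- function(p_accept_top1 = 0.82,
                                p_accept_top23 = 0.17,
                                p_refine = 0.05,
                                override = NULL) {
  for (p in c(p_accept_top1, p_accept_top23, p_refine)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]",
                             call. = FALSE)
  }
  if (!is.null(override)) {
    if (is.null(names(override)) || any(override < 0) ||
        abs(sum(override) - 1) > 1e-9) {
      stop("override must be a named probability vector", call. = FALSE)
    }
  }
  structure(list(p_accept_top1 = p_accept_top1,
                 p_accept_top23 = p_accept_top23,
                 p_refine = p_refine, override = override),
            class = "va_physician_behaviour")
}

refine_label <- function(cause) paste0(cause, "_refined")

#' Simulate a physician's certified cause from a decision report
#'
#' @param reports A `va_report` or a `va_reports` list.
#' @param behaviour A [physician_behaviour()].
#' @param seed Integer seed (one `set.seed` call; reports processed in
#'   order, draws per report: accept-top1, accept-top23, rank choice,
#'   override, refine).
#' @return Character vector of certified causes (free-entry refinements are
#'   the accepted cause with the suffix `"_refined"`).
#' @export
simulate_physician <- function(reports, behaviour = physician_behaviour(),
                               seed = 1L) {
  stopifnot(inherits(behaviour, "va_physician_behaviour"))
  if (inherits(reports, "va_report")) reports <- list(reports)
  set.seed(seed)
  vapply(reports, function(r) {
    override_pool <- behaviour$override %||%
      stats::setNames(rep(1 / length(r$scores), length(r$scores)),
                      names(r$scores))
    draw_override <- function() {
      sample(names(override_pool), 1L, prob = override_pool)
    }
    top <- r$ranked_causes$cause
    choice <- if (r$undetermined) {
      draw_override()
    } else if (stats::runif(1) < behaviour$p_accept_top1) {
      top[1L]
    } else if (length(top) > 1L &&
               stats::runif(1) < behaviour$p_accept_top23) {
      top[sample(2:length(top), 1L)]
    } else {
      draw_override()
    }
    if (!r$undetermined && choice %in% top &&
        stats::runif(1) < behaviour$p_refine) {
      choice <- refine_label(choice)
    }
    choice
  }, character(1))
}

#' Run a cohort through the full certification pipeline
#'
#' Convenience wrapper tying the modules together for simulation studies:
#' routes every death through the SOP, builds decision reports for the
#' FULL_VA pathway, simulates the physician's certified cause (deaths on
#' the RECORDS and NARRATIVE pathways are certified as the true cause --
#' the external evidence supplied the diagnosis), and assembles the weekly
#' export table of certification outcomes.
#'
#' @param records A `va_records` cohort with `true_cause` set (see
#'   [generate_field_cohort()]).
#' @param model A fitted [va_tariff()] model.
#' @param behaviour A [physician_behaviour()].
#' @param thresholds,bins,restrictions Decision configuration.
#' @param seed Integer seed for the physician simulation.
#' @return A list with `outcomes` (data.frame, one row per death, weekly
#'   export columns) and `reports` (the FULL_VA `va_reports`, named by
#'   death id).
#' @export
simulate_certification <- function(records, model,
                                   behaviour = physician_behaviour(),
                                   thresholds = va_thresholds(),
                                   bins = va_likelihood_bins(),
                                   restrictions = NULL, seed = 1L) {
  pathway <- route_certification(records)
  full_idx <- which(pathway == "FULL_VA")
  reports <- predict(model, records[full_idx, , drop = FALSE],
                     type = "report", thresholds = thresholds, bins = bins,
                     restrictions = restrictions)
  names(reports) <- records$death_id[full_idx]
  phys_full <- simulate_physician(reports, behaviour, seed = seed)
  physician <- records$true_cause
  physician[full_idx] <- phys_full
  rows <- lapply(seq_len(nrow(records)), function(i) {
    rep_i <- if (pathway[i] == "FULL_VA") {
      reports[[match(i, full_idx)]]
    } else {
      NULL
    }
    record_certification(pathway[i], rep_i, physician[i],
                         true_cause = records$true_cause[i] %||%
                           NA_character_,
                         death_id = records$death_id[i])
  })
  outcomes <- do.call(rbind, rows)
  rownames(outcomes) <- NULL
  list(outcomes = outcomes, reports = reports)
}
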