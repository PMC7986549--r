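# Shared fixture: a small fitted model with distinguishable causes.
fit_toy_model <- function(seed = 42) {
  prof <- generate_cause_profiles(4, 12, sharpness = 0.9, seed = seed)
  train <- generate_training_library(prof, deaths_per_cause = 40, seed = seed)
  va_tariff(train, va_cause_list(prof$causes), truncate_k = NULL,
            seed = seed)
}

test_that("demographic restrictions censor causes rule by rule", {
  scores <- c(a = 3, b = 2, c = 1)
  rec <- data.frame(death_id = "d1", sex = "male", age_value = 40,
                    age_unit = "years")
  # empty table: everything stays eligible
  empty <- restriction_table(data.frame(cause = character(),
                                        sexes = character(),
                                        age_min_days = numeric(),
                                        age_max_days = numeric()))
  expect_true(all(apply_demographic_restrictions(scores, rec, empty)))

  tbl <- restriction_table(data.frame(
    cause = c("a", "b", "c"),
    sexes = c("female", "any", "any"),
    age_min_days = c(NA, 50 * 365.25, NA),
    age_max_days = c(NA, NA, 45 * 365.25)))
  elig <- apply_demographic_restrictions(scores, rec, tbl)
  # hand evaluation: a is female-only; b needs age >= 50y; c allows <= 45y
  expect_equal(elig, c(a = FALSE, b = FALSE, c = TRUE))

  rec$sex <- "female"; rec$age_value <- 60
  elig <- apply_demographic_restrictions(scores, rec, tbl)
  expect_equal(elig, c(a = TRUE, b = TRUE, c = FALSE))
})

test_that("threshold qualification sorts, tie-breaks and abstains", {
  th <- va_thresholds(min_score = 1, min_rank = 0.5)
  scores <- c(a = 5, b = 5, c = 3, d = 0.5, e = 4)
  ranks <- c(a = 0.7, b = 0.9, c = 0.4, d = 0.9, e = 0.8)
  # c fails rank, d fails score; b beats a on rank at equal score
  expect_equal(qualify_causes(scores, ranks, th), c("b", "a", "e"))

  # identical score and rank -> lexicographic
  scores2 <- c(zed = 2, ant = 2)
  ranks2 <- c(zed = 0.8, ant = 0.8)
  expect_equal(qualify_causes(scores2, ranks2, th), c("ant", "zed"))

  # nothing qualifies -> empty (undetermined)
  expect_equal(qualify_causes(c(a = -1), c(a = 0.9), th), character(0))
  # everything qualifies -> all, sorted by score
  expect_equal(qualify_causes(c(a = 1, b = 3), c(a = 1, b = 1),
                              va_thresholds(0, 0)), c("b", "a"))
})

test_that("raising either threshold never adds qualifying causes", {
  set.seed(99)
  for (rep_i in 1:20) {
    k <- sample(3:8, 1)
    scores <- setNames(round(rnorm(k, 0, 3), 1), paste0("c", seq_len(k)))
    ranks <- setNames(round(runif(k), 2), names(scores))
    q0 <- qualify_causes(scores, ranks, va_thresholds(0, 0))
    for (ms in c(0, 1, 2)) for (mr in c(0, 0.5, 0.9)) {
      q <- qualify_causes(scores, ranks, va_thresholds(ms, mr))
      expect_true(all(q %in% q0))
      q_hi <- qualify_causes(scores, ranks, va_thresholds(ms + 1, mr))
      expect_true(all(q_hi %in% q))
      q_hr <- qualify_causes(scores, ranks,
                             va_thresholds(ms, min(mr + 0.3, 1)))
      expect_true(all(q_hr %in% q))
    }
  }
})

test_that("likelihood categories follow the bins and are monotone", {
  bins <- va_likelihood_bins()
  expect_equal(assign_likelihood(1.0, bins), "very likely")
  expect_equal(assign_likelihood(0.51, bins), "possible")
  expect_equal(assign_likelihood(0.50, bins), "possible")
  expect_equal(assign_likelihood(0.85, bins), "likely")
  expect_error(assign_likelihood(0.4, bins), "outside the qualifying range")

  grid <- seq(0.5, 1, by = 0.01)
  lv <- match(assign_likelihood(grid, bins), bins$labels)
  expect_true(all(diff(lv) >= 0))

  expect_error(va_likelihood_bins(edges = c(0.5, 0.5, 1),
                                  labels = c("a", "b")), "increasing")
})

test_that("decision reports compose the component behaviour", {
  fit <- fit_toy_model()
  prof <- generate_cause_profiles(4, 12, sharpness = 0.9, seed = 42)
  cohort <- generate_field_cohort(prof, setNames(rep(0.25, 4), prof$causes),
                                  n = 10, seed = 7)
  rec <- cohort[1, ]
  rep1 <- build_decision_report(rec, fit)

  # report equals the composition of the component operations
  scores <- score_deaths(rec, fit$tariff)[1, ]
  ranks <- vapply(names(scores),
                  function(j) percentile_rank(scores[[j]], j, fit$ref),
                  numeric(1))
  qual <- qualify_causes(scores, ranks, va_thresholds())
  expect_equal(rep1$ranked_causes$cause, head(qual, 3))
  if (nrow(rep1$ranked_causes)) {
    expect_equal(rep1$ranked_causes$likelihood,
                 assign_likelihood(ranks[head(qual, 3)],
                                   va_likelihood_bins()))
    # sorted by score descending
    expect_true(all(diff(rep1$ranked_causes$score) <= 0))
  }
  expect_equal(rep1$undetermined, length(qual) == 0)

  # endorsed symptoms listed in schema order
  symptom_cols <- prof$symptoms
  vals <- unlist(rec[symptom_cols])
  expect_equal(rep1$endorsed_symptoms,
               symptom_cols[!is.na(vals) & vals == 1])

  # at most three causes even when four qualify
  rep_all <- build_decision_report(rec, fit,
                                   thresholds = va_thresholds(-Inf, 0))
  expect_equal(nrow(rep_all$ranked_causes), 3L)

  # zero endorsements with a positive score floor -> undetermined, empty list
  blank <- rec
  blank[symptom_cols] <- 0L
  rep0 <- build_decision_report(blank, fit,
                                thresholds = va_thresholds(min_score = 0.5))
  expect_true(rep0$undetermined)
  expect_equal(rep0$endorsed_symptoms, character(0))
  expect_equal(nrow(rep0$ranked_causes), 0L)
})

test_that("SOP routing picks exactly one pathway and partitions a cohort", {
  rec <- function(mra, rc, nc) {
    data.frame(medical_records_available = mra, records_confident = rc,
               narrative_confident = nc)
  }
  expect_equal(route_certification(rec(TRUE, TRUE, FALSE)), "RECORDS")
  expect_equal(route_certification(rec(FALSE, FALSE, TRUE)), "NARRATIVE")
  expect_equal(route_certification(rec(FALSE, FALSE, FALSE)), "FULL_VA")
  # records available but insufficient: fall through to the narrative/VA
  expect_equal(route_certification(rec(TRUE, FALSE, TRUE)), "NARRATIVE")
  expect_equal(route_certification(rec(TRUE, FALSE, FALSE)), "FULL_VA")

  # records_confident defaults to availability when the flag is absent
  expect_equal(route_certification(
    data.frame(medical_records_available = TRUE,
               narrative_confident = FALSE)), "RECORDS")

  set.seed(4)
  cohort <- rec(runif(200) < 0.3, runif(200) < 0.5, runif(200) < 0.2)
  pw <- route_certification(cohort)
  expect_equal(length(pw), 200)
  expect_equal(sum(pw == "RECORDS") + sum(pw == "NARRATIVE") +
                 sum(pw == "FULL_VA"), 200)
})

test_that("certification outcomes capture tool use and agreement", {
  fit <- fit_toy_model()
  prof <- generate_cause_profiles(4, 12, sharpness = 0.9, seed = 42)
  cohort <- generate_field_cohort(prof, setNames(rep(0.25, 4), prof$causes),
                                  n = 5, seed = 3)
  rep1 <- build_decision_report(cohort[1, ], fit,
                                thresholds = va_thresholds(-Inf, 0))
  top <- rep1$ranked_causes$cause

  out <- record_certification("FULL_VA", rep1, top[1])
  expect_true(out$used_tool_diagnosis)
  expect_true(out$agreement_top1)

  out2 <- record_certification("FULL_VA", rep1, top[2])
  expect_true(out2$used_tool_diagnosis)
  expect_false(out2$agreement_top1)

  # free-entry refinement outside the top 3
  out3 <- record_certification("FULL_VA", rep1, "nasopharyngeal cancer")
  expect_false(out3$used_tool_diagnosis)
  expect_false(out3$agreement_top1)

  # undetermined report: outcome retained, tool never credited
  undet <- build_decision_report(cohort[2, ], fit,
                                 thresholds = va_thresholds(Inf, 1))
  out4 <- record_certification("FULL_VA", undet, "stroke")
  expect_true(out4$undetermined)
  expect_false(out4$used_tool_diagnosis)

  expect_error(record_certification("FULL_VA", NULL, "stroke"),
               "report is required")
  expect_error(record_certification("RECORDS", rep1, "stroke"),
               "must not be supplied")
  expect_error(record_certification("RECORDS", NULL, ""),
               "physician cause")
})
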