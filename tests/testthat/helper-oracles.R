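# Independent brute-force oracles and tiny fixture builders. The oracles
# deliberately avoid the package's code paths: quantiles are interpolated by
# hand, scores accumulated in double loops.

# Type-7 quantile (linear interpolation between order statistics), by hand.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_round_half_away <- function(v, g) {
  if (is.null(g) || g <= 0) return(v)
  sign(v) * floor(abs(v) / g + 0.5) * g
}

# Endorsement rates by explicit counting.
oracle_endorsement <- function(cause, endorsements, cause_ids) {
  symptoms <- colnames(endorsements)
  x <- matrix(0, length(symptoms), length(cause_ids),
              dimnames = list(symptoms, cause_ids))
  for (j in cause_ids) {
    rows <- which(cause == j)
    for (s in symptoms) {
      cnt <- 0
      for (i in rows) if (endorsements[i, s] == 1) cnt <- cnt + 1
      x[s, j] <- cnt / length(rows)
    }
  }
  x
}

# Tariff transform cell by cell.
oracle_tariff <- function(x, granularity = 0.5, iqr_floor = 0.001) {
  out <- x
  for (s in rownames(x)) {
    row <- x[s, ]
    med <- oracle_quantile(row, 0.5)
    iqr <- oracle_quantile(row, 0.75) - oracle_quantile(row, 0.25)
    for (j in colnames(x)) {
      out[s, j] <- oracle_round_half_away((x[s, j] - med) /
                                            max(iqr, iqr_floor), granularity)
    }
  }
  out
}

# Score accumulation as an explicit double loop.
oracle_scores <- function(endorsements, tariff) {
  out <- matrix(0, nrow(endorsements), ncol(tariff),
                dimnames = list(NULL, colnames(tariff)))
  for (i in seq_len(nrow(endorsements))) {
    for (j in colnames(tariff)) {
      s <- 0
      for (sym in rownames(tariff)) {
        v <- endorsements[i, sym]
        if (!is.na(v) && v == 1) s <- s + tariff[sym, j]
      }
      out[i, j] <- s
    }
  }
  out
}

# Random small training fixture: every cause gets >= 1 death.
random_training <- function(n_causes, n_symptoms, n_deaths, seed) {
  set.seed(seed)
  causes <- sprintf("C%02d", seq_len(n_causes))
  symptoms <- sprintf("S%02d", seq_len(n_symptoms))
  cause <- c(causes, sample(causes, n_deaths - n_causes, replace = TRUE))
  e <- matrix(rbinom(n_deaths * n_symptoms, 1, 0.4), n_deaths, n_symptoms,
              dimnames = list(NULL, symptoms))
  list(training = va_training(sprintf("T%03d", seq_len(n_deaths)), cause, e),
       causes = va_cause_list(causes),
       endorsements = e, cause = cause, cause_ids = causes)
}

# Small deterministic record table used across parsing tests.
toy_schema <- function() va_schema("adult", c("s1", "s2", "s3"))

toy_records_csv <- function(path) {
  writeLines(c(
    "death_id,age_value,age_unit,sex,medical_records_available,narrative_confident,s1,s2,s3",
    "d1,70,years,male,yes,no,1,0,",
    "d2,45,years,female,0,1,,1,1",
    "d3,30,days,male,false,false,0,,0"), path)
  path
}
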