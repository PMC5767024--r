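# Independent oracles and fixture builders shared across the suite.
# These deliberately use naive loop/enumeration implementations so they
# stay independent of the package's vectorized code paths.

# Cohen's kappa by explicit contingency-table enumeration: count every
# (label1, label2) cell with loops, then po from the diagonal and pe from
# the products of the margins.
oracle_cohen_kappa <- function(r1, r2, categories = sort(unique(c(r1, r2)))) {
  n <- length(r1)
  k <- length(categories)
  tab <- matrix(0, k, k, dimnames = list(categories, categories))
  for (i in seq_len(n)) tab[r1[i], r2[i]] <- tab[r1[i], r2[i]] + 1
  po <- 0
  for (c in categories) po <- po + tab[c, c]
  po <- po / n
  pe <- 0
  for (c in categories) pe <- pe + sum(tab[c, ]) / n * sum(tab[, c]) / n
  if (pe >= 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

# Interval-lookup oracle for threshold classifiers.
oracle_interval_status <- function(value, low, high) {
  if (value < low) "low" else if (value > high) "high" else "normal"
}

oracle_proteinuria <- function(value) {
  if (value < 30) "normal" else if (value < 300) "microalbuminuria" else "albuminuria"
}

oracle_stage <- function(gfr) {
  if (gfr >= 90) "1" else if (gfr >= 60) "2" else if (gfr >= 45) "3a"
  else if (gfr >= 30) "3b" else if (gfr >= 15) "4" else "5"
}

# A complete adult record satisfying all invariants.
make_complete_record <- function(id = "t1", gender = "female", age = 60,
                                 weight = 80, creatinine = 0.54,
                                 urea = 25.2, potassium = 4.1,
                                 proteinuria = 0.6, ...) {
  patient_record(id = id, gender = gender, age = age, weight = weight,
                 sah = TRUE, dm = TRUE, creatinine = creatinine, urea = urea,
                 potassium = potassium, proteinuria = proteinuria, ...)
}

# Random complete record drawn inside broad plausible ranges.
random_record <- function(id) {
  patient_record(id = as.character(id),
                 gender = sample(c("male", "female"), 1),
                 age = sample(18:95, 1),
                 weight = round(runif(1, 40, 130), 1),
                 sah = runif(1) < 0.5, dm = runif(1) < 0.5,
                 creatinine = round(runif(1, 0.3, 6), 2),
                 urea = round(runif(1, 10, 150), 1),
                 potassium = round(runif(1, 2.5, 7), 1),
                 proteinuria = round(runif(1, 0, 1500), 1))
}

chart_fixture <- function() {
  system.file("extdata", "chart-sample.csv", package = "ckdscreen")
}

ratings_fixture <- function() {
  system.file("extdata", "ratings-sample.csv", package = "ckdscreen")
}
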