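#' Specify a synthetic screening cohort
#'
#' Describes a cohort of the kind screened in nephrology outpatient
#' settings: adults aged 31-79, a high prevalence of systemic arterial
#' hypertension (default 94.5%) with diabetes in a majority of the
#' hypertensive subjects (default 58.82%; non-hypertensive subjects in the
#' comorbid cohort default to diabetic, so every subject carries at least
#' one risk factor). Lab values are drawn from truncated normal/log-normal
#' families chosen so that all CKD stages and proteinuria categories are
#' reachable; they are synthetic sampling conveniences, not epidemiological
#' estimates. An optional `target_mix` over risk levels makes the generator
#' sample each record inside a risk-matrix cell of the requested level (the
#' creatinine is back-solved from the drawn GFR through Cockcroft-Gault),
#' giving records with known ground truth.
#'
#' @param n Number of subjects.
#' @param seed Integer seed; generation is reproducible given the seed.
#' @param sah_prevalence Probability of the hypertension flag.
#' @param dm_given_sah Probability of diabetes among hypertensive subjects.
#' @param dm_given_no_sah Probability of diabetes among the rest.
#' @param age_range Integer age bounds (inclusive).
#' @param target_mix Optional named probabilities over the four risk
#'   levels; names must be risk levels, values sum to 1.
#' @param prop_missing_proteinuria Fraction of records with the proteinuria
#'   lab blanked after ground truth is computed (paper charts often lack
#'   it); default 0.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 60, seed = 1,
                        sah_prevalence = 0.945,
                        dm_given_sah = 0.5882,
                        dm_given_no_sah = 1,
                        age_range = c(31, 79),
                        target_mix = NULL,
                        prop_missing_proteinuria = 0) {
  stopifnot(n >= 1,
            sah_prevalence >= 0, sah_prevalence <= 1,
            dm_given_sah >= 0, dm_given_sah <= 1,
            dm_given_no_sah >= 0, dm_given_no_sah <= 1,
            prop_missing_proteinuria >= 0, prop_missing_proteinuria <= 1)
  if (!is.null(target_mix)) {
    if (is.null(names(target_mix)) || !all(names(target_mix) %in% RISK_LEVELS))
      stop("target_mix must be named with risk levels")
    if (any(target_mix < 0) || abs(sum(target_mix) - 1) > 1e-8)
      stop("target_mix probabilities must be non-negative and sum to 1")
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 sah_prevalence = sah_prevalence,
                 dm_given_sah = dm_given_sah,
                 dm_given_no_sah = dm_given_no_sah,
                 age_range = as.integer(age_range),
                 target_mix = target_mix,
                 prop_missing_proteinuria = prop_missing_proteinuria),
            class = "cohort_spec")
}

rtrunc <- function(n, rfun, lower, upper, ...) {
  out <- rfun(n, ...)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0) {
    out[bad] <- rfun(length(bad), ...)
    bad <- which(out < lower | out > upper)
  }
  out
}

# GFR sampling bands per stage and proteinuria bands per category, used
# when a target risk mix pins down the matrix cell.
stage_gfr_band <- function(stage, edges) {
  switch(stage,
         "1" = c(edges[1], edges[1] + 60),
         "2" = c(edges[2], edges[1]),
         "3a" = c(edges[3], edges[2]),
         "3b" = c(edges[4], edges[3]),
         "4" = c(edges[5], edges[4]),
         "5" = c(2, edges[5]))
}

category_prot_band <- function(category, cuts) {
  switch(category,
         normal = c(0, cuts$microalbuminuria),
         microalbuminuria = c(cuts$microalbuminuria, cuts$albuminuria),
         albuminuria = c(cuts$albuminuria, cuts$albuminuria * 5))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws `spec$n` patient records and evaluates each through the risk
#' workflow, returning both the records and their ground-truth
#' evaluations. Every generated record passes [validate_record()]; the
#' same seed always yields the identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @param config Threshold configuration used for the ground-truth
#'   evaluations.
#' @return List with `records` (list of [patient_record()]) and `truth`
#'   (data frame: `id`, `category`, `stage`, `risk`).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 5, seed = 42))
#' table(cohort$truth$risk)
#' @export
generate_cohort <- function(spec, config = ckd_config()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n
  gender <- sample(c("male", "female"), n, replace = TRUE)
  age <- sample(seq(spec$age_range[1], spec$age_range[2]), n, replace = TRUE)
  weight <- round(rtrunc(n, stats::rnorm, 40, 140, mean = 75, sd = 15), 1)
  sah <- stats::runif(n) < spec$sah_prevalence
  dm <- ifelse(sah, stats::runif(n) < spec$dm_given_sah,
               stats::runif(n) < spec$dm_given_no_sah)
  urea <- round(rtrunc(n, stats::rnorm, 5, 250, mean = 32, sd = 12), 1)
  potassium <- round(rtrunc(n, stats::rnorm, 2.5, 7.5, mean = 4.5, sd = 0.6), 1)

  edges <- as.numeric(config$stage_edges)
  cuts <- config$proteinuria
  m <- config$risk_matrix

  if (is.null(spec$target_mix)) {
    creatinine <- round(rtrunc(n, stats::rlnorm, 0.3, 10,
                               meanlog = log(1.0), sdlog = 0.55), 2)
    proteinuria <- round(rtrunc(n, stats::rlnorm, 0, 4000,
                                meanlog = log(25), sdlog = 1.6), 1)
  } else {
    mix <- spec$target_mix[RISK_LEVELS]
    mix[is.na(mix)] <- 0
    names(mix) <- RISK_LEVELS
    levels_drawn <- sample(RISK_LEVELS, n, replace = TRUE, prob = mix)
    creatinine <- proteinuria <- numeric(n)
    for (i in seq_len(n)) {
      hits <- which(m == levels_drawn[i], arr.ind = TRUE)
      if (nrow(hits) == 0)
        stop("infeasible target mix: no matrix cell has risk level ",
             levels_drawn[i])
      pick <- hits[sample(nrow(hits), 1), ]
      stage <- rownames(m)[pick[1]]
      category <- colnames(m)[pick[2]]
      # keep clear of band edges so rounding cannot move the record
      # across a stage or category boundary
      band <- stage_gfr_band(stage, edges)
      gfr <- stats::runif(1, band[1] + 0.05, band[2] - 0.05)
      pband <- category_prot_band(category, cuts)
      proteinuria[i] <- round(stats::runif(1, pband[1] + 0.1,
                                           pband[2] - 0.1), 1)
      fct <- if (gender[i] == "female") 0.85 else 1
      # invert Cockcroft-Gault so the record's estimated GFR lands in band
      creatinine[i] <- (140 - age[i]) * weight[i] * fct / (72 * gfr)
    }
    creatinine <- signif(creatinine, 6)
  }

  records <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- patient_record(id = as.character(i), gender = gender[i],
                          age = age[i], weight = weight[i],
                          sah = sah[i], dm = dm[i],
                          creatinine = creatinine[i], urea = urea[i],
                          potassium = potassium[i],
                          proteinuria = proteinuria[i])
    ev <- evaluate_risk(rec, config, time = as.POSIXct("2000-01-01", tz = "UTC"))
    records[[i]] <- rec
    truth[[i]] <- data.frame(id = rec$id, category = ev$category,
                             stage = ev$stage, risk = ev$risk)
  }
  # blank proteinuria after ground truth, emulating chart missingness
  if (spec$prop_missing_proteinuria > 0) {
    k <- round(spec$prop_missing_proteinuria * n)
    if (k > 0) {
      drop <- sample(n, k)
      for (i in drop) records[[i]]$labs$proteinuria <- NA_real_
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(records = records, truth = truth)
}

#' Rater confusion models
#'
#' `confusion_adjacent()` builds a row-stochastic confusion matrix over an
#' ordered category set in which a rater reports the true category with
#' probability `1 - error` and otherwise an adjacent category (split evenly
#' between the two neighbours; edge categories send all error mass to
#' their single neighbour) — the near-miss pattern typical of expert
#' disagreement on ordered risk scales.
#'
#' `confusion_for_kappa()` builds the blend
#' \eqn{row_t = a\,e_t + (1 - a)\,\pi} with \eqn{a = \sqrt{\kappa_0}},
#' where \eqn{\pi} is the true-label marginal: under this model each
#' rater's marginal equals \eqn{\pi} and the expected pairwise Cohen's
#' kappa between any two raters is exactly \eqn{a^2 = \kappa_0}, giving a
#' calibrated design-agreement dial.
#'
#' @param error Probability of reporting an adjacent category.
#' @param categories Ordered category set (defaults to the four risk
#'   levels).
#' @param kappa0 Design agreement level in [0, 1].
#' @param marginal True-label marginal distribution (named or in category
#'   order).
#' @return Row-stochastic matrix with categories as dimnames.
#' @export
confusion_adjacent <- function(error, categories = RISK_LEVELS) {
  stopifnot(error >= 0, error <= 1, length(categories) >= 2)
  k <- length(categories)
  m <- matrix(0, k, k, dimnames = list(categories, categories))
  for (i in seq_len(k)) {
    m[i, i] <- 1 - error
    nb <- intersect(c(i - 1, i + 1), seq_len(k))
    m[i, nb] <- error / length(nb)
  }
  m
}

#' @rdname confusion_adjacent
#' @export
confusion_for_kappa <- function(kappa0, marginal, categories = RISK_LEVELS) {
  stopifnot(kappa0 >= 0, kappa0 <= 1)
  if (!is.null(names(marginal))) marginal <- marginal[categories]
  marginal <- as.numeric(marginal)
  stopifnot(length(marginal) == length(categories),
            all(marginal >= 0), abs(sum(marginal) - 1) < 1e-8)
  a <- sqrt(kappa0)
  k <- length(categories)
  m <- a * diag(k) + (1 - a) * matrix(marginal, k, k, byrow = TRUE)
  dimnames(m) <- list(categories, categories)
  m
}

#' Simulate a panel of raters around known true labels
#'
#' Each rater's column is drawn independently from its confusion model
#' given the subject's true label, emulating a panel of experts (plus a
#' tool) rating the same subjects. Reproducible given the seed.
#'
#' @param truth Character vector of true labels.
#' @param raters Number of raters, or a character vector of rater names.
#' @param confusion A single confusion matrix applied to all raters, or a
#'   list with one matrix per rater. Rows must sum to 1 and dimnames must
#'   cover the categories in `truth`.
#' @param seed Integer seed.
#' @return A [rating_matrix()] with one column per rater.
#' @examples
#' rm <- simulate_raters(rep(c("low", "high"), 10), raters = 3,
#'                       confusion = confusion_adjacent(0.1), seed = 7)
#' global_kappa(rm)$k
#' @export
simulate_raters <- function(truth, raters = 3, confusion, seed = 1) {
  truth <- as.character(truth)
  rater_names <- if (is.character(raters)) raters
                 else paste0("rater", seq_len(raters))
  n_raters <- length(rater_names)
  stopifnot(n_raters >= 2)
  conf_list <- if (is.list(confusion)) confusion
               else rep(list(confusion), n_raters)
  stopifnot(length(conf_list) == n_raters)
  for (cm in conf_list) {
    stopifnot(is.matrix(cm), !is.null(rownames(cm)),
              all(abs(rowSums(cm) - 1) < 1e-8),
              all(truth %in% rownames(cm)))
  }
  set.seed(seed)
  categories <- colnames(conf_list[[1]])
  out <- matrix(NA_character_, length(truth), n_raters,
                dimnames = list(NULL, rater_names))
  for (j in seq_len(n_raters)) {
    cm <- conf_list[[j]]
    for (i in seq_along(truth)) {
      out[i, j] <- sample(colnames(cm), 1, prob = cm[truth[i], ])
    }
  }
  rating_matrix(out, categories = categories)
}
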