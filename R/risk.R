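#' The KDIGO stage-by-albuminuria risk matrix
#'
#' Risk of CKD development and progression is stratified on a grid of CKD
#' stage (rows, by GFR band) against proteinuria category (columns). Each of
#' the 18 cells carries one of four risk levels: low, moderate, high or
#' very high. The default grid follows the KDIGO guideline heat map:
#' stages 1-2 map normal/micro/albuminuria to low/moderate/high, stage 3a
#' to moderate/high/very high, stage 3b to high/very high/very high, and
#' stages 4-5 are very high throughout.
#'
#' @param config Threshold configuration; the matrix ships in the shared
#'   configuration file and may be overridden there.
#' @return A 6 x 3 character matrix with stages as rownames and proteinuria
#'   categories as colnames, entries drawn from the four risk levels.
#' @export
risk_matrix <- function(config = ckd_config()) {
  config$risk_matrix
}

# Convert the nested config list (stage -> category -> level) to a matrix.
as_risk_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  m <- matrix(NA_character_, nrow = length(CKD_STAGES),
              ncol = length(PROTEINURIA_CATEGORIES),
              dimnames = list(CKD_STAGES, PROTEINURIA_CATEGORIES))
  for (s in CKD_STAGES) for (p in PROTEINURIA_CATEGORIES) {
    m[s, p] <- x[[s]][[p]] %||% NA_character_
  }
  m
}

#' Validate a risk matrix for totality and monotonicity
#'
#' A usable risk grid must define every stage-by-category cell exactly once
#' (totality) with a known risk level, and must be monotone: risk never
#' decreases as the stage worsens at fixed proteinuria, nor as proteinuria
#' worsens at fixed stage. A configuration violating monotonicity is
#' rejected unless explicitly overridden, in which case a warning is issued.
#'
#' @param m Matrix as returned by [risk_matrix()].
#' @param override If `TRUE`, demote monotonicity violations to a warning.
#' @return `m`, invisibly, if acceptable.
#' @export
validate_risk_matrix <- function(m, override = FALSE) {
  stopifnot(is.matrix(m),
            identical(rownames(m), CKD_STAGES),
            identical(colnames(m), PROTEINURIA_CATEGORIES))
  if (anyNA(m) || !all(m %in% RISK_LEVELS))
    stop("risk matrix is not total: every cell must hold one of ",
         paste(RISK_LEVELS, collapse = ", "))
  rank <- matrix(match(m, RISK_LEVELS), nrow = nrow(m), dimnames = dimnames(m))
  bad_rows <- apply(rank, 1, is.unsorted)           # along proteinuria
  bad_cols <- apply(rank, 2, is.unsorted)           # along stage
  if (any(bad_rows) || any(bad_cols)) {
    msg <- "risk matrix is not monotone in stage and proteinuria severity"
    if (override) warning(msg) else stop(msg)
  }
  invisible(m)
}

#' Evaluate CKD risk from proteinuria and GFR values
#'
#' The core decision workflow: verify the proteinuria category, classify
#' the CKD stage from the GFR, and look the pair up in the risk matrix.
#' Exactly one risk level is produced for any valid input pair.
#'
#' @param proteinuria Albumin-to-creatinine ratio in mg/g.
#' @param gfr GFR in mL/min.
#' @param config Threshold configuration.
#' @return List with `category`, `stage` and `risk` (each a character
#'   scalar from its label set).
#' @examples
#' evaluate_risk_values(200, 50)  # microalbuminuria, stage 3a, high risk
#' @export
evaluate_risk_values <- function(proteinuria, gfr, config = ckd_config()) {
  category <- as.character(classify_proteinuria(proteinuria, config))
  stage <- as.character(classify_stage(gfr, config))
  risk <- config$risk_matrix[stage, category]
  list(category = category, stage = stage, risk = risk)
}

#' Evaluate the CKD risk of a patient record
#'
#' Runs the full risk-identification workflow on a record: estimates the
#' GFR with Cockcroft-Gault (unless a `gfr` override is supplied),
#' classifies proteinuria and stage, looks up the risk level, flags the
#' serum biomarkers against their reference intervals, and attaches the
#' comorbidity flags and a referral narrative. Biomarker and comorbidity
#' flags annotate the narrative but never alter the matrix risk level.
#'
#' A record is evaluable only when creatinine, proteinuria, age, weight
#' and gender are all present; otherwise an explicit `incomplete_panel`
#' outcome is returned (never a partial evaluation).
#'
#' @param record A [patient_record()].
#' @param config Threshold configuration.
#' @param gfr Optional externally supplied GFR (mL/min) overriding the
#'   Cockcroft-Gault estimate.
#' @param time Evaluation timestamp (POSIXct); injectable for reproducible
#'   output.
#' @return An object of class `risk_evaluation` (fields: `id`, `category`,
#'   `stage`, `risk`, `gfr`, `gfr_displayed`, `biomarker_flags`,
#'   `comorbidities`, `advice`, `time`), or of class `incomplete_panel`
#'   listing the missing fields.
#' @examples
#' rec <- patient_record("2", "female", 60, 80, sah = TRUE, dm = TRUE,
#'                       creatinine = 0.54, urea = 25.2, potassium = 4.1,
#'                       proteinuria = 0.6)
#' evaluate_risk(rec)
#' @export
evaluate_risk <- function(record, config = ckd_config(), gfr = NULL,
                          time = Sys.time()) {
  stopifnot(inherits(record, "patient_record"))
  needed <- c(creatinine = record$labs$creatinine,
              proteinuria = record$labs$proteinuria,
              age = record$age, weight = record$weight)
  missing <- names(needed)[is.na(needed)]
  if (!record$gender %in% c("male", "female")) missing <- c(missing, "gender")
  if (length(missing) > 0) {
    return(structure(list(id = record$id, missing = missing,
                          message = paste("incomplete panel: missing",
                                          paste(missing, collapse = ", "))),
                     class = "incomplete_panel"))
  }
  findings <- validate_record(record)
  if (nrow(findings) > 0)
    stop("record fails validation: ", paste(findings$message, collapse = "; "))

  if (is.null(gfr)) {
    g <- estimate_gfr(record$age, record$weight, record$labs$creatinine,
                      record$gender)
    gfr_value <- g$clearance
    gfr_shown <- g$displayed
  } else {
    gfr_value <- gfr
    gfr_shown <- truncate1(gfr)
  }
  core <- evaluate_risk_values(record$labs$proteinuria, gfr_value, config)

  flags <- list()
  for (b in c("creatinine", "urea", "potassium")) {
    v <- record$labs[[b]]
    if (!is.na(v)) flags[[b]] <- classify_biomarker(b, v, config)
  }

  advice <- risk_advice(core$risk, core$stage)
  structure(
    list(id = record$id,
         category = core$category, stage = core$stage, risk = core$risk,
         gfr = gfr_value, gfr_displayed = gfr_shown,
         biomarker_flags = flags,
         comorbidities = c(sah = record$sah, dm = record$dm),
         advice = advice,
         time = format(time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")),
    class = "risk_evaluation"
  )
}

# Referral narrative per risk level; wording is the package's own.
risk_advice <- function(risk, stage) {
  switch(risk,
    low = "Low risk of CKD development. Maintain routine screening.",
    moderate = sprintf(
      "Moderate risk of CKD (stage %s). A consultation with a physician is recommended to review kidney function.", stage),
    high = sprintf(
      "Alert: high risk of CKD (stage %s). Referral to a nephrologist for a face-to-face evaluation is recommended.", stage),
    very_high = sprintf(
      "Alert: very high risk of CKD (stage %s). Urgent referral to a nephrologist is recommended.", stage),
    stop("unknown risk level: ", risk))
}

#' @export
print.risk_evaluation <- function(x, ...) {
  cat(sprintf("CKD risk evaluation for patient %s (%s)\n", x$id, x$time))
  cat(sprintf("  GFR %.1f mL/min -> stage %s; proteinuria: %s\n",
              x$gfr_displayed, x$stage, x$category))
  cat(sprintf("  Risk level: %s\n", gsub("_", " ", x$risk)))
  for (f in x$biomarker_flags) {
    if (f$status != "normal")
      cat(sprintf("  Note: %s %s (%.2f %s)\n", f$biomarker, f$status,
                  f$value, f$unit))
  }
  if (any(x$comorbidities))
    cat("  Risk factors present:",
        paste(toupper(names(x$comorbidities))[x$comorbidities], collapse = ", "),
        "\n")
  cat("  ", x$advice, "\n", sep = "")
  invisible(x)
}

#' @export
print.incomplete_panel <- function(x, ...) {
  cat(sprintf("Evaluation refused for patient %s: %s\n", x$id, x$message))
  invisible(x)
}

#' Enumerate all terminal classifications of the risk workflow
#'
#' Exhaustively drives the proteinuria-stage-risk workflow over every
#' proteinuria category and CKD stage combination (using a representative
#' value inside each band) and collects the terminal classification of each
#' run. The decision process has exactly 18 terminal states — the full
#' 3 x 6 grid — each mapped to one of the four risk levels.
#'
#' @param config Threshold configuration.
#' @return Data frame with one row per terminal state and columns
#'   `category`, `stage`, `risk`.
#' @export
enumerate_terminal_states <- function(config = ckd_config()) {
  cuts <- config$proteinuria
  prot_reps <- c(normal = cuts$microalbuminuria / 2,
                 microalbuminuria = (cuts$microalbuminuria + cuts$albuminuria) / 2,
                 albuminuria = cuts$albuminuria * 2)
  edges <- as.numeric(config$stage_edges)
  gfr_reps <- c(edges[1] + 10, (edges[-5] + edges[-1]) / 2, edges[5] / 2)
  names(gfr_reps) <- CKD_STAGES
  out <- list()
  for (p in PROTEINURIA_CATEGORIES) for (s in CKD_STAGES) {
    term <- evaluate_risk_values(prot_reps[[p]], gfr_reps[[s]], config)
    out[[length(out) + 1]] <- data.frame(category = term$category,
                                         stage = term$stage,
                                         risk = term$risk)
  }
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Recommend the next screening date after an evaluation
#'
#' Patients are periodically reminded to attend a healthcare facility for
#' screening tests; the recommended interval shortens as risk rises
#' (defaults: low and moderate 12 months, high 6, very high 3 —
#' configurable, and never longer for a higher risk).
#'
#' @param last_eval A `risk_evaluation` (needs `risk` and `time`).
#' @param today Reference date for the `overdue` flag.
#' @param config Threshold configuration.
#' @return A `Date`: evaluation date plus the configured interval. The
#'   attribute `overdue` is `TRUE` when the due date is on or before
#'   `today`.
#' @export
next_screening_due <- function(last_eval, today = Sys.Date(),
                               config = ckd_config()) {
  stopifnot(!is.null(last_eval$risk), !is.null(last_eval$time))
  months <- config$screening_intervals_months[[last_eval$risk]]
  if (is.null(months)) stop("no screening interval configured for risk level ",
                            last_eval$risk)
  start <- as.Date(substr(last_eval$time, 1, 10))
  due <- if (months == 0) start
         else seq(start, by = paste(months, "months"), length.out = 2)[2]
  attr(due, "overdue") <- due <= today
  due
}

#' Persist and read the evaluation history
#'
#' Risk evaluations are kept as an append-only JSON-lines history so the
#' disease progression can be followed across evaluations.
#'
#' @param evaluation A `risk_evaluation`.
#' @param path JSON-lines history file; created if absent.
#' @return `append_evaluation_history` returns `path` invisibly;
#'   `read_evaluation_history` returns a list of evaluations (plain lists).
#' @export
append_evaluation_history <- function(evaluation, path) {
  stopifnot(inherits(evaluation, "risk_evaluation"))
  x <- unclass(evaluation)
  x$biomarker_flags <- lapply(x$biomarker_flags, unclass)
  line <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null")
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}

#' @rdname append_evaluation_history
#' @export
read_evaluation_history <- function(path) {
  if (!file.exists(path)) return(list())
  lines <- readLines(path, warn = FALSE)
  lapply(lines[nzchar(lines)], jsonlite::fromJSON)
}
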