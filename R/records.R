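#' Construct a personal health record for one subject
#'
#' The record mirrors the paper-chart layout used in nephrology screening:
#' demographics (gender, age, weight), comorbidity flags for systemic
#' arterial hypertension (SAH) and diabetes mellitus (DM), and a lab panel
#' with serum creatinine, urea, potassium (mg/dL, mg/dL, mEq/L) and the
#' urinary albumin-to-creatinine ratio (mg/g). Any lab may be absent (`NA`);
#' evaluation later refuses records whose panel is incomplete rather than
#' producing a partial answer.
#'
#' @param id Opaque subject identifier.
#' @param gender `"male"` or `"female"`.
#' @param age Age in whole years. Evaluation is adult-only (age >= 18).
#' @param weight Weight in kg, positive.
#' @param sah,dm Logical comorbidity flags (hypertension, diabetes).
#' @param creatinine,urea,potassium,proteinuria Lab values; `NA` if missing.
#' @param recorded_gfr GFR as recorded in the source chart, if any (mL/min).
#' @param medications List of [medication()] objects.
#' @param allergies List of [allergy()] objects.
#' @param monitoring_log List of self-monitoring readings.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(id, gender, age, weight,
                           sah = FALSE, dm = FALSE,
                           creatinine = NA_real_, urea = NA_real_,
                           potassium = NA_real_, proteinuria = NA_real_,
                           recorded_gfr = NA_real_,
                           medications = list(), allergies = list(),
                           monitoring_log = list()) {
  structure(
    list(id = as.character(id),
         gender = as.character(gender),
         age = as.numeric(age),
         weight = as.numeric(weight),
         sah = isTRUE(sah), dm = isTRUE(dm),
         labs = list(creatinine = as.numeric(creatinine),
                     urea = as.numeric(urea),
                     potassium = as.numeric(potassium),
                     proteinuria = as.numeric(proteinuria)),
         recorded_gfr = as.numeric(recorded_gfr),
         medications = medications,
         allergies = allergies,
         monitoring_log = monitoring_log),
    class = "patient_record"
  )
}

#' @rdname patient_record
#' @param substance Drug or allergen substance name, non-empty.
#' @param dose,schedule Free-text dose and schedule.
#' @export
medication <- function(substance, dose = NA_character_, schedule = NA_character_) {
  structure(list(substance = as.character(substance),
                 dose = as.character(dose),
                 schedule = as.character(schedule)),
            class = "medication")
}

#' @rdname patient_record
#' @param reaction Free-text description of the allergic reaction.
#' @export
allergy <- function(substance, reaction = NA_character_) {
  structure(list(substance = as.character(substance),
                 reaction = as.character(reaction)),
            class = "allergy")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("Patient %s: %s, %d y, %.1f kg%s%s\n", x$id, x$gender,
              as.integer(x$age), x$weight,
              if (x$sah) ", SAH" else "", if (x$dm) ", DM" else ""))
  labs <- x$labs
  cat(sprintf("  creatinine %s, urea %s, potassium %s, proteinuria %s\n",
              format(labs$creatinine), format(labs$urea),
              format(labs$potassium), format(labs$proteinuria)))
  invisible(x)
}

#' Validate a patient record against its invariants
#'
#' Checks the adult-only scope (age at least 18), positive weight, a binary
#' gender code, non-negative finite lab values, and non-empty substance
#' names on medications and allergies. Violations are reported as findings,
#' not raised as errors, so a batch of records can be screened in one pass.
#'
#' @param record A [patient_record()].
#' @return A data frame with columns `field` and `message`; zero rows iff
#'   all invariants hold.
#' @export
validate_record <- function(record) {
  stopifnot(inherits(record, "patient_record"))
  findings <- list()
  add <- function(field, message) {
    findings[[length(findings) + 1]] <<- data.frame(field = field,
                                                    message = message)
  }
  if (!record$gender %in% c("male", "female"))
    add("gender", "gender must be exactly one of 'male' or 'female'")
  if (is.na(record$age) || record$age != trunc(record$age))
    add("age", "age must be an integer number of years")
  else if (record$age < 18)
    add("age", "age below adult scope (evaluation requires age >= 18)")
  if (is.na(record$weight) || record$weight <= 0)
    add("weight", "weight non-positive")
  for (lab in names(record$labs)) {
    v <- record$labs[[lab]]
    if (!is.na(v) && (!is.finite(v) || v < 0))
      add(lab, sprintf("%s must be a non-negative finite value", lab))
  }
  for (m in record$medications) {
    if (!nzchar(trimws(m$substance %||% "")))
      add("medications", "medication substance must be non-empty")
  }
  for (a in record$allergies) {
    if (!nzchar(trimws(a$substance %||% "")))
      add("allergies", "allergy substance must be non-empty")
  }
  if (length(findings) == 0)
    data.frame(field = character(), message = character())
  else
    do.call(rbind, findings)
}

# Chart-style CSV header (comorbidities as "X" marks, F/M gender codes).
TABLE_HEADER <- c("ID", "SAH", "DM", "Creatinine", "Urea", "Microalbuminuria",
                  "Potassium", "Weight", "Age", "Gender", "GFR")

#' Read and write patient records
#'
#' Two on-disk forms are supported. The CSV dialect mirrors the screening
#' chart layout: header `ID,SAH,DM,Creatinine,Urea,Microalbuminuria,
#' Potassium,Weight,Age,Gender,GFR`, an `X` marking a present comorbidity
#' (blank = absent), `F`/`M` gender codes, and blank cells for missing labs
#' (proteinuria in particular is frequently unrecorded in paper charts).
#' The JSON form serializes full records including medications, allergies
#' and the monitoring log. `load_records(save_records(x))` is the identity
#' on record fields.
#'
#' @param path File to read or write. Format is taken from the extension
#'   (`.csv` or `.json`) unless `format` is given.
#' @param format `"csv"`, `"json"`, or `"auto"`.
#' @return `load_records` returns a list of [patient_record()] objects;
#'   `save_records` returns `path` invisibly.
#' @export
load_records <- function(path, format = c("auto", "csv", "json")) {
  format <- resolve_format(match.arg(format), path)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "json") return(records_from_json(path))
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(df), TABLE_HEADER))
    stop("CSV header does not match the expected chart dialect; expected: ",
         paste(TABLE_HEADER, collapse = ","))
  records <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    num <- function(col) {
      cell <- trimws(row[[col]])
      if (!nzchar(cell)) return(NA_real_)
      v <- suppressWarnings(as.numeric(cell))
      if (is.na(v)) stop(sprintf("malformed value in row %d, column %s: '%s'",
                                 i, col, cell))
      v
    }
    gender <- switch(toupper(trimws(row[["Gender"]])),
                     "F" = "female", "M" = "male",
                     stop(sprintf("malformed value in row %d, column Gender: '%s'",
                                  i, row[["Gender"]])))
    records[[i]] <- patient_record(
      id = row[["ID"]], gender = gender,
      age = num("Age"), weight = num("Weight"),
      sah = toupper(trimws(row[["SAH"]])) == "X",
      dm = toupper(trimws(row[["DM"]])) == "X",
      creatinine = num("Creatinine"), urea = num("Urea"),
      potassium = num("Potassium"), proteinuria = num("Microalbuminuria"),
      recorded_gfr = num("GFR"))
  }
  records
}

#' @rdname load_records
#' @param records List of [patient_record()] objects.
#' @export
save_records <- function(records, path, format = c("auto", "csv", "json")) {
  format <- resolve_format(match.arg(format), path)
  if (inherits(records, "patient_record")) records <- list(records)
  if (format == "json") {
    jsonlite::write_json(lapply(records, unclass_record), path,
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
    return(invisible(path))
  }
  rows <- lapply(records, function(r) {
    cell <- function(v) if (is.na(v)) "" else format(v, trim = TRUE)
    data.frame(ID = r$id,
               SAH = if (r$sah) "X" else "",
               DM = if (r$dm) "X" else "",
               Creatinine = cell(r$labs$creatinine),
               Urea = cell(r$labs$urea),
               Microalbuminuria = cell(r$labs$proteinuria),
               Potassium = cell(r$labs$potassium),
               Weight = cell(r$weight),
               Age = cell(r$age),
               Gender = if (r$gender == "female") "F" else "M",
               GFR = cell(r$recorded_gfr),
               check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "json")) ext
  else stop("cannot infer format from extension '", ext, "'; pass format=")
}

unclass_record <- function(r) {
  out <- unclass(r)
  out$medications <- lapply(r$medications, unclass)
  out$allergies <- lapply(r$allergies, unclass)
  out
}

records_from_json <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(x) {
    null_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
    patient_record(
      id = x$id, gender = x$gender, age = null_na(x$age),
      weight = null_na(x$weight),
      sah = isTRUE(x$sah), dm = isTRUE(x$dm),
      creatinine = null_na(x$labs$creatinine),
      urea = null_na(x$labs$urea),
      potassium = null_na(x$labs$potassium),
      proteinuria = null_na(x$labs$proteinuria),
      recorded_gfr = null_na(x$recorded_gfr),
      medications = lapply(x$medications, function(m)
        medication(m$substance, m$dose %||% NA_character_,
                   m$schedule %||% NA_character_)),
      allergies = lapply(x$allergies, function(a)
        allergy(a$substance, a$reaction %||% NA_character_)),
      monitoring_log = x$monitoring_log %||% list())
  })
}

#' Check a medication list for allergy conflicts and drug interactions
#'
#' Non-compliance and adverse drug events complicate the clinical course of
#' chronic patients, so every prescribed substance is screened against the
#' subject's declared allergies and against a user-supplied pairwise
#' interaction table. Substance matching is case-insensitive and exact; the
#' interaction table is treated as symmetric (an unordered pair list). No
#' interaction knowledge is bundled: the table is an external input.
#'
#' @param meds List of [medication()] objects.
#' @param allergies List of [allergy()] objects.
#' @param interactions Two-column data frame (or matrix) of interacting
#'   substance pairs; may be `NULL` for none.
#' @return Data frame of alerts with columns `type` (`"allergy"` or
#'   `"interaction"`), `substance_a`, `substance_b` (`NA` for allergy
#'   alerts) and `message`; zero rows when there is nothing to flag.
#'   Duplicate alerts are collapsed.
#' @examples
#' check_medication_alerts(list(medication("Ibuprofen")),
#'                         list(allergy("ibuprofen")), NULL)
#' @export
check_medication_alerts <- function(meds, allergies, interactions = NULL) {
  med_subs <- vapply(meds, function(m) m$substance, character(1))
  alg_subs <- vapply(allergies, function(a) a$substance, character(1))
  alerts <- list()
  for (s in unique(tolower(med_subs))) {
    if (s %in% tolower(alg_subs)) {
      orig <- med_subs[match(s, tolower(med_subs))]
      alerts[[length(alerts) + 1]] <- data.frame(
        type = "allergy", substance_a = orig, substance_b = NA_character_,
        message = sprintf("patient is allergic to prescribed substance '%s'", orig))
    }
  }
  if (!is.null(interactions) && NROW(interactions) > 0) {
    tab <- as.data.frame(interactions, stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop("interaction table must have two columns")
    pair_key <- function(a, b) paste(sort(c(tolower(a), tolower(b))), collapse = "|")
    known <- unique(mapply(pair_key, tab[[1]], tab[[2]]))
    meds_lower <- unique(tolower(med_subs))
    if (length(meds_lower) >= 2) {
      combos <- utils::combn(meds_lower, 2)
      for (j in seq_len(ncol(combos))) {
        a <- combos[1, j]; b <- combos[2, j]
        if (pair_key(a, b) %in% known) {
          # alphabetical pair order keeps output independent of med order
          ordered <- sort(c(a, b))
          oa <- med_subs[match(ordered[1], tolower(med_subs))]
          ob <- med_subs[match(ordered[2], tolower(med_subs))]
          alerts[[length(alerts) + 1]] <- data.frame(
            type = "interaction", substance_a = oa, substance_b = ob,
            message = sprintf("prescribed substances '%s' and '%s' interact", oa, ob))
        }
      }
    }
  }
  if (length(alerts) == 0) {
    return(data.frame(type = character(), substance_a = character(),
                      substance_b = character(), message = character()))
  }
  unique(do.call(rbind, alerts))
}

#' Append and read self-monitoring log entries
#'
#' Readings (blood pressure, glucose) are persisted as append-only JSON
#' lines so a monitoring history accumulates across sessions.
#'
#' @param reading A reading object, see [blood_pressure_reading()] and
#'   [glucose_reading()].
#' @param path JSON-lines file; created if absent.
#' @return `append_monitoring_log` returns `path` invisibly;
#'   `read_monitoring_log` returns a list of readings (as plain lists).
#' @export
append_monitoring_log <- function(reading, path) {
  line <- jsonlite::toJSON(unclass(reading), auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null")
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}

#' @rdname append_monitoring_log
#' @export
read_monitoring_log <- function(path) {
  if (!file.exists(path)) return(list())
  lines <- readLines(path, warn = FALSE)
  lapply(lines[nzchar(lines)], jsonlite::fromJSON)
}
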