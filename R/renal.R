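#' Estimate creatinine clearance with the Cockcroft-Gault equation
#'
#' Computes the glomerular filtration rate proxy
#' \deqn{C = \frac{(140 - I)\,K}{72\,P}}
#' where `I` is age in years, `K` weight in kg and `P` plasmatic creatinine
#' in mg/dL, multiplied by 0.85 for women. Cockcroft-Gault is preferred here
#' over MDRD-family equations because it needs no race parameter, which is
#' hard to assign consistently in admixed populations.
#'
#' The displayed value truncates (toward zero, not rounds) the full-precision
#' clearance at one decimal, the convention used when rendering results.
#'
#' @param age Age in years; must be below 140 for a positive estimate.
#' @param weight Body weight in kilograms, positive.
#' @param creatinine Plasmatic creatinine in mg/dL, positive.
#' @param gender `"male"` or `"female"` (abbreviations accepted).
#' @return An object of class `gfr_result`: a list with `clearance`
#'   (full-precision mL/min) and `displayed` (one-decimal truncation).
#' @examples
#' estimate_gfr(age = 60, weight = 80, creatinine = 0.54, gender = "female")
#' @export
estimate_gfr <- function(age, weight, creatinine, gender = c("male", "female")) {
  gender <- match.arg(gender)
  stopifnot(is.numeric(age), is.numeric(weight), is.numeric(creatinine))
  if (age >= 140) stop("age must be below 140 years for a positive estimate")
  if (weight <= 0) stop("weight must be positive")
  if (creatinine <= 0) stop("creatinine must be positive")
  factor <- if (gender == "female") 0.85 else 1
  clearance <- (140 - age) * weight / (creatinine * 72) * factor
  structure(
    list(clearance = clearance,
         displayed = truncate1(clearance),
         gender = gender),
    class = "gfr_result"
  )
}

# One-decimal truncation toward zero, with a guard against binary
# representation error just below a decimal boundary (e.g. 155.7 stored
# as 155.69999...).
truncate1 <- function(x) trunc(round(x * 10, 6)) / 10

#' @export
print.gfr_result <- function(x, ...) {
  cat(sprintf("Estimated creatinine clearance: %.1f mL/min (Cockcroft-Gault)\n",
              x$displayed))
  invisible(x)
}

#' Classify proteinuria from the albumin-to-creatinine ratio
#'
#' Categories at the conventional 30 and 300 mg/g cut-offs: below 30 is
#' normal, 30 up to (but excluding) 300 is microalbuminuria, and 300 or more
#' is albuminuria. The middle band is half-open so every non-negative value
#' is classifiable.
#'
#' @param value Albumin-to-creatinine ratio in mg/g, non-negative.
#' @param config Threshold configuration, see [ckd_config()].
#' @return Ordered factor with levels normal < microalbuminuria < albuminuria.
#' @examples
#' classify_proteinuria(200)   # microalbuminuria
#' @export
classify_proteinuria <- function(value, config = ckd_config()) {
  stopifnot(is.numeric(value))
  if (any(value < 0)) stop("proteinuria value must be non-negative")
  cuts <- config$proteinuria
  cat <- ifelse(value < cuts$microalbuminuria, "normal",
         ifelse(value < cuts$albuminuria, "microalbuminuria", "albuminuria"))
  factor(cat, levels = PROTEINURIA_CATEGORIES, ordered = TRUE)
}

#' Classify CKD stage from the GFR
#'
#' Maps a positive GFR (mL/min) onto the six KDIGO stages. With the default
#' edges 90/60/45/30/15 the bands are: stage 1 at 90 or above, stage 2 in
#' [60, 90), 3a in [45, 60), 3b in [30, 45), 4 in [15, 30), stage 5 below
#' 15. Boundaries belong to the less-severe stage; the six half-open bands
#' tile the positive axis with no gaps or overlaps.
#'
#' @param gfr GFR in mL/min, positive.
#' @param config Threshold configuration, see [ckd_config()].
#' @return Ordered factor with levels 1 < 2 < 3a < 3b < 4 < 5.
#' @examples
#' classify_stage(50)   # stage 3a
#' @export
classify_stage <- function(gfr, config = ckd_config()) {
  stopifnot(is.numeric(gfr))
  if (any(gfr <= 0)) stop("GFR must be positive")
  edges <- as.numeric(config$stage_edges)
  stopifnot(length(edges) == 5, !is.unsorted(rev(edges), strictly = TRUE))
  idx <- vapply(gfr, function(g) {
    i <- which(g >= edges)
    if (length(i) == 0) 6L else min(i)
  }, integer(1))
  factor(CKD_STAGES[idx], levels = CKD_STAGES, ordered = TRUE)
}

#' Flag a biomarker value against its reference interval
#'
#' Compares a serum biomarker to its closed reference interval (endpoints
#' count as normal). Shipped defaults: creatinine 0.6-1.4 mg/dL, urea
#' 20.0-40.0 mg/dL, potassium 3.5-5.5 mEq/L.
#'
#' @param name One of `"creatinine"`, `"urea"`, `"potassium"` (or any
#'   biomarker declared in the configuration).
#' @param value Measured value, non-negative.
#' @param config Threshold configuration, see [ckd_config()].
#' @return An object of class `biomarker_flag`: list with `biomarker`,
#'   `value`, `status` (`"low"`, `"normal"` or `"high"`) and `reference`
#'   (the interval used).
#' @examples
#' classify_biomarker("potassium", 5.6)  # high
#' @export
classify_biomarker <- function(name, value, config = ckd_config()) {
  ref <- config$biomarkers[[name]]
  if (is.null(ref)) {
    stop("unknown biomarker: ", name, " (declared: ",
         paste(names(config$biomarkers), collapse = ", "), ")")
  }
  stopifnot(is.numeric(value), length(value) == 1)
  if (value < 0) stop("biomarker value must be non-negative")
  status <- if (value < ref$low) "low" else if (value > ref$high) "high" else "normal"
  structure(
    list(biomarker = name, value = value, status = status,
         reference = c(low = ref$low, high = ref$high),
         unit = ref$unit %||% ""),
    class = "biomarker_flag"
  )
}

#' @export
print.biomarker_flag <- function(x, ...) {
  cat(sprintf("%s %.2f %s: %s (reference %.1f-%.1f)\n",
              x$biomarker, x$value, x$unit, x$status,
              x$reference["low"], x$reference["high"]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
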