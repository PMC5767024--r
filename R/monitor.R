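#' Self-monitoring readings
#'
#' Constructors for the two reading types used in comorbidity
#' self-monitoring: blood pressure for systemic arterial hypertension and
#' blood glucose for diabetes. Readings can originate from manual entry or
#' from a wireless sensor; both paths produce identical objects apart from
#' the `source` tag and classify identically downstream.
#'
#' @param systolic,diastolic Blood pressure in mmHg; systolic must exceed
#'   diastolic and both must be positive.
#' @param value Glucose in mg/dL, positive.
#' @param context Measurement context: `"preprandial"`, `"postprandial"`
#'   or `"fasting"` (mandatory; targets differ by context).
#' @param time Timestamp string; injectable for reproducible logs.
#' @param source `"manual"` or `"sensor"`.
#' @return An object of class `bp_reading` or `glucose_reading`.
#' @export
blood_pressure_reading <- function(systolic, diastolic,
                                   time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                   source = c("manual", "sensor")) {
  source <- match.arg(source)
  stopifnot(is.numeric(systolic), is.numeric(diastolic))
  if (diastolic <= 0) stop("diastolic pressure must be positive")
  if (systolic <= diastolic)
    stop("systolic pressure must exceed diastolic pressure")
  structure(list(type = "blood_pressure", systolic = systolic,
                 diastolic = diastolic, time = time, source = source),
            class = "bp_reading")
}

#' @rdname blood_pressure_reading
#' @export
glucose_reading <- function(value, context = GLUCOSE_CONTEXTS,
                            time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                            source = c("manual", "sensor")) {
  context <- match.arg(context)
  source <- match.arg(source)
  stopifnot(is.numeric(value))
  if (value <= 0) stop("glucose value must be positive")
  structure(list(type = "glucose", value = value, context = context,
                 time = time, source = source),
            class = "glucose_reading")
}

#' Classify a blood-pressure reading against hypertension targets
#'
#' A reading is above target when the systolic value reaches the systolic
#' threshold OR the diastolic value reaches the diastolic threshold
#' (defaults 140/90 mmHg, inclusive, configurable). The result carries a
#' one-line feedback string suitable for direct display.
#'
#' @param reading A [blood_pressure_reading()], or a systolic value in mmHg
#'   if `diastolic` is given.
#' @param diastolic Diastolic mmHg when `reading` is numeric.
#' @param config Threshold configuration.
#' @return List of class `monitor_result` with `status` (`"controlled"` or
#'   `"above_target"`) and `feedback`.
#' @examples
#' classify_blood_pressure(120, 80)$status   # controlled
#' @export
classify_blood_pressure <- function(reading, diastolic = NULL,
                                    config = ckd_config()) {
  if (is.numeric(reading)) {
    reading <- blood_pressure_reading(reading, diastolic)
  }
  stopifnot(inherits(reading, "bp_reading"))
  th <- config$blood_pressure
  above <- reading$systolic >= th$systolic || reading$diastolic >= th$diastolic
  status <- if (above) "above_target" else "controlled"
  feedback <- if (above) {
    sprintf("Blood pressure %g/%g mmHg is above the %g/%g target; hypertension is not controlled.",
            reading$systolic, reading$diastolic, th$systolic, th$diastolic)
  } else {
    sprintf("Blood pressure %g/%g mmHg is within the %g/%g target; hypertension is controlled.",
            reading$systolic, reading$diastolic, th$systolic, th$diastolic)
  }
  structure(list(status = status, feedback = feedback, reading = reading),
            class = "monitor_result")
}

#' Classify a glucose reading against its context-specific target
#'
#' Glucose targets depend on the measurement context (defaults:
#' preprandial 70-130 mg/dL, postprandial below 180, fasting 70-99; all
#' configurable). The postprandial upper bound is strict (a value exactly
#' at the bound is out of range); preprandial and fasting intervals are
#' inclusive.
#'
#' @param reading A [glucose_reading()], or a numeric mg/dL value if
#'   `context` is given.
#' @param context Measurement context when `reading` is numeric.
#' @param config Threshold configuration.
#' @return List of class `monitor_result` with `status` (`"in_range"` or
#'   `"out_of_range"`) and `feedback`.
#' @examples
#' classify_glucose(95, "fasting")$status    # in_range
#' @export
classify_glucose <- function(reading, context = NULL, config = ckd_config()) {
  if (is.numeric(reading)) {
    reading <- glucose_reading(reading, context)
  }
  stopifnot(inherits(reading, "glucose_reading"))
  target <- config$glucose[[reading$context]]
  if (is.null(target)) stop("unknown glucose context: ", reading$context)
  v <- reading$value
  too_high <- if (isTRUE(target$strict_high)) v >= target$high else v > target$high
  out <- v < target$low || too_high
  status <- if (out) "out_of_range" else "in_range"
  feedback <- if (out) {
    sprintf("%s glucose %g mg/dL is out of the target range; diabetes control should be reviewed.",
            reading$context, v)
  } else {
    sprintf("%s glucose %g mg/dL is within the target range.",
            reading$context, v)
  }
  structure(list(status = status, feedback = feedback, reading = reading),
            class = "monitor_result")
}

#' @export
print.monitor_result <- function(x, ...) {
  cat(x$feedback, "\n")
  invisible(x)
}

#' Ingest a raw sensor stream item as a reading
#'
#' Wireless monitoring devices deliver tagged raw items; this converts them
#' to the same reading objects as manual entry (with `source = "sensor"`),
#' so the downstream classification is identical on both paths. A malformed
#' item (missing or unknown type tag, missing fields) is rejected with an
#' error after a log message.
#'
#' @param item Named list with a `type` tag: either
#'   `list(type = "blood_pressure", systolic =, diastolic =)` or
#'   `list(type = "glucose", value =, context =)`, plus optional `time`.
#' @return A [blood_pressure_reading()] or [glucose_reading()] with
#'   `source = "sensor"`.
#' @export
ingest_sensor_value <- function(item) {
  reject <- function(why) {
    message("sensor item rejected: ", why)
    stop("malformed sensor item: ", why)
  }
  if (!is.list(item) || is.null(item$type)) reject("missing type tag")
  time <- item$time %||% format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  switch(as.character(item$type),
    blood_pressure = {
      if (is.null(item$systolic) || is.null(item$diastolic))
        reject("blood_pressure item needs systolic and diastolic")
      blood_pressure_reading(item$systolic, item$diastolic, time = time,
                             source = "sensor")
    },
    glucose = {
      if (is.null(item$value) || is.null(item$context))
        reject("glucose item needs value and context")
      glucose_reading(item$value, item$context, time = time, source = "sensor")
    },
    reject(paste0("unknown type tag '", item$type, "'")))
}
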