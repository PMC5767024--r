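# Simplified CDA-R2-like clinical document template. One fixed namespace
# stands in for the OID machinery of full HL7 CDA; element names are fixed
# so documents are byte-deterministic for fixed inputs and timestamp.
CDA_NS <- "urn:ckdscreen:cda:simplified"

#' Build a simplified HL7-CDA-style clinical document
#'
#' Serializes a personal health record and (optionally) its CKD risk
#' evaluation into a simplified CDA-R2-like XML document so results can be
#' shared with physicians and reused in later consultations. The template
#' has a header (patient demographics, author, effective time) and four
#' sections: medications, allergies, lab results (each entry with name,
#' value, unit and optional date) and the risk evaluation (category, stage,
#' risk level, narrative). Full HL7 CDA conformance and terminology binding
#' are out of scope; the document validates against the simplified schema
#' shipped with the package.
#'
#' @param record A validated [patient_record()].
#' @param evaluation Optional `risk_evaluation`; when absent the evaluation
#'   section is emitted empty.
#' @param effective_time Document timestamp string; injectable so output is
#'   byte-deterministic.
#' @param author Authoring application identifier.
#' @param extensions Character vector of opaque XML fragments (e.g.
#'   recovered by [parse_clinical_document()]) appended verbatim after the
#'   known sections.
#' @return UTF-8 XML as a character scalar.
#' @export
build_clinical_document <- function(record, evaluation = NULL,
                                    effective_time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                    author = "ckdscreen",
                                    extensions = character()) {
  stopifnot(inherits(record, "patient_record"))
  findings <- validate_record(record)
  if (nrow(findings) > 0)
    stop("refusing to export invalid record: ",
         paste(findings$message, collapse = "; "))
  if (!is.null(evaluation) && !inherits(evaluation, "risk_evaluation"))
    stop("evaluation must be a risk_evaluation or NULL")

  doc <- xml2::xml_new_root("ClinicalDocument", xmlns = CDA_NS)
  header <- xml2::xml_add_child(doc, "header")
  patient <- xml2::xml_add_child(header, "patient")
  xml2::xml_add_child(patient, "id", record$id)
  xml2::xml_add_child(patient, "gender", record$gender)
  xml2::xml_add_child(patient, "age", format_num(record$age))
  xml2::xml_add_child(patient, "weight", format_num(record$weight))
  xml2::xml_add_child(patient, "sah", tolower(record$sah))
  xml2::xml_add_child(patient, "dm", tolower(record$dm))
  xml2::xml_add_child(header, "author", author)
  xml2::xml_add_child(header, "effectiveTime", effective_time)

  meds <- xml2::xml_add_child(doc, "medications")
  for (m in record$medications) {
    e <- xml2::xml_add_child(meds, "medication")
    xml2::xml_add_child(e, "substance", m$substance)
    if (!is.na(m$dose)) xml2::xml_add_child(e, "dose", m$dose)
    if (!is.na(m$schedule)) xml2::xml_add_child(e, "schedule", m$schedule)
  }
  algs <- xml2::xml_add_child(doc, "allergies")
  for (a in record$allergies) {
    e <- xml2::xml_add_child(algs, "allergy")
    xml2::xml_add_child(e, "substance", a$substance)
    if (!is.na(a$reaction)) xml2::xml_add_child(e, "reaction", a$reaction)
  }

  labs <- xml2::xml_add_child(doc, "labResults")
  units <- c(creatinine = "mg/dL", urea = "mg/dL", potassium = "mEq/L",
             proteinuria = "mg/g")
  for (lab in names(record$labs)) {
    v <- record$labs[[lab]]
    if (is.na(v)) next
    e <- xml2::xml_add_child(labs, "result")
    xml2::xml_add_child(e, "name", lab)
    xml2::xml_add_child(e, "value", format_num(v))
    xml2::xml_add_child(e, "unit", units[[lab]])
  }

  ev <- xml2::xml_add_child(doc, "riskEvaluation")
  if (!is.null(evaluation)) {
    xml2::xml_add_child(ev, "proteinuriaCategory", evaluation$category)
    xml2::xml_add_child(ev, "stage", evaluation$stage)
    xml2::xml_add_child(ev, "riskLevel", evaluation$risk)
    xml2::xml_add_child(ev, "gfr", format_num(evaluation$gfr_displayed))
    xml2::xml_add_child(ev, "narrative", evaluation$advice)
    xml2::xml_add_child(ev, "time", evaluation$time)
  }

  for (frag in extensions) {
    node <- xml2::read_xml(frag)
    xml2::xml_add_child(doc, node)
  }
  as.character(doc)
}

format_num <- function(x) format(x, trim = TRUE, scientific = FALSE)

#' Parse a simplified clinical document
#'
#' Recovers the record fragment, the evaluation fragment (if present) and
#' any unknown vendor sections (preserved verbatim as opaque XML strings)
#' from a document produced by [build_clinical_document()] or a compatible
#' source. `parse_clinical_document(build_clinical_document(r, e))`
#' reproduces the fields of `r` and `e`.
#'
#' @param xml XML text (character) or an `xml_document`.
#' @return List with components `record` (a [patient_record()]),
#'   `evaluation` (list of the evaluation fields, or `NULL`), `author`,
#'   `effective_time` and `extensions` (character vector of opaque XML).
#' @export
parse_clinical_document <- function(xml) {
  doc <- if (inherits(xml, "xml_document")) xml else xml2::read_xml(xml)
  ns <- c(d = CDA_NS)
  get1 <- function(node, path) {
    hit <- xml2::xml_find_first(node, path, ns)
    if (inherits(hit, "xml_missing")) NA_character_ else xml2::xml_text(hit)
  }
  patient <- xml2::xml_find_first(doc, "./d:header/d:patient", ns)
  if (inherits(patient, "xml_missing"))
    stop("header incomplete: missing patient element")
  id <- get1(patient, "./d:id")
  if (is.na(id) || !nzchar(id)) stop("header incomplete: missing patient id")
  effective_time <- get1(doc, "./d:header/d:effectiveTime")
  if (is.na(effective_time))
    stop("header incomplete: missing effectiveTime element")

  num <- function(x) if (is.na(x)) NA_real_ else as.numeric(x)
  labs <- xml2::xml_find_all(doc, "./d:labResults/d:result", ns)
  lab_vals <- list(creatinine = NA_real_, urea = NA_real_,
                   potassium = NA_real_, proteinuria = NA_real_)
  for (e in labs) lab_vals[[get1(e, "./d:name")]] <- num(get1(e, "./d:value"))

  meds <- lapply(xml2::xml_find_all(doc, "./d:medications/d:medication", ns),
                 function(e) medication(get1(e, "./d:substance"),
                                        get1(e, "./d:dose"),
                                        get1(e, "./d:schedule")))
  algs <- lapply(xml2::xml_find_all(doc, "./d:allergies/d:allergy", ns),
                 function(e) allergy(get1(e, "./d:substance"),
                                     get1(e, "./d:reaction")))

  record <- patient_record(
    id = id, gender = get1(patient, "./d:gender"),
    age = num(get1(patient, "./d:age")),
    weight = num(get1(patient, "./d:weight")),
    sah = identical(get1(patient, "./d:sah"), "true"),
    dm = identical(get1(patient, "./d:dm"), "true"),
    creatinine = lab_vals$creatinine, urea = lab_vals$urea,
    potassium = lab_vals$potassium, proteinuria = lab_vals$proteinuria,
    medications = meds, allergies = algs)

  ev_node <- xml2::xml_find_first(doc, "./d:riskEvaluation", ns)
  evaluation <- NULL
  if (!inherits(ev_node, "xml_missing") &&
      length(xml2::xml_children(ev_node)) > 0) {
    evaluation <- list(category = get1(ev_node, "./d:proteinuriaCategory"),
                       stage = get1(ev_node, "./d:stage"),
                       risk = get1(ev_node, "./d:riskLevel"),
                       gfr_displayed = num(get1(ev_node, "./d:gfr")),
                       advice = get1(ev_node, "./d:narrative"),
                       time = get1(ev_node, "./d:time"))
  }

  known <- c("header", "medications", "allergies", "labResults",
             "riskEvaluation")
  extensions <- character()
  for (child in xml2::xml_children(doc)) {
    if (!xml2::xml_name(child) %in% known)
      extensions <- c(extensions, as.character(child))
  }
  list(record = record, evaluation = evaluation,
       author = get1(doc, "./d:header/d:author"),
       effective_time = effective_time,
       extensions = extensions)
}

#' Validate a clinical document against the shipped simplified schema
#'
#' @param xml XML text or `xml_document`.
#' @return `TRUE` if valid; otherwise `FALSE` with validation messages in
#'   the `errors` attribute.
#' @export
validate_clinical_document <- function(xml) {
  doc <- if (inherits(xml, "xml_document")) xml else xml2::read_xml(xml)
  schema_path <- system.file("extdata", "cda-schema.xsd",
                             package = "ckdscreen", mustWork = TRUE)
  xml2::xml_validate(doc, xml2::read_xml(schema_path))
}
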