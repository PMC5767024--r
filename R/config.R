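#' @keywords internal
"_PACKAGE"

# Category label sets used throughout. Order encodes clinical severity.
RISK_LEVELS <- c("low", "moderate", "high", "very_high")
PROTEINURIA_CATEGORIES <- c("normal", "microalbuminuria", "albuminuria")
CKD_STAGES <- c("1", "2", "3a", "3b", "4", "5")
GLUCOSE_CONTEXTS <- c("preprandial", "postprandial", "fasting")

#' Load the threshold configuration
#'
#' All clinical cut-offs used by the package live in one structured YAML
#' configuration: biomarker reference intervals, proteinuria category
#' cut-offs, GFR stage band edges, the stage-by-albuminuria risk matrix,
#' screening intervals per risk level, and blood-pressure / glucose targets.
#' The shipped defaults follow the KDIGO CKD guideline (stage bands and risk
#' grid) and the ESH/ESC and diabetes-care guidelines (monitoring targets);
#' every value can be overridden by a user file with the same keys.
#'
#' @param path Optional path to a YAML file. Keys present in the file replace
#'   the corresponding defaults; absent keys keep their default values.
#' @return A named list with components `biomarkers`, `proteinuria`,
#'   `stage_edges`, `risk_matrix`, `screening_intervals_months`,
#'   `blood_pressure` and `glucose`.
#' @examples
#' cfg <- ckd_config()
#' cfg$biomarkers$creatinine
#' @export
ckd_config <- function(path = NULL) {
  default_path <- system.file("extdata", "default-config.yaml",
                              package = "ckdscreen", mustWork = TRUE)
  cfg <- yaml::read_yaml(default_path)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- modify_list_deep(cfg, user)
  }
  cfg$risk_matrix <- as_risk_matrix(cfg$risk_matrix)
  validate_risk_matrix(cfg$risk_matrix,
                       override = isTRUE(cfg$allow_nonmonotone_matrix))
  cfg
}

# Recursive list merge: values in `override` win, nested lists merge.
modify_list_deep <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}
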