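#' The 22-category major-depressive-disorder annotation scheme
#'
#' The scheme has three groups: 9 depressive-symptom parent categories
#' (DSM-5), 12 psychosocial-stressor parent categories (DSM-IV Axis IV,
#' enriched with the corpus-driven categories "weather" and "media"), and a
#' single "no evidence of clinical depression" label. The order is fixed and
#' is the order used to index correlation matrices and heatmap axes.
#'
#' Categories are identified by snake_case ids in serialized corpora; the
#' `label` column carries the printed display name.
#'
#' @return A tibble with columns `index`, `category` (snake_case id),
#'   `group` (factor: `"SYMPTOM"`, `"STRESSOR"`, `"NO_EVIDENCE"`) and
#'   `label` (display name).
#' @examples
#' sad_scheme()
#' @export
sad_scheme <- function() {
  sym <- c(
    depressed_mood = "Depressed mood",
    anhedonia = "Anhedonia",
    weight_change_or_appetite = "Weight change or change in appetite",
    disturbed_sleep = "Disturbed sleep",
    psychomotor_agitation_or_retardation =
      "Psychomotor agitation or retardation",
    fatigue_or_loss_of_energy = "Fatigue or loss of energy",
    worthlessness_or_guilt =
      "Feelings of worthlessness or excessive inappropriate guilt",
    diminished_ability_to_think =
      "Diminished ability to think or concentrate, indecisiveness",
    thoughts_of_death_or_suicide =
      "Recurrent thoughts of death, suicidal ideation")
  str <- c(
    expected_life_course_problems =
      "Problems with expected life course with respect to self",
    primary_support_group_problems = "Problems with primary support group",
    social_environment_problems = "Problems related to the social environment",
    educational_problems = "Educational problems",
    occupational_problems = "Occupational problems",
    housing_problems = "Housing problems",
    economic_problems = "Economic problems",
    health_care_access_problems = "Problems with access to health care",
    legal_system_problems = "Problems related to the legal system and crime",
    other_psychosocial_problems =
      "Other psychosocial and environmental problems",
    weather = "Weather",
    media = "Media")
  noe <- c(no_evidence = "No evidence of clinical depression")
  tibble::tibble(
    index = seq_len(22L),
    category = c(names(sym), names(str), names(noe)),
    group = factor(rep(c("SYMPTOM", "STRESSOR", "NO_EVIDENCE"),
                       times = c(9L, 12L, 1L)),
                   levels = c("SYMPTOM", "STRESSOR", "NO_EVIDENCE")),
    label = unname(c(sym, str, noe)))
}

#' Scheme category ids
#'
#' @param group Optional group filter: `"SYMPTOM"`, `"STRESSOR"`,
#'   `"NO_EVIDENCE"`, or `"EVIDENCE"` for the 21 symptom + stressor
#'   categories.
#' @return Character vector of category ids in scheme order.
#' @examples
#' scheme_categories("SYMPTOM")
#' @export
scheme_categories <- function(group = NULL) {
  sc <- sad_scheme()
  if (is.null(group)) return(sc$category)
  group <- match.arg(group, c("SYMPTOM", "STRESSOR", "NO_EVIDENCE", "EVIDENCE"))
  if (group == "EVIDENCE") {
    sc$category[sc$group != "NO_EVIDENCE"]
  } else {
    sc$category[sc$group == group]
  }
}

#' The no-evidence category id
#' @return The string `"no_evidence"`.
#' @keywords internal
#' @export
no_evidence_label <- function() "no_evidence"

assert_known_categories <- function(categories, where = "category") {
  bad <- setdiff(unique(categories), sad_scheme()$category)
  if (length(bad) > 0L) {
    stop(sprintf("unknown %s label(s): %s", where,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
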