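#' The 18 weekly-survey symptom indicators
#'
#' Column names of the binary symptom indicators collected by the weekly
#' acute-respiratory-symptom survey, in canonical order. Every report table
#' handled by the package carries exactly these 18 logical columns.
#'
#' @return Character vector of length 18.
#' @export
#' @examples
#' ili_symptoms()
ili_symptoms <- function() {
  c(
    "fever", "chills", "runny_or_blocked_nose", "sneezing", "cough",
    "sore_throat", "shortness_of_breath", "muscle_or_joint_pain",
    "headache", "malaise", "loss_of_appetite", "colored_phlegm",
    "watery_bloodshot_eyes", "nausea", "vomiting", "diarrhea",
    "stomach_ache", "chest_pain"
  )
}

#' Enumerated participant covariate levels
#'
#' The categorical levels accepted in roster tables, keyed by column. The
#' first level of each vector is the reference level used by the
#' participation models (female, 21-30 years, nursing, Chinese).
#'
#' @return Named list of character vectors.
#' @export
participant_levels <- function() {
  list(
    gender = c("female", "male"),
    age_group = c("21-30", "31-40", "41-50", ">50"),
    job_category = c(
      "nursing", "administration_other", "ancillary", "allied_health",
      "medical"
    ),
    ethnicity = c("chinese", "other"),
    hospital = c("TTSH", "KKH")
  )
}

participant_bool_fields <- function() {
  c(
    "children_in_household", "vaccinated_past_year", "allergy",
    "registration_complete", "background_complete"
  )
}

# Covariates entering the multivariable participation models, in the order
# they are reported.
model_covariates <- function() {
  c(
    "gender", "age_group", "job_category", "ethnicity",
    "children_in_household", "vaccinated_past_year", "allergy"
  )
}
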