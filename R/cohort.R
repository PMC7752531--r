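#' Apply the enrollment exclusion filter
#'
#' Removes participants who never completed app registration, then those who
#' did not submit a full background survey, mirroring the two-stage exclusion
#' applied before cohort analysis. The order of remaining rows is preserved
#' and the operation is idempotent.
#'
#' @param roster Roster tibble ([load_roster()] / [simulate_roster()]).
#' @return A list with `cohort` (the analysis roster) and `exclusion_log`, a
#'   tibble of `reason, n` with one row per exclusion stage.
#' @examples
#' r <- simulate_roster(sim_config(n_participants = 20, seed = 1))
#' apply_exclusions(r)$exclusion_log
#' @export
apply_exclusions <- function(roster) {
  reg_incomplete <- !roster$registration_complete
  stage1 <- roster[!reg_incomplete, , drop = FALSE]
  bg_incomplete <- !stage1$background_complete
  cohort <- stage1[!bg_incomplete, , drop = FALSE]
  log <- tibble::tibble(
    reason = c("registration_incomplete", "background_incomplete"),
    n = c(sum(reg_incomplete), sum(bg_incomplete))
  )
  list(cohort = cohort, exclusion_log = log)
}
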