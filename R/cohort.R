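# Cohort clinical summary: category/symptom/age-band/treatment rates from
# per-subject records.

COHORT_LEVELS <- list(
  sex = c("male", "female"),
  onset_band = c("<6", "6-12", "12-18"),
  diagnosis = c("TS", "CTD", "PTD"),
  symptoms = c("blinking", "grimacing", "throat_clearing", "shrug",
               "head_shake", "spit"),
  prior_drugs = c("0", "1", "2", "3", "4"))

#' Summarize a tic-disorder cohort
#'
#' Produces a clinical summary table (variable, level, count, rate in
#' percent of the cohort) from per-subject records: sex, age band at
#' onset, DSM-V diagnostic category, tic symptoms (multi-label), and
#' number of previously tried medications.  Every level is reported even
#' at count zero; rates are percentages of the cohort size rounded to two
#' decimals.  Exclusive variables therefore sum to the cohort size while
#' symptom rates need not.
#'
#' @param cohort data frame with columns `subject_id`, `sex`
#'   (`male`/`female`), `onset_band` (`<6`, `6-12`, `12-18`), `diagnosis`
#'   (`TS`/`CTD`/`PTD`), `symptoms` (comma-separated subset of
#'   `blinking, grimacing, throat_clearing, shrug, head_shake, spit`),
#'   `prior_drugs` (0..4).
#' @return data frame with columns `variable`, `level`, `count`,
#'   `rate_percent`.
#' @examples
#' summarize_cohort(synth_cohort(seed = 1))
#' @export
summarize_cohort <- function(cohort) {
  if (!nrow(cohort)) stop("empty cohort")
  n <- nrow(cohort)
  one <- function(variable, values, levels) {
    count <- vapply(levels, function(l) sum(values == l), integer(1))
    data.frame(variable = variable, level = levels, count = unname(count),
               rate_percent = round(100 * unname(count) / n, 2),
               stringsAsFactors = FALSE)
  }
  sym <- strsplit(as.character(cohort$symptoms), "[,;] *")
  sym_count <- vapply(COHORT_LEVELS$symptoms, function(s) {
    sum(vapply(sym, function(x) s %in% x, logical(1)))
  }, integer(1))
  rbind(
    one("sex", cohort$sex, COHORT_LEVELS$sex),
    one("onset_band", cohort$onset_band, COHORT_LEVELS$onset_band),
    one("diagnosis", cohort$diagnosis, COHORT_LEVELS$diagnosis),
    data.frame(variable = "symptom", level = COHORT_LEVELS$symptoms,
               count = unname(sym_count),
               rate_percent = round(100 * unname(sym_count) / n, 2),
               stringsAsFactors = FALSE),
    one("prior_drugs", as.character(cohort$prior_drugs), COHORT_LEVELS$prior_drugs))
}

#' Read a cohort table
#'
#' @param path TSV with the columns described in [summarize_cohort()].
#' @return data frame of subject records.
#' @export
read_cohort <- function(path) {
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "onset_band", "diagnosis", "symptoms",
            "prior_drugs")
  if (!all(need %in% names(x))) {
    stop("cohort table must have columns: ", paste(need, collapse = ", "))
  }
  x
}
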