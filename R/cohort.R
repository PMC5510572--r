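# Clinical cohort table: parsing, onset statistics, carrier counts, and the
# penetrance estimate.

#' Read a clinical cohort table
#'
#' The cohort schema is one row per individual:
#' `pedigree_id`, `pedigree_label`, `phenotype_class` (pedigree-level
#' phenotype), `status` (`affected` / `unaffected_carrier`), `sex`,
#' `age_onset`, `age_diagnosis` (years; `na`/`nk`/empty map to missing,
#' fractional ages are preserved), `tumor_size`, `diagnosis`.
#'
#' @param path TSV file path.
#' @return A tibble of class `cohort_table`.
#' @seealso [aip_cohort()] for the bundled worked-example table.
#' @export
read_cohort_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, na = c("", "na", "nk", "NA"),
                       col_types = readr::cols(
                         pedigree_id = "i", pedigree_label = "c",
                         phenotype_class = "c", status = "c", sex = "c",
                         age_onset = "d", age_diagnosis = "d",
                         tumor_size = "c", diagnosis = "c"))
  bad <- setdiff(unique(x$status), c("affected", "unaffected_carrier"))
  if (length(bad)) abort(paste0("Unknown status value(s): ", paste(bad, collapse = ", ")))
  if (any(stats::na.omit(c(x$age_onset, x$age_diagnosis)) < 0)) {
    abort("Ages must be >= 0.")
  }
  class(x) <- c("cohort_table", class(x))
  x
}

#' The AIP c.805_825dup cohort table
#'
#' The bundled transcription of the worked example's clinical table: nine
#' pedigrees carrying the AIP c.805_825dup allele, with 16 affected
#' individuals and 9 unaffected carriers. Onset and diagnosis ages are in
#' years; 15 affected individuals have a recorded onset age.
#'
#' @return A `cohort_table` tibble.
#' @export
#' @examples
#' summarize_onset(aip_cohort())
aip_cohort <- function() {
  read_cohort_table(system.file("extdata", "aip_cohort_table1.tsv",
                                package = "founderhap", mustWork = TRUE))
}

#' Onset-age statistics over affected individuals
#'
#' Summarizes the age at symptom onset over all affected individuals with a
#' recorded onset; individuals with missing onset are excluded from the
#' statistics (but still count as affected).
#'
#' @param table A `cohort_table` (or compatible data frame).
#' @return A one-row tibble: `mean`, `median`, `min`, `max`, `n_with_onset`.
#' @export
summarize_onset <- function(table) {
  onset <- table$age_onset[table$status == "affected" & !is.na(table$age_onset)]
  if (length(onset) == 0L) abort("No affected individual has a recorded onset age.")
  tibble::tibble(mean = mean(onset), median = median(onset),
                 min = min(onset), max = max(onset),
                 n_with_onset = length(onset))
}

#' Count affected and unaffected carriers
#'
#' @param table A `cohort_table`.
#' @return A one-row tibble: `n_affected`, `n_unaffected_carriers`.
#' @export
count_carriers <- function(table) {
  tibble::tibble(
    n_affected = sum(table$status == "affected"),
    n_unaffected_carriers = sum(table$status == "unaffected_carrier"))
}

#' Penetrance with half-weighting of untyped at-risk relatives
#'
#' Estimates penetrance as
#' `n_affected / (n_affected + n_genotyped_unaffected_carriers +
#' 0.5 * n_untyped_at_risk)`, i.e. assuming half of the at-risk relatives
#' who were not genotyped carry the allele.
#'
#' @param n_affected Affected carriers.
#' @param n_genotyped_unaffected_carriers Genotyped unaffected carriers.
#' @param n_untyped_at_risk At-risk relatives never genotyped.
#' @return Penetrance as a fraction in `[0, 1]`.
#' @export
#' @examples
#' estimate_penetrance(3, 10, 0)  # 3/13
estimate_penetrance <- function(n_affected, n_genotyped_unaffected_carriers,
                                n_untyped_at_risk = 0) {
  n_affected <- check_count(n_affected, "n_affected")
  n_genotyped_unaffected_carriers <-
    check_count(n_genotyped_unaffected_carriers, "n_genotyped_unaffected_carriers")
  n_untyped_at_risk <- check_count(n_untyped_at_risk, "n_untyped_at_risk")
  denom <- n_affected + n_genotyped_unaffected_carriers + 0.5 * n_untyped_at_risk
  if (denom <= 0) abort("Penetrance denominator must be positive.")
  n_affected / denom
}
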