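#' Published summary tables from the CAVAS / HEXA D_CCN analysis
#'
#' Small transcriptions of the published cohort-level summary values that
#' accompany the method: cohort sizes, case counts and person-years; the
#' top-10 hub foods of each group network with consumer counts and raw
#' centralities; the top-5 foods of each differential subnetwork with
#' integrated centralities and network roles; and the quartile-level
#' incidence-rate-ratio table. The restricted individual-level cohort data
#' are not included — these tables only carry the printed aggregate values,
#' which the package uses for arithmetic consistency checks (crude rates,
#' consumer percentages, case-count conservation) and for validating the
#' role-classification hierarchy against the published role labels.
#'
#' @param which One of `"cohort_summary"`, `"hub_food_consumers"`,
#'   `"differential_hub_centralities"`, `"quartile_irr"`.
#' @return The requested table as a tibble.
#' @export
published_table <- function(which = c("cohort_summary",
                                      "hub_food_consumers",
                                      "differential_hub_centralities",
                                      "quartile_irr")) {
  which <- match.arg(which)
  path <- system.file(
    "extdata", paste0(which, "_published.csv"), package = "dccn",
    mustWork = TRUE
  )
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
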