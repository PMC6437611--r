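#' Published Armenia benchmark tables
#'
#' Point summaries transcribed from the published 2012-2016 biobehavioural
#' survey size-estimation study of female sex workers (FSW), men who have sex
#' with men (MSM), and people who inject drugs (PWID) in Yerevan, Gyumri and
#' Vanadzor. The survey microdata were never deposited; only these printed
#' summaries are available, and they serve as reference inputs for the
#' assessment rules and method comparisons.
#'
#' `armenia_table1()` holds the expert reference values (minimum expert low,
#' averaged expert median used as the prior median, maximum expert high),
#' the reported posterior quantiles of the population size, and the published
#' fit assessment for each of the 15 datasets.
#'
#' `armenia_table2()` holds the published point estimates from the comparison
#' methods: unique-object multiplier, service multiplier, wisdom of the
#' crowds (WOC), and the size model with and without visibility imputation.
#' The `no_fit` flag marks datasets where the model without visibility
#' imputation failed to converge; `NA` marks values that could not be
#' computed because the needed questions were not asked.
#'
#' @return a tibble.
#' @export
armenia_table1 <- function() {
  path <- system.file("extdata", "armenia_table1.csv", package = "rdsize",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname armenia_table1
#' @export
armenia_table2 <- function() {
  path <- system.file("extdata", "armenia_table2.csv", package = "rdsize",
                      mustWork = TRUE)
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          sspse_no_visibility = readr::col_character()))
  dplyr::mutate(
    tb,
    no_fit = !is.na(.data$sspse_no_visibility) &
      .data$sspse_no_visibility == "No fit",
    sspse_no_visibility = suppressWarnings(
      as.numeric(.data$sspse_no_visibility)))
}
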