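#' Published group-mean trait table for two spiny lobster species
#'
#' Reported group means (with 95% confidence intervals and group sizes) of
#' metabolic traits for the resident southern rock lobster *Jasus edwardsii*
#' and the range-shifting eastern rock lobster *Sagmariasus verreauxi*
#' acclimated to 14.0 / 17.5 / 21.5 degC. Traits: SMR (mg O2 h^-1 kg^-1, at
#' 21.5 degC experimental temperature), EPOC (mg O2 kg^-1), recovery time
#' (h), recovery rate (mg O2 h^-1 kg^-1) -- each per acclimation group --
#' and species-pooled aerobic scope and MMR (mg O2 h^-1 kg^-1). Rows with
#' missing `acclimation_temp` are pooled across acclimation groups; rows
#' with missing `experimental_temp` are averaged across experimental
#' temperatures. Useful for worked-example contrasts and divergence
#' arithmetic without access to the raw trial data.
#'
#' @return A tibble with columns `species`, `trait`, `acclimation_temp`,
#'   `experimental_temp`, `mean`, `ci_low`, `ci_high`, `n`.
#' @examples
#' ref <- reference_trait_means()
#' subset(ref, trait == "recovery_rate")
#' @export
reference_trait_means <- function() {
  path <- system.file("extdata", "reference_trait_means.csv",
    package = "flipscope", mustWork = TRUE
  )
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
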