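# Thermal sensitivity and group-level comparison of trait tables: Q10
# coefficients, mean/95% CI summaries, species divergence and acclimation
# contrasts. All functions take a tidy trait table (one row per trial) or
# two endpoint means and return tibbles.

#' Q10 thermal coefficient
#'
#' The factor by which a rate increases per 10 degC rise:
#' \deqn{Q_{10} = (R_2 / R_1)^{10 / (T_2 - T_1)}}
#'
#' @param r1,r2 Trait means (must be positive) at temperatures `t1`, `t2`.
#' @param t1,t2 Temperatures, degC (`t1 != t2`). Vectorised.
#' @return Q10, dimensionless.
#' @examples
#' q10(10, 20, 14, 24) # exact doubling over 10 degC -> 2
#' @export
q10 <- function(r1, r2, t1, t2) {
  if (any(r1 <= 0 | r2 <= 0)) abort("Rates must be positive to compute Q10.")
  if (any(t1 == t2)) abort("Q10 is undefined for equal temperatures.")
  (r2 / r1)^(10 / (t2 - t1))
}

#' Q10 table from endpoint group means
#'
#' Computes Q10 per trait and group from the trait means at the two endpoint
#' experimental temperatures (default 14.0 and 21.5 degC), matching the
#' convention of computing thermal coefficients from data means over the
#' experimental range rather than from a log-linear fit.
#'
#' @param trait_table Tidy table with an `experimental_temp` column and one
#'   column per trait.
#' @param traits Character vector of trait column names.
#' @param t1,t2 Endpoint temperatures, degC.
#' @param by Grouping columns (e.g. species, acclimation_temp).
#' @return A tibble with the group keys, `trait`, `r1`, `r2`, `t1`, `t2`
#'   and `q10`.
#' @export
q10_table <- function(trait_table, traits, t1 = 14, t2 = 21.5,
                      by = c("species", "acclimation_temp")) {
  means <- trait_table %>%
    filter(.data$experimental_temp %in% c(t1, t2)) %>%
    group_by(across(all_of(c(by, "experimental_temp")))) %>%
    summarise(across(all_of(traits), ~ mean(.x, na.rm = TRUE)), .groups = "drop") %>%
    tidyr::pivot_longer(all_of(traits), names_to = "trait", values_to = "mean") %>%
    tidyr::pivot_wider(
      names_from = "experimental_temp", values_from = "mean",
      names_prefix = "T"
    )
  cn <- c(paste0("T", t1), paste0("T", t2))
  if (!all(cn %in% names(means))) {
    abort("Both endpoint temperatures must be present in the trait table.")
  }
  means %>%
    rename(r1 = all_of(cn[1]), r2 = all_of(cn[2])) %>%
    mutate(t1 = t1, t2 = t2, q10 = q10(.data$r1, .data$r2, t1, t2))
}

#' Group means with 95% confidence intervals
#'
#' Mean and t-distribution 95% CI per group and trait. Groups of size 1
#' have undefined CIs and are flagged, not dropped.
#'
#' @param trait_table Tidy trait table.
#' @param keys Grouping columns.
#' @param traits Trait column names.
#' @param conf_level Confidence level.
#' @return A long tibble with keys, `trait`, `n`, `mean`, `ci_low`,
#'   `ci_high` and `ci_defined`.
#' @export
group_summaries <- function(trait_table, keys, traits, conf_level = 0.95) {
  long <- trait_table %>%
    tidyr::pivot_longer(all_of(traits), names_to = "trait", values_to = "value") %>%
    filter(!is.na(.data$value))
  if (nrow(long) == 0) abort("No non-missing trait values to summarise.")
  long %>%
    group_by(across(all_of(c(keys, "trait")))) %>%
    summarise(
      n = n(),
      mean = mean(.data$value),
      .half = ifelse(
        n() > 1,
        qt(1 - (1 - conf_level) / 2, n() - 1) * sd(.data$value) / sqrt(n()),
        NA_real_
      ),
      .groups = "drop"
    ) %>%
    mutate(
      ci_low = .data$mean - .data$.half,
      ci_high = .data$mean + .data$.half,
      ci_defined = !is.na(.data$.half)
    ) %>%
    select(-".half")
}

#' Relative divergence of one species from a reference species
#'
#' Percent difference of pooled trait means of a comparison species relative
#' to a reference species,
#' \eqn{100 (\bar{x}_{comp} / \bar{x}_{ref} - 1)}, computed per trait within
#' each pooling cell (by default per acclimation temperature).
#'
#' @param trait_table Tidy trait table with a `species` column.
#' @param traits Trait column names.
#' @param reference_species,comparison_species Species labels.
#' @param pool_by Pooling columns (may be empty for a grand pooled mean).
#' @return A tibble with the pooling keys, `trait`, `mean_reference`,
#'   `mean_comparison` and `divergence_pct`.
#' @export
relative_divergence <- function(trait_table, traits,
                                reference_species, comparison_species,
                                pool_by = "acclimation_temp") {
  means <- trait_table %>%
    filter(.data$species %in% c(reference_species, comparison_species)) %>%
    group_by(across(all_of(c("species", pool_by)))) %>%
    summarise(across(all_of(traits), ~ mean(.x, na.rm = TRUE)), .groups = "drop") %>%
    tidyr::pivot_longer(all_of(traits), names_to = "trait", values_to = "mean")
  ref <- means %>%
    filter(.data$species == reference_species) %>%
    select(-"species") %>%
    rename(mean_reference = "mean")
  comp <- means %>%
    filter(.data$species == comparison_species) %>%
    select(-"species") %>%
    rename(mean_comparison = "mean")
  joined <- inner_join(ref, comp, by = c(pool_by, "trait"))
  if (nrow(joined) < nrow(ref) || nrow(joined) < nrow(comp)) {
    abort("Both species must be present in every pooled cell.")
  }
  if (any(joined$mean_reference <= 0)) {
    abort("Reference means must be positive to express divergence in percent.")
  }
  joined %>%
    mutate(divergence_pct = 100 * (.data$mean_comparison / .data$mean_reference - 1))
}

#' Acclimation contrast: percent decrease from cold to warm acclimation
#'
#' \eqn{100 (1 - \bar{x}_{warm} / \bar{x}_{cold})} for one trait, optionally
#' within groups.
#'
#' @param trait_table Tidy trait table with an `acclimation_temp` column.
#' @param trait Trait column name.
#' @param warm_temp,cold_temp Acclimation temperatures to contrast, degC.
#' @param by Optional grouping columns.
#' @return A tibble with any group keys, `mean_cold`, `mean_warm` and
#'   `decrease_pct`.
#' @export
acclimation_contrast <- function(trait_table, trait, warm_temp, cold_temp,
                                 by = NULL) {
  means <- trait_table %>%
    filter(.data$acclimation_temp %in% c(warm_temp, cold_temp)) %>%
    group_by(across(all_of(c(by, "acclimation_temp")))) %>%
    summarise(
      mean = mean(.data[[trait]], na.rm = TRUE),
      .groups = "drop"
    ) %>%
    tidyr::pivot_wider(names_from = "acclimation_temp", values_from = "mean")
  cw <- as.character(c(cold_temp, warm_temp))
  if (!all(cw %in% names(means))) {
    abort("Both acclimation groups must be present.")
  }
  out <- means %>%
    rename(mean_cold = all_of(cw[1]), mean_warm = all_of(cw[2]))
  if (any(out$mean_cold <= 0)) {
    abort("Cold-acclimation mean must be positive.")
  }
  out %>% mutate(decrease_pct = 100 * (1 - .data$mean_warm / .data$mean_cold))
}
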