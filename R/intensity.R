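#' Standardized environmental-change-driver intensity
#'
#' Standardizes a compound concentration against its environmental quality
#' criterion: intensity = log(conc_treatment / conc_criteria).  Zero means the
#' observed level is exactly at the criterion; negative values are below the
#' criterion (considered safe), positive values above it.  Both concentrations
#' must be in the same units.
#'
#' @param conc_treatment Observed concentration(s) at the treatment or
#'   impacted site (> 0).
#' @param conc_criteria Environmental quality criterion concentration(s),
#'   same units (> 0).
#' @param log_base Logarithm base, 10 (default: one intensity unit is one
#'   order of magnitude) or `exp(1)`.
#' @return Standardized intensity, same length as the inputs.
#' @export
ecd_intensity <- function(conc_treatment, conc_criteria, log_base = 10) {
  if (any(conc_treatment <= 0) || any(conc_criteria <= 0)) {
    abort("Concentrations must be strictly positive.")
  }
  log(conc_treatment / conc_criteria, base = log_base)
}

#' Dominant compound intensity
#'
#' With multiple stressors or nutrients reported for one observation, the
#' analysis uses the compound with the highest standardized intensity.  Ties
#' are broken by input order (first compound wins) and reported.
#'
#' @param compounds Data frame with columns `compound`, `conc_treatment`,
#'   `conc_criteria`.
#' @inheritParams ecd_intensity
#' @return A one-row tibble with `compound` and `intensity`.
#' @export
max_intensity <- function(compounds, log_base = 10) {
  compounds <- tibble::as_tibble(compounds)
  if (nrow(compounds) == 0) abort("Need at least one compound level.")
  ints <- ecd_intensity(compounds$conc_treatment, compounds$conc_criteria,
                        log_base = log_base)
  i <- which.max(ints)  # first maximum on ties
  if (sum(ints == ints[i]) > 1L) {
    inform(sprintf("Intensity tie: keeping first compound '%s'.",
                   compounds$compound[i]))
  }
  tibble::tibble(compound = compounds$compound[i], intensity = ints[i])
}

#' Join standardized intensities onto an effect-size table
#'
#' Computes the per-observation dominant compound intensity and adds it as an
#' `intensity` column (with the selected `intensity_compound`).
#'
#' @param effects Effect-size tibble with an `obs_id` column (see
#'   [build_effect_table()]).
#' @param compound_levels Data frame with one row per (observation, compound):
#'   columns `obs_id`, `compound`, `conc_treatment`, `conc_criteria`.
#' @inheritParams ecd_intensity
#' @return `effects` with `intensity` and `intensity_compound` columns;
#'   observations absent from `compound_levels` get `NA`.
#' @export
add_intensity <- function(effects, compound_levels, log_base = 10) {
  compound_levels <- tibble::as_tibble(compound_levels)
  picked <- compound_levels |>
    dplyr::group_by(.data$obs_id) |>
    dplyr::group_modify(~ max_intensity(.x, log_base = log_base)) |>
    dplyr::ungroup() |>
    dplyr::rename(intensity_compound = "compound")
  dplyr::left_join(effects, picked, by = "obs_id")
}
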