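# Published reference values shipped as data: period summaries and lake
# metadata for two Andean lakes in Cajas National Park (remote
# high-elevation Lake Fondococha, peri-urban Lake Llaviucu), used in worked
# examples and as fixed inputs for desk-reproducible checks.

#' Published period summaries for the two reference Andean lakes
#'
#' Period-mean concentrations (ug g^-1 dry sediment) and fluxes (published
#' in mg m^-2 yr^-1, converted here to the package's internal
#' ug m^-2 yr^-1) for the pre-1950 and post-1950 periods, the published
#' post/pre Factor, and the "Recent" mean of the two topmost samples.
#' The published Factor columns were computed from unrounded data and are
#' kept separately (`conc_factor_printed`, `flux_factor_printed`) so they
#' can be compared with factors recomputed from the printed means.
#'
#' @return named list of two `period_summary`-like data.frames
#'   (`fondococha`, `llaviucu`) with columns `element`, `conc_pre`,
#'   `conc_post`, `conc_recent`, `flux_pre`, `flux_post`, `flux_recent`
#'   (ug m^-2 yr^-1) plus the printed factors.
#' @export
andes_reference_summaries <- function() {
  load1 <- function(fname) {
    d <- utils::read.csv(system.file("extdata", fname,
                                     package = "limnotrace", mustWork = TRUE))
    for (k in c("pre", "post", "recent")) {
      d[[paste0("flux_", k)]] <- flux_as_ug(d[[paste0("flux_", k, "_mg")]])
      d[[paste0("flux_", k, "_mg")]] <- NULL
    }
    structure(d, class = c("period_summary", "data.frame"))
  }
  list(fondococha = load1("fondococha_summary.csv"),
       llaviucu = load1("llaviucu_summary.csv"))
}

#' Metadata of the two reference lakes
#'
#' @return named list of two [lake_metadata()] objects: remote
#'   high-elevation Lake Fondococha (3.4 ha, 0.6 km^2 catchment) and
#'   peri-urban Lake Llaviucu (18.9 ha, 47.7 km^2 catchment), both cored
#'   in 2014.
#' @export
andes_reference_lakes <- function() {
  list(
    fondococha = lake_metadata("Fondococha", coring_year = 2014,
                               lake_area_ha = 3.4,
                               catchment_area_km2 = 0.6,
                               elevation_m = 4130,
                               notes = "remote, Paramo grassland"),
    llaviucu = lake_metadata("Llaviucu", coring_year = 2014,
                             lake_area_ha = 18.9,
                             catchment_area_km2 = 47.7,
                             elevation_m = 3140,
                             notes = "peri-urban, montane forest"))
}
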