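#' Published annual fire-exposure proxies for the Pantanal jaguar population
#'
#' Regional summary series bundled with the package: for each year
#' 2005-2020 and region (the Pantanal ecoregion and its Brazilian,
#' Paraguayan and Bolivian parts), the published density-weighted proxy
#' count of jaguars in fire-affected cells (`proxy_affected`) and the
#' proxy total population of the region (`proxy_total`). These printed
#' values let the summary arithmetic — reference medians, factor effects,
#' regional shares, percentages of population affected — be reproduced
#' without the multi-gigabyte fire archive, density raster and telemetry
#' deposits the full pipeline consumes.
#'
#' @return Data frame with columns `year`, `region`, `proxy_affected`,
#'   `proxy_total`.
#' @export
pantanal_proxy_series <- function() {
  utils::read.csv(system.file("extdata", "pantanal_fire_proxies.csv",
                              package = "firetrack"),
                  stringsAsFactors = FALSE)
}

#' Published 2020 home-range and protected-area fire totals
#'
#' Headline 2020 totals for the tracked jaguar cohort: number of
#' home ranges monitored and affected by fire, protected-area extent
#' within home ranges (km²), the part of it burned, and the Brazilian
#' share of that burned extent.
#'
#' @return Named numeric vector (`hr_total`, `hr_affected`,
#'   `pa_within_hr_km2`, `pa_within_hr_burned_km2`,
#'   `pa_within_hr_burned_brazil_km2`).
#' @export
pantanal_hr_summary <- function() {
  d <- utils::read.csv(system.file("extdata", "pantanal_hr_fire_2020.csv",
                                   package = "firetrack"),
                       stringsAsFactors = FALSE)
  stats::setNames(d$value, d$quantity)
}
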