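#' Published pan-tropical biome shares
#'
#' Reference per-biome percentage shares of tropical land area, field
#' sampling locations and study citations, with location/citation densities
#' (per 10^5 km^2) and the citation:sampling ratio, as reported for a
#' pan-tropical geocoded literature database of 2738 articles, 6370 sampling
#' locations and 89,468 citations in natural terrestrial habitats. Shipped
#' as a plain-text table and used by the acceptance checks to exercise the
#' share/ratio arithmetic of [biome_summary()].
#'
#' @return A tibble with one row per biome: `biome`, `pct_area`,
#'   `pct_locations`, `loc_density`, `pct_citations`, `cit_density`,
#'   `ratio`.
#' @export
published_biome_shares <- function() {
  path <- system.file("extdata", "tropical_biome_shares.csv",
                      package = "tropirep", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
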