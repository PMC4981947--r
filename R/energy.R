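#' Fraction of primary production exported by flamingo grazing
#'
#' The energy-export arithmetic for a soda lake dominated by filter-feeding
#' flamingos: of the fraction of daily primary production they ingest, only a
#' part returns to the lake (faeces, carcasses); the rest is metabolised or
#' carried to the terrestrial ecosystem. The exported share is
#' `ingested * (1 - returned)` — e.g. ingestion of 60% of production with one
#' third returned removes 40% of daily primary production from the aquatic
#' food web.
#'
#' @param ingested fraction of daily primary production ingested, in `[0, 1]`.
#' @param returned fraction of the ingested biomass returned to the lake,
#'   in `[0, 1]`.
#' @return Export fraction in `[0, 1]`.
#' @examples
#' export_fraction(0.60, 1/3)
#' @export
export_fraction <- function(ingested, returned) {
  assert_number(ingested, "ingested", lower = 0, upper = 1)
  assert_number(returned, "returned", lower = 0, upper = 1)
  ingested * (1 - returned)
}

#' Lake energy budget summary
#'
#' @param ingested,returned see [export_fraction()].
#' @return Object of class `energy_budget` with the three fractions.
#' @export
energy_budget <- function(ingested, returned) {
  structure(list(ingested = ingested, returned = returned,
                 export = export_fraction(ingested, returned)),
            class = "energy_budget")
}

#' @export
print.energy_budget <- function(x, ...) {
  cat(sprintf(
    "Energy budget: %.0f%% of daily primary production ingested, %.0f%% of that returned -> %.0f%% removed from the aquatic food web\n",
    100 * x$ingested, 100 * x$returned, 100 * x$export))
  invisible(x)
}
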