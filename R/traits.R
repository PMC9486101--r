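#' The 19-trait yield-component vocabulary
#'
#' Controlled vocabulary of the yield-related traits admitted in the QTL
#' catalog. Each trait belongs to one of the two main yield components:
#' grains number per unit area (\code{"grain_number"}) or grain weight
#' (\code{"grain_weight"}).
#'
#' @return A data.frame with columns \code{code}, \code{name} and
#'   \code{category} (19 rows).
#' @examples
#' tv <- trait_vocabulary()
#' nrow(tv)          # 19
#' table(tv$category)
#' @export
trait_vocabulary <- function() {
  gn <- rbind(
    c("GNPS", "Grain number per spike"),
    c("GNP",  "Grain number per plant"),
    c("SNP",  "Spike number per plant"),
    c("SLNS", "Spikelet number per spike"),
    c("GNSL", "Grain number per spikelet"),
    c("GY",   "Grain yield"),
    c("SNM",  "Spike number per m2"),
    c("HI",   "Harvest index"),
    c("GNM",  "Grain number per m2"),
    c("GYPS", "Grain yield per spike")
  )
  gw <- rbind(
    c("SL",   "Spike length"),
    c("SW",   "Spike width"),
    c("GL",   "Grain length"),
    c("GW",   "Grain width"),
    c("TGW",  "Thousand grain weight"),
    c("TW",   "Test weight"),
    c("GP",   "Grain perimeter"),
    c("GA",   "Grain area"),
    c("GWPS", "Grain weight per spike")
  )
  data.frame(
    code = c(gn[, 1], gw[, 1]),
    name = c(gn[, 2], gw[, 2]),
    category = rep(c("grain_number", "grain_weight"), c(nrow(gn), nrow(gw))),
    stringsAsFactors = FALSE
  )
}

#' Look up the yield-component category of trait codes
#'
#' @param trait character vector of trait codes.
#' @return Character vector, \code{"grain_number"} or \code{"grain_weight"};
#'   \code{NA} for codes outside the vocabulary.
#' @export
trait_category <- function(trait) {
  tv <- trait_vocabulary()
  tv$category[match(trait, tv$code)]
}

# Population designs the CI formulas cover, and the wheat chromosome set.
POP_TYPES <- c("RIL", "DH", "F2", "F2:3", "BC", "MAGIC")
CHROMOSOMES <- paste0(rep(1:7, each = 2), c("A", "B"))
REGIMES <- c("irrigated", "rainfed")
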