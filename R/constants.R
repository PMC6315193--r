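#' Versioned numeric constants used across the pipeline
#'
#' Central, documented store for every calibrated constant so that the
#' provenance of each number is auditable in one place.
#'
#' @section Digital DDH calibration:
#' `dddh_glm` holds the coefficients of the logistic transform mapping the
#' identity-based intergenomic distance (formula `d4`, i.e. one minus the
#' fraction of identical columns over all retained HSP columns) to a DDH
#' analog percentage: `dDDH = 100 / (1 + exp(a + b * d))`. The coefficients
#' are this package's own calibration, anchored at two fixed points: an
#' essentially complete hybridization signal for identical genomes
#' (dDDH = 99.9 at d = 0) and the published species-boundary correspondence
#' between 70% DDH and 95% average nucleotide identity (dDDH = 70 at
#' d = 0.05). They are not the coefficients fitted by the Genome-to-Genome
#' Distance Calculator; absolute dDDH values from different calibrations are
#' therefore not interchangeable, although threshold behaviour at the species
#' boundary is aligned by construction.
#'
#' @section Karlin-Altschul constants:
#' Ungapped nucleotide constants for +1/-2 scoring (`lambda` 1.33, `K` 0.621)
#' and gapped BLOSUM62 11/1 constants (`lambda` 0.267, `K` 0.041), used only
#' to place raw scores on a bit scale for E-value filtering.
#'
#' @return A named list of constants (invisibly used by the package).
#' @export
pd_constants <- function() {
  list(
    dddh_glm = list(
      a = log(1 / 0.999 - 1),                       # -6.9068: dDDH(0) = 99.9
      b = (log(1 / 0.70 - 1) - log(1 / 0.999 - 1)) / 0.05,  # dDDH(0.05) = 70
      distance_formula = "d4",
      source = "phylodelim calibration v1 (anchors: 99.9% at d=0; 70% at d=0.05)"
    ),
    karlin = list(
      nucleotide = list(lambda = 1.33, K = 0.621),
      protein    = list(lambda = 0.267, K = 0.041)
    ),
    gbdp_max_distance = c(d0 = 1, d4 = 1, d5 = 10, d6 = 1),
    version = "phylodelim-constants-1"
  )
}
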