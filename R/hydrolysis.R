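#' Conditions for the RNA hydrolysis lifetime estimate
#'
#' @param temperature degC.
#' @param pH Solution pH.
#' @param mg Mg2+, mM.
#' @param monovalent Monovalent cations, mM.
#' @param n Strand length in nucleotides (n - 1 cleavable linkages).
#' @return A `hydrolysis_conditions` list.
#' @export
#' @examples
#' # the deployed chamber conditions (45 degC, pH 7 Tris buffer, 61mer)
#' hydrolysis_conditions()
hydrolysis_conditions <- function(temperature = 45, pH = 7, mg = 0.05,
                                  monovalent = 8.9, n = 61) {
  if (pH <= 0 || pH >= 14) stop("hydrolysis_conditions: pH out of range",
                                call. = FALSE)
  if (n < 2) stop("hydrolysis_conditions: need n >= 2", call. = FALSE)
  structure(list(temperature = temperature, pH = pH, mg = mg,
                 monovalent = monovalent, n = n),
            class = "hydrolysis_conditions")
}

## Reference per-linkage cleavage rate (1/s) at 45 degC, pH 7, trace Mg:
## anchored so a 61mer has a 83-day half-life under the deployed chamber
## conditions. The implied per-linkage rate (9.7e-8 /min at 45 degC;
## ~6e-9 /min extrapolated to 23 degC with Ea = 100 kJ/mol) is within the
## spread of published transesterification measurements at pH 7.
.K_REF <- log(2) / (83 * 86400 * 60)
.T_REF <- 45
.PH_REF <- 7
.EA_HYDROLYSIS <- 1e5          # J/mol, mid-range literature activation energy

#' RNA strand half-life from base-catalysed backbone cleavage
#'
#' First-order per-linkage transesterification rate, log-linear in pH
#' (specific-base catalysis), Arrhenius in temperature (activation energy
#' 100 kJ/mol), with an optional linear Mg2+ catalysis term (negligible at
#' the deployed 50 uM and off by default). The strand cleavage rate is
#' `(n - 1) k` and the half-life `ln 2 / ((n - 1) k)`.
#'
#' @param cond A [hydrolysis_conditions()].
#' @param mg_alpha Linear Mg2+ catalysis coefficient, 1/mM (default 0).
#' @return Half-life in days; attribute `"flagged"` marks conditions outside
#'   the rate law's comfortable range (pH outside 5-9 or temperature above
#'   90 degC).
#' @export
#' @examples
#' rna_half_life(hydrolysis_conditions()) # ~83 days
#' rna_half_life(hydrolysis_conditions(pH = 8)) # 10x shorter
rna_half_life <- function(cond, mg_alpha = 0) {
  stopifnot(inherits(cond, "hydrolysis_conditions"))
  TK <- cond$temperature + 273.15
  T0 <- .T_REF + 273.15
  k <- .K_REF *
    10^(cond$pH - .PH_REF) *
    exp(-.EA_HYDROLYSIS / 8.3145 * (1 / TK - 1 / T0)) *
    (1 + mg_alpha * cond$mg)
  t_half <- log(2) / ((cond$n - 1) * k) / 86400
  flagged <- cond$pH < 5 || cond$pH > 9 || cond$temperature > 90
  structure(t_half, flagged = flagged)
}
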