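## Reference parameter fixtures.
##
## These are synthetic reference parameter sets for the wild-type-like and
## mutant-like channels, chosen by fitting the model to the published
## anchor observables (the coupling-ratio-vs-[K+] values and a typical
## single-channel conductance scale, with inward rectification and reduced
## conductance for the mutant-like set). They define the generator truths
## used throughout the tests; they are fixtures of this package, not
## estimates of any experimentally fitted rate constants.

#' Reference wild-type-like rate constants
#'
#' A parameter set reproducing the qualitative wild-type phenotype:
#' near-linear current-voltage relation at high K+, conductance saturating
#' with K+, and a coupling ratio falling from about 2.15 at 15 mM to about
#' 1.39 at 150 mM symmetric K+. Binding rates (k1 and the extracellular
#' binding k4) are bimolecular (1/(s*M)); all other rates in 1/s.
#'
#' @return a [RateParameterSet-class] with all ten rates free.
#' @export
wtRateParameters <- function() {
  rateParameterSet(c(
    k1 = 1.26422e+08,
    k2 = 2.11073e+07,
    k3 = 3.06242e+08,
    k4 = 2.85239e+12,
    k5 = 2.37266e+11,
    k6 = 1.25236e+08,
    k7 = 7.88540e+07,
    k8 = 6.50834e+05,
    k9 = 8.05161e+11,
    k10 = 8.19819e+10))
}

#' Reference mutant-like rate constants
#'
#' Derived from [wtRateParameters()] by modifying only the wide-pore-site
#' rates {k1, k2, k5, k7, k8}: increased binding (k1), decreased release
#' (k2) and attenuated pore-filter transfer rates (k5, k7), which produces
#' inward rectification, reduced conductance and a higher coupling ratio at
#' every K+.
#'
#' @return a [RateParameterSet-class] with {k1, k2, k5, k7, k8} free.
#' @export
mutantRateParameters <- function() {
  wt <- wtRateParameters()@k0
  wt["k1"] <- wt["k1"] * 6.99355
  wt["k2"] <- wt["k2"] * 0.197349
  wt["k5"] <- wt["k5"] * 0.525048
  wt["k7"] <- wt["k7"] * 0.143809
  wt["k8"] <- wt["k8"] * 0.00935217
  rateParameterSet(wt, free = c("k1", "k2", "k5", "k7", "k8"))
}
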