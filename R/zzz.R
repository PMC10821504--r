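#' MolDFT: self-contained DFT characterisation of small molecules
#'
#' A compact Gaussian-basis Kohn-Sham engine plus the ground-state
#' characterisation layers built on it: conceptual-DFT reactivity
#' indices, ELF basin topology, NCI analysis, MEP maps, RRHO reaction
#' thermochemistry and a drug-likeness rule engine.
#'
#' @useDynLib MolDFT, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
#' @importFrom utils head modifyList
#' @keywords internal
"_PACKAGE"
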