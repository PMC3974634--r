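#' Construct simulation parameters
#'
#' @param nClones number of accepted clones to simulate.
#' @param seed integer RNG seed, or \code{NA} to use the current RNG state.
#' @param pAlt SDSA/HJ-dissolution fraction for ends-in simulation (default
#'   0.17, the observed minor-pathway fraction).
#' @param dsb \code{list(arm =, position =)} for the chromosomal DSB, or
#'   \code{NULL}.
#' @param rReject per-mismatch rejection probability of mismatch repair.
#' @param hostSuppression MLH1-proficient efficiency penalty (default 50).
#' @param nMismatches vector mismatch count m (default 15).
#' @param errorRate,missingRate genotyping noise rates for [addNoise()].
#' @return a [SimParams-class].
#' @examples
#' SimParams(nClones = 230, seed = 1)
#' @export
SimParams <- function(nClones = 100, seed = NA, pAlt = 0.17, dsb = NULL,
                      rReject = 0, hostSuppression = 50, nMismatches = 15,
                      errorRate = 0, missingRate = 0) {
    new("SimParams",
        nClones = as.integer(nClones), seed = as.integer(seed),
        pAlt = pAlt, dsb = if (is.null(dsb)) list() else dsb,
        rReject = rReject, hostSuppression = hostSuppression,
        nMismatches = as.integer(nMismatches),
        errorRate = errorRate, missingRate = missingRate)
}

setMethod("show", "SimParams", function(object) {
    cat(sprintf(
        "SimParams: n=%d seed=%s pAlt=%g rReject=%g hostSup=%g m=%d\n",
        object@nClones, object@seed, object@pAlt, object@rReject,
        object@hostSuppression, object@nMismatches))
    if (length(object@dsb))
        cat(sprintf("  DSB: %s arm, position %g bp\n",
                    object@dsb$arm, object@dsb$position))
})

maybeSetSeed <- function(params) {
    if (!is.na(params@seed)) set.seed(params@seed)
    invisible(NULL)
}
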