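#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
#' @importFrom graphics abline lines
#' @importFrom stats lm coef residuals runif rbinom rnbinom weighted.mean
NULL

MARKER_KINDS <- c("SNP", "HAIRPIN", "HALF_SITE")
ARMS <- c("LEFT", "RIGHT")
CALL_SYMBOLS <- c("V", "C", "S", "N")
MECHANISMS <- c("ENDS_OUT_DSBR", "SSA_ASSIMILATION", "ENDS_IN_DSBR",
                "ENDS_IN_ALT", "RANDOM_INTEGRATION", "DOUBLE_EVENT")

#' MarkerMap: geometry of a marked targeting locus
#'
#' A \code{MarkerMap} describes the geometry used throughout the package: a
#' selection cassette flanked by two homology arms, each carrying polymorphic
#' markers (restriction-site SNPs, hairpin palindromes, and optionally half of
#' a meganuclease recognition site marking a double-strand-break position).
#' Marker positions are 1-based base pairs measured outward from the inner end
#' of each arm (the junction with the cassette); the cassette itself is
#' treated as a point for recombination geometry.
#'
#' @slot markers a \code{DataFrame} with columns \code{id} (unique character),
#'   \code{arm} (\code{"LEFT"} or \code{"RIGHT"}), \code{distance} (bp from
#'   the cassette junction, in (0, arm length]) and \code{kind} (\code{"SNP"},
#'   \code{"HAIRPIN"} or \code{"HALF_SITE"}; at most one half-site per map).
#' @slot armLengths named numeric of length 2 (\code{left}, \code{right}), bp.
#' @slot cassetteId character scalar naming the selection cassette.
#'
#' @seealso [MarkerMap()], [makeDefaultMap()], [signedDistance()],
#'   [validateMarkerMap()]
#' @exportClass MarkerMap
setClass("MarkerMap",
    representation(markers = "DataFrame",
                   armLengths = "numeric",
                   cassetteId = "character"))

## Geometry invariants are checked by the MarkerMap() constructor through
## validateMarkerMap(), which reports all violations instead of throwing --
## a class validity method would make deliberately invalid maps (built with
## validate = FALSE for inspection) unconstructable.

#' CloneTable: per-clone marker genotypes
#'
#' A \code{CloneTable} extends \code{SummarizedExperiment}: rows are the
#' SNP/hairpin markers of a [MarkerMap-class], columns are clones, and the
#' \code{"calls"} assay holds one genotype call per marker and clone:
#' \code{"V"} (viral/vector allele), \code{"C"} (chromosomal allele),
#' \code{"S"} (sectored: colony contains both) or \code{"N"} (no call).
#' Clone-level fields live in \code{colData}: \code{halfSitePresent} (half of
#' the meganuclease site retained), \code{selected} (survived drug selection),
#' \code{truthMechanism} (ground truth for simulated clones, \code{NA} for
#' observed data) and \code{parentId} (for subclones). Colony-mode simulations
#' additionally carry \code{"subcloneA"}/\code{"subcloneB"} assays with the
#' genotypes of the two daughter cell populations. The generating
#' \code{MarkerMap} and provenance string are stored in \code{metadata()}.
#'
#' @seealso [CloneTable()], [markerMap()], [calls()], [retentionProfile()]
#' @exportClass CloneTable
setClass("CloneTable", contains = "SummarizedExperiment")

setValidity("CloneTable", function(object) {
    map <- metadata(object)$map
    if (is.null(map))
        return("metadata()$map must hold the MarkerMap")
    want <- genotypedMarkers(map)$id
    if (!identical(rownames(object), as.character(want)))
        return("rows must be exactly the SNP/HAIRPIN markers of the map, in map order")
    cl <- assay(object, "calls")
    if (!all(cl %in% CALL_SYMBOLS))
        return(sprintf("invalid call symbol(s): %s",
                       paste(unique(cl[!cl %in% CALL_SYMBOLS]), collapse = ", ")))
    cd <- colData(object)
    need <- c("halfSitePresent", "selected", "truthMechanism")
    if (!all(need %in% colnames(cd)))
        return(sprintf("colData must contain %s", paste(need, collapse = ", ")))
    if (any(cd$halfSitePresent) && !hasHalfSite(map))
        return("halfSitePresent is true but the map has no HALF_SITE marker")
    ok <- is.na(cd$truthMechanism) | cd$truthMechanism %in% MECHANISMS
    if (!all(ok))
        return("unknown truthMechanism value")
    TRUE
})

#' SimParams: stochastic model parameters
#'
#' Bundles every parameter of the mechanism simulators. Defaults reflect the
#' experimental design emulated by the package: clone panels of order
#' 10--250, no genotyping noise, a 15-mismatch vector, and an
#' SDSA/HJ-dissolution fraction of 0.17 for DSB-induced targeting.
#'
#' @slot nClones number of accepted (selection-surviving) clones to emit.
#' @slot seed integer seed, or \code{NA} to leave the RNG state alone.
#' @slot pAlt probability that an ends-in event resolves by the
#'   SDSA/HJ-dissolution pathway rather than double-HJ resolution.
#' @slot dsb list \code{(arm, position)} locating the chromosomal
#'   double-strand break, or empty list for no DSB.
#' @slot rReject per-mismatch event-rejection probability of the
#'   mismatch-repair machinery, in [0, 1).
#' @slot hostSuppression multiplicative efficiency penalty (>= 1) applied in a
#'   mismatch-repair-proficient host; default 50, the reported lower bound of
#'   the MLH1+ effect.
#' @slot nMismatches total mismatch count m of the vector (15 for the default
#'   fully marked vector, 2 for the low-mismatch vector).
#' @slot errorRate,missingRate genotyping-noise probabilities used by
#'   [addNoise()].
#'
#' @seealso [SimParams()]
#' @exportClass SimParams
setClass("SimParams",
    representation(nClones = "integer", seed = "integer", pAlt = "numeric",
                   dsb = "list", rReject = "numeric",
                   hostSuppression = "numeric", nMismatches = "integer",
                   errorRate = "numeric", missingRate = "numeric"),
    prototype(nClones = 100L, seed = NA_integer_, pAlt = 0.17, dsb = list(),
              rReject = 0, hostSuppression = 50, nMismatches = 15L,
              errorRate = 0, missingRate = 0))

setValidity("SimParams", function(object) {
    msg <- character()
    if (length(object@nClones) != 1L || is.na(object@nClones) ||
        object@nClones < 0L)
        msg <- c(msg, "nClones must be a single non-negative integer")
    probs <- c(pAlt = object@pAlt, rReject = object@rReject,
               errorRate = object@errorRate, missingRate = object@missingRate)
    bad <- names(probs)[!is.finite(probs) | probs < 0 | probs > 1]
    if (length(bad))
        msg <- c(msg, sprintf("probabilities out of [0,1]: %s",
                              paste(bad, collapse = ", ")))
    if (object@rReject >= 1)
        msg <- c(msg, "rReject must be < 1")
    if (!is.finite(object@hostSuppression) || object@hostSuppression < 1)
        msg <- c(msg, "hostSuppression must be >= 1")
    if (object@nMismatches < 0L)
        msg <- c(msg, "nMismatches must be >= 0")
    if (length(object@dsb)) {
        if (!all(c("arm", "position") %in% names(object@dsb)))
            msg <- c(msg, "dsb must have elements 'arm' and 'position'")
        else if (!object@dsb$arm %in% ARMS)
            msg <- c(msg, "dsb$arm must be LEFT or RIGHT")
        else if (!is.finite(object@dsb$position) || object@dsb$position <= 0)
            msg <- c(msg, "dsb$position must be a positive bp offset")
    }
    if (length(msg)) msg else TRUE
})
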