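## Default fixture geometry: 4 restriction-site SNPs + 1 hairpin per 1 kb
## homology arm, matching the marked targeting-vector design the package
## emulates. NcoI (-547), SacI (+261) and the two meganuclease knock-in
## positions (-569, +266) are the literature positions; the remaining
## distances are fixture values consistent with the published marker order.
DEFAULT_MARKERS <- data.frame(
    id = c("NdeI", "EcoRI", "LHP", "NcoI", "AseI",
           "SspI", "SacI", "RHP", "XbaI", "SbfI"),
    arm = rep(c("LEFT", "RIGHT"), each = 5L),
    distance = c(950, 800, 650, 547, 300, 130, 261, 400, 600, 800),
    kind = c("SNP", "SNP", "HAIRPIN", "SNP", "SNP",
             "SNP", "SNP", "HAIRPIN", "SNP", "SNP"))

HALF_SITE_POS <- c(left = 569, right = 266)

#' Default marked-locus fixture map
#'
#' Builds the 10-marker map used throughout the package: per homology arm,
#' four restriction-site SNPs and one hairpin palindrome, ordered outward
#' from the selection cassette (left arm: AseI 300, NcoI 547, LHP 650,
#' EcoRI 800, NdeI 950; right arm: SspI 130, SacI 261, RHP 400, XbaI 600,
#' SbfI 800). Optionally adds half of a meganuclease (I-SceI) recognition
#' site at the knock-in position used for DSB-induced targeting: +266 on the
#' right arm (just beyond SacI) or -569 on the left arm (just beyond NcoI).
#'
#' @param armLengthLeft,armLengthRight homology-arm lengths in bp (default
#'   1000/1000); must accommodate the outermost fixture marker.
#' @param halfSite \code{"none"} (default), \code{"left"} or \code{"right"}.
#' @return a [MarkerMap-class].
#' @examples
#' makeDefaultMap()
#' makeDefaultMap(halfSite = "right")
#' @export
makeDefaultMap <- function(armLengthLeft = 1000, armLengthRight = 1000,
                           halfSite = c("none", "left", "right")) {
    halfSite <- match.arg(halfSite)
    m <- DEFAULT_MARKERS
    need <- c(left = max(m$distance[m$arm == "LEFT"]),
              right = max(m$distance[m$arm == "RIGHT"]))
    if (armLengthLeft < need["left"] || armLengthRight < need["right"])
        stop(sprintf("arms must be at least %g (left) and %g (right) bp to hold the fixture markers",
                     need["left"], need["right"]))
    if (halfSite != "none") {
        arm <- toupper(halfSite)
        m <- rbind(m, data.frame(id = "ISceI_half", arm = arm,
                                 distance = HALF_SITE_POS[[halfSite]],
                                 kind = "HALF_SITE"))
    }
    MarkerMap(m, armLengthLeft, armLengthRight)
}

#' Simulate a mechanism mixture
#'
#' Draws each clone from one of several mechanism components according to
#' mixture weights, preserving per-clone ground-truth labels — the test
#' harness for mechanism classification.
#'
#' @param map a [MarkerMap-class].
#' @param components a list of components, each a list with \code{mechanism}
#'   (\code{"ENDS_OUT"}, \code{"SSA"}, \code{"ENDS_IN"},
#'   \code{"RANDOM_INTEGRATION"} or \code{"DOUBLE_EVENT_MIXTURE"}),
#'   \code{weight}, and optional \code{params} ([SimParams-class]; clone
#'   counts and seeds inside are ignored), \code{mode} (for ends-out) and
#'   \code{q} (for the double-event mixture).
#' @param n total number of clones.
#' @param seed integer seed.
#' @return a [CloneTable-class] with clones in component-of-origin order.
#' @examples
#' mix <- generateMixture(makeDefaultMap(),
#'     list(list(mechanism = "ENDS_OUT", weight = 0.74, mode = "COLONY"),
#'          list(mechanism = "SSA", weight = 0.26)),
#'     n = 100, seed = 1)
#' table(truthMechanism(mix))
#' @export
generateMixture <- function(map, components, n, seed = NA) {
    if (length(components) == 0L)
        stop("components must be a non-empty list")
    w <- vapply(components, function(cp) cp$weight, 0)
    if (abs(sum(w) - 1) > 1e-8)
        stop(sprintf("component weights must sum to 1 (got %g)", sum(w)))
    if (!is.na(seed)) set.seed(seed)
    sizes <- as.vector(stats::rmultinom(1L, n, w))
    seeds <- sample.int(.Machine$integer.max, length(components))
    tabs <- list()
    for (i in seq_along(components)) {
        if (sizes[i] == 0L) next
        cp <- components[[i]]
        par <- if (!is.null(cp$params)) cp$params else SimParams()
        par@nClones <- sizes[i]
        par@seed <- seeds[i]
        tabs[[length(tabs) + 1L]] <- switch(cp$mechanism,
            ENDS_OUT = simulateEndsOut(map, par,
                mode = if (!is.null(cp$mode)) cp$mode else "SEGREGANT"),
            SSA = simulateSSA(map, par),
            ENDS_IN = simulateEndsIn(map, par),
            RANDOM_INTEGRATION = simulateRandomIntegration(map, par),
            DOUBLE_EVENT_MIXTURE = simulateDoubleEventMixture(map, par,
                q = if (!is.null(cp$q)) cp$q else 0),
            stop("unknown mechanism: ", cp$mechanism))
    }
    bindCloneTables(map, tabs,
                    provenance = sprintf("mixture of %d components, n=%d, seed=%s",
                                         length(components), n,
                                         ifelse(is.na(seed), "none", seed)))
}

## concatenate clone tables over the same map (subclone assays dropped
## unless present in all parts)
bindCloneTables <- function(map, tabs, provenance = "bound") {
    stopifnot(length(tabs) > 0L)
    cl <- do.call(cbind, lapply(tabs, calls))
    colnames(cl) <- sprintf("clone_%03d", seq_len(ncol(cl)))
    haveSub <- all(vapply(tabs, function(t)
        all(c("subcloneA", "subcloneB") %in% assayNames(t)), TRUE))
    att <- vapply(tabs, attempts, 0)
    CloneTable(map, cl,
               halfSitePresent = unlist(lapply(tabs, halfSitePresent)),
               selected = unlist(lapply(tabs, isSelected)),
               truthMechanism = unlist(lapply(tabs, truthMechanism)),
               subcloneA = if (haveSub)
                   do.call(cbind, lapply(tabs, assay, "subcloneA")) else NULL,
               subcloneB = if (haveSub)
                   do.call(cbind, lapply(tabs, assay, "subcloneB")) else NULL,
               provenance = provenance,
               attempts = if (anyNA(att)) NA_real_ else sum(att))
}

#' Inject genotyping noise into a clone table
#'
#' Emulates genotyping error and missingness downstream of the mechanism
#' models (which stay exact): independently per call, with probability
#' \code{missingRate} the call becomes \code{"N"}; otherwise with probability
#' \code{errorRate} it is replaced by a uniformly chosen different call from
#' \code{V, C, S}. Ground-truth labels are untouched.
#'
#' @param table a [CloneTable-class].
#' @param errorRate,missingRate probabilities in [0, 1].
#' @param seed optional integer seed.
#' @return a [CloneTable-class] with perturbed calls.
#' @export
addNoise <- function(table, errorRate, missingRate, seed = NULL) {
    stopifnot(is(table, "CloneTable"),
              errorRate >= 0, errorRate <= 1,
              missingRate >= 0, missingRate <= 1)
    if (!is.null(seed)) set.seed(seed)
    cl <- calls(table)
    nc <- length(cl)
    u <- stats::runif(nc)
    miss <- u < missingRate
    err <- !miss & stats::runif(nc) < errorRate
    if (any(err)) {
        alt <- vapply(cl[err], function(x)
            sample(setdiff(c("V", "C", "S"), x), 1L), "")
        cl[err] <- alt
    }
    cl[miss] <- "N"
    out <- table
    assay(out, "calls") <- cl
    metadata(out)$provenance <- sprintf(
        "%s + noise(error=%g, missing=%g)", metadata(out)$provenance,
        errorRate, missingRate)
    out
}
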