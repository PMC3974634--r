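## Mechanism simulators.
##
## All simulators share the same geometric convention: a selection cassette
## flanked by two homology arms, with strand-crossover / Holliday-junction
## resolution positions drawn Uniform over the available homology interval --
## the model supported by the observed linear marker-retention gradient.
## Rejection sampling (mismatch-repair rejection, drug selection) redraws
## events until the requested number of accepted clones exists; the total
## attempt count is kept as the efficiency readout.

## V/C call matrix for one crossover per arm and clone: a marker at distance
## d from the cassette is viral iff d < crossover of its arm.
vcCalls <- function(gm, crossLeft, crossRight) {
    n <- length(crossLeft)
    m <- matrix("C", nrow = nrow(gm), ncol = n)
    for (arm in ARMS) {
        idx <- which(gm$arm == arm)
        if (!length(idx)) next
        x <- if (arm == "LEFT") crossLeft else crossRight
        v <- outer(gm$distance[idx], x, "<")
        m[idx, ][v] <- "V"
    }
    rownames(m) <- gm$id
    m
}

## total attempts needed to accept n events at per-event probability pAcc
## (negative-binomial draw; equivalent in law to redrawing rejected events)
countAttempts <- function(n, pAcc) {
    if (n == 0L) return(0)
    if (pAcc >= 1) return(as.numeric(n))
    n + stats::rnbinom(1L, size = n, prob = pAcc)
}

mmrAcceptProb <- function(params) (1 - params@rReject)^params@nMismatches

#' Simulate ends-out gene targeting
#'
#' The canonical spontaneous targeting mechanism: the double-stranded vector
#' invades the unbroken chromosome in an ends-out configuration, forming a
#' double-Holliday-junction intermediate whose resolution positions are drawn
#' independently and uniformly over each homology arm. All accepted events
#' carry the cassette, so every emitted clone is selection-surviving.
#'
#' Two sampling modes reflect the two experimental designs emulated:
#' \describe{
#'   \item{\code{"SEGREGANT"}}{a clone picked after the heteroduplex has
#'     segregated at mitosis; one strand is chosen at random per arm and a
#'     marker at distance \eqn{d} is viral iff \eqn{d} is inside the retained
#'     tract, giving marker retention probability \eqn{1 - d/L}.}
#'   \item{\code{"COLONY"}}{the in-situ sectoring assay: the colony contains
#'     both daughter genotypes, so a marker is \code{"V"} when inside both
#'     strand tracts, \code{"S"} (sectored) when inside exactly one, and
#'     \code{"C"} beyond both. The two daughter genotypes are kept in the
#'     \code{subcloneA}/\code{subcloneB} assays; a single event always
#'     segregates the two arms in trans.}
#' }
#'
#' Mismatch-repair anti-recombination rejects each event with probability
#' \eqn{1 - (1 - r)^m} (\code{rReject}, \code{nMismatches}); rejected events
#' are redrawn and counted in [attempts()].
#'
#' @param map a [MarkerMap-class].
#' @param params a [SimParams-class]; \code{dsb} must be unset.
#' @param mode \code{"SEGREGANT"} or \code{"COLONY"}.
#' @return a [CloneTable-class] of \code{nClones} accepted clones.
#' @examples
#' tab <- simulateEndsOut(makeDefaultMap(), SimParams(nClones = 230, seed = 1))
#' retentionProfile(tab)
#' @seealso [simulateSSA()], [simulateEndsIn()], [retentionProfile()]
#' @export
simulateEndsOut <- function(map, params, mode = c("SEGREGANT", "COLONY")) {
    mode <- match.arg(mode)
    stopifnot(is(map, "MarkerMap"), is(params, "SimParams"))
    if (length(params@dsb))
        stop("ends-out simulation models spontaneous targeting; params$dsb must be unset")
    maybeSetSeed(params)
    n <- params@nClones
    gm <- genotypedMarkers(map)
    att <- countAttempts(n, mmrAcceptProb(params))
    Ll <- armLengthOf(map, "LEFT"); Lr <- armLengthOf(map, "RIGHT")
    if (mode == "SEGREGANT") {
        xL <- stats::runif(n, 0, Ll)
        xR <- stats::runif(n, 0, Lr)
        cl <- vcCalls(gm, xL, xR)
        tab <- CloneTable(map, cl,
                          truthMechanism = rep("ENDS_OUT_DSBR", n),
                          provenance = simProv("ends_out SEGREGANT", params),
                          attempts = att)
    } else {
        ## two strand crossovers per arm; daughter A carries the viral-rich
        ## left strand and the viral-poor right strand (trans bookkeeping)
        xL1 <- stats::runif(n, 0, Ll); xL2 <- stats::runif(n, 0, Ll)
        xR1 <- stats::runif(n, 0, Lr); xR2 <- stats::runif(n, 0, Lr)
        subA <- vcCalls(gm, pmax(xL1, xL2), pmin(xR1, xR2))
        subB <- vcCalls(gm, pmin(xL1, xL2), pmax(xR1, xR2))
        cl <- combineDaughters(subA, subB)
        tab <- CloneTable(map, cl, subcloneA = subA, subcloneB = subB,
                          truthMechanism = rep("ENDS_OUT_DSBR", n),
                          provenance = simProv("ends_out COLONY", params),
                          attempts = att)
    }
    tab
}

## colony call from the two daughter genotypes: V both viral, C both
## chromosomal, S sectored
combineDaughters <- function(subA, subB) {
    cl <- matrix("S", nrow = nrow(subA), ncol = ncol(subA))
    cl[subA == "V" & subB == "V"] <- "V"
    cl[subA == "C" & subB == "C"] <- "C"
    rownames(cl) <- rownames(subA)
    cl
}

#' Simulate single-strand assimilation targeting
#'
#' Alternative model for single-stranded vector integration: one viral strand
#' anneals into chromosomal heteroduplex with a single crossover per arm,
#' Uniform over the arm. The daughter cell lacking the selection cassette is
#' killed by selection, so the surviving colony is homogeneous: the marginal
#' retention geometry is identical to segregant-mode ends-out targeting
#' (retention probability \eqn{1 - d/L}) but no marker is ever sectored.
#'
#' @inheritParams simulateEndsOut
#' @return a [CloneTable-class]; calls are \code{"V"}/\code{"C"} only.
#' @export
simulateSSA <- function(map, params) {
    stopifnot(is(map, "MarkerMap"), is(params, "SimParams"))
    maybeSetSeed(params)
    n <- params@nClones
    gm <- genotypedMarkers(map)
    att <- countAttempts(n, mmrAcceptProb(params))
    xL <- stats::runif(n, 0, armLengthOf(map, "LEFT"))
    xR <- stats::runif(n, 0, armLengthOf(map, "RIGHT"))
    CloneTable(map, vcCalls(gm, xL, xR),
               truthMechanism = rep("SSA_ASSIMILATION", n),
               provenance = simProv("ssa", params), attempts = att)
}

#' Simulate DSB-induced ends-in gene targeting
#'
#' With a chromosomal double-strand break at position \eqn{s} on one arm, the
#' broken chromosome ends invade the vector in an ends-in configuration. Two
#' resolution pathways are modelled, mixed with probability \code{pAlt}:
#' \describe{
#'   \item{DSBR (double-HJ resolution)}{the distal junction resolves at
#'     \eqn{y \sim U(s, L)} on the DSB arm and the proximal junction at a
#'     signed position \eqn{p} uniform over cassette-plus-far-arm; drug
#'     selection discards events whose conversion tract misses the cassette,
#'     so surviving clones retain every marker between the cassette and the
#'     DSB (the retention plateau) and markers beyond \eqn{s} with
#'     probability \eqn{(L - d)/(L - s)}.}
#'   \item{ALT (SDSA / HJ dissolution)}{the invading end anneals back after
#'     templated synthesis: the clone retains half of the meganuclease site
#'     (\code{halfSitePresent}), every DSB-arm marker between cassette and
#'     DSB, and none beyond it.}
#' }
#' \code{pAlt} is the pathway fraction among surviving clones; DSBR events
#' rejected by selection are redrawn and counted in [attempts()].
#'
#' @inheritParams simulateEndsOut
#' @param params a [SimParams-class] with \code{dsb = list(arm, position)}.
#' @return a [CloneTable-class].
#' @examples
#' p <- SimParams(nClones = 100, seed = 1,
#'                dsb = list(arm = "RIGHT", position = 266))
#' tab <- simulateEndsIn(makeDefaultMap(halfSite = "right"), p)
#' @export
simulateEndsIn <- function(map, params) {
    stopifnot(is(map, "MarkerMap"), is(params, "SimParams"))
    if (!length(params@dsb))
        stop("ends-in simulation requires params$dsb = list(arm, position)")
    dsbArm <- params@dsb$arm
    s <- params@dsb$position
    Ld <- armLengthOf(map, dsbArm)
    Lo <- armLengthOf(map, setdiff(ARMS, dsbArm))
    if (s <= 0 || s >= Ld)
        stop(sprintf("DSB position %g outside the %s arm (0, %g)", s, dsbArm, Ld))
    maybeSetSeed(params)
    n <- params@nClones
    gm <- genotypedMarkers(map)
    isAlt <- stats::runif(n) < params@pAlt
    nD <- sum(!isAlt)
    ## selection acceptance of a DSBR event: proximal resolution uniform on
    ## (-Lother, s) must land on the far side of the cassette
    pSel <- Lo / (Lo + s)
    att <- countAttempts(sum(isAlt), mmrAcceptProb(params)) +
        countAttempts(nD, pSel * mmrAcceptProb(params))
    ## DSB-arm crossover: y for DSBR, s itself for ALT
    y <- numeric(n)
    y[!isAlt] <- stats::runif(nD, s, Ld)
    y[isAlt] <- s
    ## accepted proximal resolution covers the cassette: |p| ~ U(0, Lother)
    pMag <- stats::runif(n, 0, Lo)
    if (dsbArm == "RIGHT") cl <- vcCalls(gm, pMag, y)
    else                   cl <- vcCalls(gm, y, pMag)
    mech <- ifelse(isAlt, "ENDS_IN_ALT", "ENDS_IN_DSBR")
    CloneTable(map, cl, halfSitePresent = isAlt,
               truthMechanism = mech,
               provenance = simProv(sprintf("ends_in %s@%g", dsbArm, s), params),
               attempts = att)
}

#' Simulate random (non-homologous) integration
#'
#' Random integration proceeds through the vector termini, leaving the
#' homology arms intact: every marker is retained in every clone.
#'
#' @inheritParams simulateEndsOut
#' @return a [CloneTable-class] with all calls \code{"V"}.
#' @export
simulateRandomIntegration <- function(map, params) {
    stopifnot(is(map, "MarkerMap"), is(params, "SimParams"))
    maybeSetSeed(params)
    n <- params@nClones
    gm <- genotypedMarkers(map)
    cl <- matrix("V", nrow = nrow(gm), ncol = n, dimnames = list(gm$id, NULL))
    CloneTable(map, cl, truthMechanism = rep("RANDOM_INTEGRATION", n),
               provenance = simProv("random_integration", params),
               attempts = as.numeric(n))
}

#' Simulate a mixture of single- and double-event colonies
#'
#' Sectored colonies could in principle arise from one heteroduplex-bearing
#' HR event (always trans) or from two independent targeting events landing
#' in one colony (trans or cis with equal probability). This simulator mixes
#' the two: with probability \code{1 - q} a colony is a single ends-out
#' colony-mode event; with probability \code{q} it is assembled from two
#' independent segregant genotypes, whose arm-sector orientation is therefore
#' uniform. The observed trans fraction among both-arm-sectored colonies is
#' \eqn{1 - q/2}, inverted by [estimateDoubleEventFraction()].
#'
#' @inheritParams simulateEndsOut
#' @param q fraction of double-event colonies, in [0, 1].
#' @return a [CloneTable-class] with \code{subcloneA}/\code{subcloneB} assays.
#' @export
simulateDoubleEventMixture <- function(map, params, q) {
    stopifnot(is(map, "MarkerMap"), is(params, "SimParams"),
              is.numeric(q), length(q) == 1L, q >= 0, q <= 1)
    maybeSetSeed(params)
    n <- params@nClones
    gm <- genotypedMarkers(map)
    Ll <- armLengthOf(map, "LEFT"); Lr <- armLengthOf(map, "RIGHT")
    isDouble <- stats::runif(n) < q
    ## single events: colony-mode trans bookkeeping; double events: two
    ## independent segregant genotypes as the daughter populations
    xL1 <- stats::runif(n, 0, Ll); xL2 <- stats::runif(n, 0, Ll)
    xR1 <- stats::runif(n, 0, Lr); xR2 <- stats::runif(n, 0, Lr)
    aL <- ifelse(isDouble, xL1, pmax(xL1, xL2))
    aR <- ifelse(isDouble, xR1, pmin(xR1, xR2))
    bL <- ifelse(isDouble, xL2, pmin(xL1, xL2))
    bR <- ifelse(isDouble, xR2, pmax(xR1, xR2))
    subA <- vcCalls(gm, aL, aR)
    subB <- vcCalls(gm, bL, bR)
    att <- countAttempts(n + sum(isDouble), mmrAcceptProb(params))
    CloneTable(map, combineDaughters(subA, subB),
               subcloneA = subA, subcloneB = subB,
               truthMechanism = ifelse(isDouble, "DOUBLE_EVENT",
                                       "ENDS_OUT_DSBR"),
               provenance = simProv(sprintf("double_event_mixture q=%g", q),
                                    params),
               attempts = att)
}

simProv <- function(label, params) {
    sprintf("simulated: %s n=%d seed=%s rReject=%g m=%d pAlt=%g",
            label, params@nClones,
            ifelse(is.na(params@seed), "none", params@seed),
            params@rReject, params@nMismatches, params@pAlt)
}
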