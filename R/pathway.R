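#' Classify the resolution pathway of DSB-induced targeting clones
#'
#' In DSB-induced (ends-in) targeting, SDSA and HJ dissolution both predict
#' retention of one half of the meganuclease recognition site together with
#' loss of every marker distal to the break, whereas double-HJ resolution
#' (DSBR) destroys the half site. The half-site flag is therefore the sole
#' discriminator: a clone is \code{ALT} when the half site is present and all
#' distal markers are chromosomal, \code{DSBR} when the half site is absent,
#' and \code{INCONSISTENT} when the half site is present but a distal marker
#' was retained — impossible under either model and used as a noise sentinel.
#'
#' @param table a [CloneTable-class] from an ends-in experiment.
#' @param dsb \code{list(arm, position)}; defaults to the position of the
#'   map's \code{HALF_SITE} marker.
#' @return a data.frame of class \code{"pathwayCalls"}: \code{cloneId},
#'   \code{call} (\code{"DSBR"}/\code{"ALT"}/\code{"INCONSISTENT"}),
#'   \code{reason}.
#' @examples
#' p <- SimParams(nClones = 50, seed = 1,
#'                dsb = list(arm = "RIGHT", position = 266))
#' tab <- simulateEndsIn(makeDefaultMap(halfSite = "right"), p)
#' table(classifyPathway(tab)$call)
#' @export
classifyPathway <- function(table, dsb = NULL) {
    stopifnot(is(table, "CloneTable"))
    map <- markerMap(table)
    if (is.null(dsb)) {
        hs <- halfSiteMarker(map)
        if (nrow(hs) == 0L)
            stop("no dsb given and the map has no HALF_SITE marker")
        dsb <- list(arm = hs$arm[1L], position = hs$distance[1L])
    }
    if (!dsb$arm %in% ARMS || dsb$position <= 0 ||
        dsb$position > armLengthOf(map, dsb$arm))
        stop("dsb is not on the map")
    gm <- as.data.frame(rowData(table))
    distal <- gm$arm == dsb$arm & gm$distance > dsb$position
    cl <- calls(table)
    hsp <- halfSitePresent(table)
    dcl <- cl[distal, , drop = FALSE]
    distalLost <- colSums(dcl == "V" | dcl == "S") == 0L
    call <- ifelse(!hsp, "DSBR",
                   ifelse(distalLost, "ALT", "INCONSISTENT"))
    reason <- ifelse(!hsp, "half site absent: double-HJ resolution",
              ifelse(distalLost,
                     "half site retained, all distal markers lost: SDSA/dissolution",
                     "half site retained but distal marker(s) retained"))
    structure(data.frame(cloneId = colnames(table), call = call,
                         reason = reason, row.names = NULL),
              class = c("pathwayCalls", "data.frame"))
}

#' Calibrate the per-mismatch rejection probability of mismatch repair
#'
#' Mismatch repair rejects recombination intermediates containing mismatched
#' heteroduplex. Under event-level rejection with per-mismatch survival
#' \eqn{1 - r}, a vector with \eqn{m} mismatches targets with relative
#' efficiency \eqn{(1 - r)^m}, so an observed efficiency fold-change between
#' two vectors solves \eqn{(1 - r)^{m_s - m_l} = \rho}, i.e.
#' \eqn{r = 1 - \rho^{-1/(m_l - m_s)}}.
#'
#' @param efficiencyRatio observed fold-change (low-mismatch over
#'   high-mismatch vector efficiency), > 1.
#' @param mLarge,mSmall mismatch counts of the two vectors
#'   (\code{mLarge > mSmall >= 0}).
#' @return the per-mismatch rejection probability \code{r}.
#' @examples
#' calibrateRejection(7.5, 15, 2)  # ~0.1436
#' @export
calibrateRejection <- function(efficiencyRatio, mLarge, mSmall) {
    stopifnot(is.numeric(efficiencyRatio), length(efficiencyRatio) == 1L,
              mLarge > mSmall, mSmall >= 0)
    if (efficiencyRatio <= 1) {
        warning("efficiency ratio <= 1: no detectable rejection, returning r = 0")
        return(0)
    }
    1 - efficiencyRatio^(-1 / (mLarge - mSmall))
}

#' Relative targeting efficiency under the mismatch-repair model
#'
#' Event-level acceptance probability of a vector with \code{m} mismatches:
#' \eqn{(1 - r)^m}, divided by the host-suppression factor in a
#' mismatch-repair-proficient host. Efficiencies are relative: a mismatch-free
#' vector in a deficient host has efficiency 1.
#'
#' @param model a list or [SimParams-class] carrying \code{rReject} and
#'   \code{hostSuppression}.
#' @param m vector mismatch count(s).
#' @param host \code{"DEFICIENT"} or \code{"PROFICIENT"}.
#' @return numeric efficiency in (0, 1].
#' @examples
#' r <- calibrateRejection(7.5, 15, 2)
#' mmr <- SimParams(rReject = r)
#' relativeEfficiency(mmr, 2) / relativeEfficiency(mmr, 15)  # 7.5
#' @export
relativeEfficiency <- function(model, m, host = c("DEFICIENT", "PROFICIENT")) {
    host <- match.arg(host)
    stopifnot(all(m >= 0))
    r <- if (is(model, "SimParams")) model@rReject else model$rReject
    hs <- if (is(model, "SimParams")) model@hostSuppression else
        model$hostSuppression
    eff <- (1 - r)^m
    if (host == "PROFICIENT") eff <- eff / hs
    eff
}

#' Monte-Carlo targeting acceptance rate under mismatch-repair rejection
#'
#' Simulates \code{nEvents} candidate targeting events, each accepted with
#' the probability given by [relativeEfficiency()], and returns the empirical
#' acceptance rate. Used to check the closed-form efficiency model against
#' the event-level rejection mechanism.
#'
#' @inheritParams relativeEfficiency
#' @param nEvents number of candidate events to draw.
#' @param seed optional integer seed.
#' @return a list: \code{accepted}, \code{nEvents}, \code{rate}.
#' @export
simulateMmrAcceptance <- function(model, m, host = c("DEFICIENT", "PROFICIENT"),
                                  nEvents = 1e5, seed = NULL) {
    host <- match.arg(host)
    if (!is.null(seed)) set.seed(seed)
    p <- relativeEfficiency(model, m, host)
    acc <- stats::rbinom(1L, size = as.integer(nEvents), prob = p)
    list(accepted = acc, nEvents = as.integer(nEvents),
         rate = acc / nEvents)
}
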