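#' Classify colonies as sectored or unsectored
#'
#' A colony from the in-situ assay is sectored when at least one marker call
#' is \code{"S"}, i.e. the colony contains both the viral and the chromosomal
#' allele at that marker — the signature of an unrepaired heteroduplex
#' segregating at mitosis. Tracts falling entirely between two neighbouring
#' markers are undetectable, so short heteroduplexes classify unsectored.
#'
#' @param table a [CloneTable-class] in colony mode (or a single clone's call
#'   vector).
#' @return character vector, \code{"SECTORED"}/\code{"UNSECTORED"} per clone.
#' @export
classifySectoring <- function(table) {
    cl <- if (is(table, "CloneTable")) calls(table) else
        matrix(table, ncol = 1L)
    out <- ifelse(colSums(cl == "S") > 0L, "SECTORED", "UNSECTORED")
    names(out) <- colnames(cl)
    out
}

#' Classify a sectored colony's subclones as trans or cis
#'
#' For a colony sectored on both homology arms, single-cell subcloning
#' recovers its two genotypically pure populations. At each parent-sectored
#' marker the two subclones must carry the viral and chromosomal alleles
#' reciprocally. The configuration is \code{TRANS} when the subclone carrying
#' the viral alleles on the left arm carries the chromosomal alleles on the
#' right arm (the signature of one heteroduplex-bearing HR event), and
#' \code{CIS} when one subclone is viral on both arms. Any violated
#' precondition — a parent not sectored on both arms, non-reciprocal
#' subclones, or within-arm disagreement about which subclone is viral —
#' yields \code{AMBIGUOUS} with the reason recorded.
#'
#' @param subcloneA,subcloneB named character call vectors (\code{"V"}/
#'   \code{"C"}) of the two subclones over the parent's markers.
#' @param parent named character call vector of the parent colony.
#' @return a list of class \code{"configurationCall"}: \code{call}
#'   (\code{"TRANS"}, \code{"CIS"} or \code{"AMBIGUOUS"}), \code{reason},
#'   and \code{evidence} (per-arm viral-carrying subclone at the sectored
#'   markers).
#' @export
classifyConfiguration <- function(subcloneA, subcloneB, parent) {
    arms <- attr(parent, "arm")
    if (is.null(arms))
        stop("parent call vector must carry an 'arm' attribute; use configurationCalls() on a CloneTable")
    sect <- names(parent)[parent == "S"]
    ambiguous <- function(reason)
        structure(list(call = "AMBIGUOUS", reason = reason,
                       evidence = NULL), class = "configurationCall")
    sectArms <- unique(arms[match(sect, names(parent))])
    if (!all(ARMS %in% sectArms))
        return(ambiguous("parent is not sectored on both arms"))
    a <- subcloneA[sect]; b <- subcloneB[sect]
    if (any(!(a == "V" & b == "C") & !(a == "C" & b == "V")))
        return(ambiguous("subclones are not reciprocal at the sectored markers"))
    carrier <- character(2L); names(carrier) <- ARMS
    for (arm in ARMS) {
        mk <- sect[arms[match(sect, names(parent))] == arm]
        who <- ifelse(subcloneA[mk] == "V", "A", "B")
        if (length(unique(who)) > 1L)
            return(ambiguous(sprintf(
                "subclones disagree within the %s arm", arm)))
        carrier[arm] <- who[1L]
    }
    call <- if (carrier["LEFT"] == carrier["RIGHT"]) "CIS" else "TRANS"
    structure(list(call = call, reason = NA_character_, evidence = carrier),
              class = "configurationCall")
}

#' @export
print.configurationCall <- function(x, ...) {
    cat("configuration:", x$call)
    if (!is.na(x$reason)) cat(" (", x$reason, ")", sep = "")
    cat("\n")
    invisible(x)
}

#' Configuration calls for every colony of a colony-mode table
#'
#' Applies [classifyConfiguration()] to each colony using the
#' \code{subcloneA}/\code{subcloneB} assays produced by the colony-mode
#' simulators (or read back from disk).
#'
#' @param table a [CloneTable-class] with subclone assays.
#' @return a data.frame: \code{colonyId}, \code{call}, \code{reason}.
#' @export
configurationCalls <- function(table) {
    stopifnot(is(table, "CloneTable"))
    if (!all(c("subcloneA", "subcloneB") %in% assayNames(table)))
        stop("table has no subclone assays; simulate in COLONY mode")
    cl <- calls(table)
    sa <- assay(table, "subcloneA")
    sb <- assay(table, "subcloneB")
    arms <- rowData(table)$arm
    res <- lapply(seq_len(ncol(table)), function(j) {
        parent <- cl[, j]
        attr(parent, "arm") <- arms
        classifyConfiguration(sa[, j], sb[, j], parent)
    })
    data.frame(colonyId = colnames(table),
               call = vapply(res, `[[`, "", "call"),
               reason = vapply(res, `[[`, "", "reason"))
}

#' Estimate the double-event colony fraction from the trans proportion
#'
#' Under the mixture model in which a single HR event always yields a trans
#' configuration while a colony formed by two independent targeting events is
#' trans or cis with equal probability, the observed trans proportion
#' \eqn{p} among both-arm-sectored colonies satisfies \eqn{p = 1 - q/2},
#' i.e. \eqn{q = 2(1 - p)}.
#'
#' @param pTrans observed trans proportion, in [0.5, 1].
#' @param nColonies optional number of colonies behind \code{pTrans}; when
#'   given, an exact binomial 95\% interval on \code{pTrans} is propagated
#'   through the estimator.
#' @return the estimated double-event fraction \code{q}; with
#'   \code{nColonies}, a named vector \code{c(q, lower, upper)}.
#' @examples
#' estimateDoubleEventFraction(0.896)  # 0.208
#' @export
estimateDoubleEventFraction <- function(pTrans, nColonies = NULL) {
    stopifnot(is.numeric(pTrans), length(pTrans) == 1L)
    if (pTrans > 1)
        stop("pTrans is a proportion and cannot exceed 1")
    if (pTrans < 0.5)
        stop("pTrans < 0.5 is outside the mixture model (q would exceed 1)")
    q <- 2 * (1 - pTrans)
    if (is.null(nColonies))
        return(q)
    ci <- stats::binom.test(round(pTrans * nColonies), nColonies)$conf.int
    c(q = q, lower = max(2 * (1 - ci[2L]), 0), upper = min(2 * (1 - ci[1L]), 1))
}

#' Sectoring summary of a colony-mode table
#'
#' @param table a colony-mode [CloneTable-class].
#' @return a list: \code{sectoredFraction}, per-colony sectoring calls, and —
#'   when subclone assays are present — trans/cis counts among
#'   both-arm-sectored colonies and the estimated double-event fraction.
#' @export
sectoringSummary <- function(table) {
    sec <- classifySectoring(table)
    out <- list(nColonies = length(sec),
                sectoredFraction = mean(sec == "SECTORED"),
                sectoring = sec)
    if (all(c("subcloneA", "subcloneB") %in% assayNames(table))) {
        cfg <- configurationCalls(table)
        informative <- cfg$call %in% c("TRANS", "CIS")
        nT <- sum(cfg$call == "TRANS"); nC <- sum(cfg$call == "CIS")
        out$configurations <- cfg
        out$nTrans <- nT
        out$nCis <- nC
        if (nT + nC > 0) {
            out$pTrans <- nT / (nT + nC)
            out$qDoubleEvent <- if (out$pTrans >= 0.5)
                estimateDoubleEventFraction(out$pTrans, nT + nC) else NA
        }
    }
    out
}
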