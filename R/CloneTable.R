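#' Construct a CloneTable
#'
#' Low-level constructor used by the simulators and readers. Most users get
#' \code{CloneTable} objects from [simulateEndsOut()] and friends or from
#' [readCloneTable()].
#'
#' @param map the [MarkerMap-class] the calls refer to.
#' @param calls character matrix of calls in \code{V, C, S, N}; rows are the
#'   SNP/hairpin markers of \code{map} (map order), columns are clones.
#' @param halfSitePresent,selected logical vectors, one element per clone.
#' @param truthMechanism character vector of ground-truth mechanism labels
#'   (or \code{NA} for observed data).
#' @param parentId parent colony ids for subclones, \code{NA} otherwise.
#' @param subcloneA,subcloneB optional V/C call matrices for the two daughter
#'   populations of colony-mode simulations.
#' @param provenance free-text provenance (simulation parameters or file).
#' @param attempts total number of events drawn to obtain the accepted
#'   clones (rejection-sampling efficiency readout).
#' @return a [CloneTable-class].
#' @export
CloneTable <- function(map, calls,
                       halfSitePresent = rep(FALSE, ncol(calls)),
                       selected = rep(TRUE, ncol(calls)),
                       truthMechanism = rep(NA_character_, ncol(calls)),
                       parentId = rep(NA_character_, ncol(calls)),
                       subcloneA = NULL, subcloneB = NULL,
                       provenance = "", attempts = NA_real_) {
    gm <- genotypedMarkers(map)
    calls <- as.matrix(calls)
    if (is.null(rownames(calls)))
        rownames(calls) <- gm$id
    if (is.null(colnames(calls)))
        colnames(calls) <- sprintf("clone_%03d", seq_len(ncol(calls)))
    assays <- list(calls = calls)
    if (!is.null(subcloneA)) {
        dimnames(subcloneA) <- dimnames(calls)
        dimnames(subcloneB) <- dimnames(calls)
        assays$subcloneA <- subcloneA
        assays$subcloneB <- subcloneB
    }
    se <- SummarizedExperiment(
        assays = assays,
        rowData = gm,
        colData = DataFrame(halfSitePresent = as.logical(halfSitePresent),
                            selected = as.logical(selected),
                            truthMechanism = as.character(truthMechanism),
                            parentId = as.character(parentId),
                            row.names = colnames(calls)))
    metadata(se)$map <- map
    metadata(se)$provenance <- provenance
    metadata(se)$attempts <- attempts
    new("CloneTable", se)
}

#' @describeIn CloneTable the [MarkerMap-class] the table refers to.
#' @param x a \code{CloneTable}.
#' @export
markerMap <- function(x) metadata(x)$map

#' @describeIn CloneTable the calls assay (markers x clones character
#'   matrix).
#' @export
calls <- function(x) assay(x, "calls")

#' @describeIn CloneTable logical, half meganuclease site retained per clone.
#' @export
halfSitePresent <- function(x) colData(x)$halfSitePresent

#' @describeIn CloneTable logical, clone survived drug selection.
#' @export
isSelected <- function(x) colData(x)$selected

#' @describeIn CloneTable ground-truth mechanism labels (NA if unknown).
#' @export
truthMechanism <- function(x) colData(x)$truthMechanism

#' @describeIn CloneTable total number of events drawn (including rejected
#'   ones) to produce the table, or NA when not simulated.
#' @export
attempts <- function(x) metadata(x)$attempts

setMethod("show", "CloneTable", function(object) {
    cat(sprintf("CloneTable: %d clones x %d markers\n",
                ncol(object), nrow(object)))
    tm <- truthMechanism(object)
    if (!all(is.na(tm))) {
        tab <- table(tm, useNA = "no")
        cat("  mechanisms:",
            paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    }
    if (!is.na(attempts(object)))
        cat(sprintf("  attempts: %g (acceptance %.3f)\n", attempts(object),
                    ncol(object) / attempts(object)))
    cat(sprintf("  provenance: %s\n", metadata(object)$provenance))
})
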