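#' Construct a MarkerMap
#'
#' @param markers a data.frame (or DataFrame) with columns \code{id},
#'   \code{arm} ("LEFT"/"RIGHT"), \code{distance} (bp > 0 from the cassette
#'   junction) and \code{kind} ("SNP", "HAIRPIN" or "HALF_SITE").
#' @param armLengthLeft,armLengthRight homology-arm lengths in bp.
#' @param cassetteId name of the selection cassette (default "NEO").
#' @param validate if \code{TRUE} (default) reject invalid geometry; set to
#'   \code{FALSE} to build an object for inspection with
#'   [validateMarkerMap()].
#' @return a [MarkerMap-class] object.
#' @examples
#' map <- makeDefaultMap()
#' map
#' signedDistance(map, c("NcoI", "SacI"))
#' @export
MarkerMap <- function(markers, armLengthLeft, armLengthRight,
                      cassetteId = "NEO", validate = TRUE) {
    markers <- DataFrame(id = as.character(markers$id),
                         arm = as.character(markers$arm),
                         distance = as.numeric(markers$distance),
                         kind = as.character(markers$kind))
    obj <- new("MarkerMap", markers = markers,
               armLengths = c(left = as.numeric(armLengthLeft),
                              right = as.numeric(armLengthRight)),
               cassetteId = as.character(cassetteId))
    if (validate) {
        v <- validateMarkerMap(obj)
        if (length(v))
            stop("invalid MarkerMap:\n  ", paste(v, collapse = "\n  "))
    }
    obj
}

#' Validate marker-map geometry
#'
#' Checks every map invariant and returns the violations found instead of
#' throwing, so malformed configurations can be reported in full.
#'
#' @param map a [MarkerMap-class] (possibly built with \code{validate =
#'   FALSE}).
#' @return character vector of violation descriptions, each naming the marker
#'   and rule concerned; empty when the map is valid.
#' @export
validateMarkerMap <- function(map) {
    m <- map@markers
    msg <- character()
    if (length(map@armLengths) != 2L ||
        !identical(names(map@armLengths), c("left", "right")) ||
        any(!is.finite(map@armLengths)) || any(map@armLengths <= 0))
        msg <- c(msg, "armLengths must be positive finite c(left=, right=)")
    bad <- !m$arm %in% ARMS
    if (any(bad))
        msg <- c(msg, sprintf("marker %s: arm must be LEFT or RIGHT",
                              m$id[bad]))
    bad <- !m$kind %in% MARKER_KINDS
    if (any(bad))
        msg <- c(msg, sprintf("marker %s: unknown kind '%s'",
                              m$id[bad], m$kind[bad]))
    dup <- unique(m$id[duplicated(m$id)])
    if (length(dup))
        msg <- c(msg, sprintf("marker id '%s' is not unique", dup))
    if (sum(m$kind == "HALF_SITE") > 1L)
        msg <- c(msg, "at most one HALF_SITE marker is allowed per map")
    if (length(msg) == 0L || all(grepl("^marker id", msg))) {
        lim <- unname(map@armLengths[ifelse(m$arm == "LEFT", "left", "right")])
        bad <- !is.finite(m$distance) | m$distance <= 0 | m$distance > lim
        if (any(bad))
            msg <- c(msg, sprintf(
                "marker %s: distance %s outside (0, %s] of the %s arm",
                m$id[bad], m$distance[bad], lim[bad], m$arm[bad]))
    }
    msg
}

#' @describeIn MarkerMap marker table (a \code{DataFrame}).
#' @param x,object a \code{MarkerMap}.
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))

#' @export
setMethod("markers", "MarkerMap", function(x) x@markers)

#' @describeIn MarkerMap named arm lengths \code{c(left=, right=)} in bp.
#' @export
setGeneric("armLengths", function(x) standardGeneric("armLengths"))

#' @export
setMethod("armLengths", "MarkerMap", function(x) x@armLengths)

#' @describeIn MarkerMap selection-cassette identifier.
#' @export
setGeneric("cassetteId", function(x) standardGeneric("cassetteId"))

#' @export
setMethod("cassetteId", "MarkerMap", function(x) x@cassetteId)

armLengthOf <- function(map, arm) {
    unname(map@armLengths[ifelse(arm == "LEFT", "left", "right")])
}

## SNP + HAIRPIN markers, i.e. the markers genotyped in a clone table (the
## half-site is carried as a per-clone flag, not a genotype row)
genotypedMarkers <- function(map) {
    m <- map@markers
    m[m$kind != "HALF_SITE", , drop = FALSE]
}

hasHalfSite <- function(map) any(map@markers$kind == "HALF_SITE")

halfSiteMarker <- function(map) {
    m <- map@markers
    m[m$kind == "HALF_SITE", , drop = FALSE]
}

#' Signed distance of markers from the central heterology
#'
#' Markers on the left homology arm get negative positions, markers on the
#' right arm positive positions; the magnitude is the distance from the inner
#' end of the arm (the cassette junction).
#'
#' @param map a [MarkerMap-class].
#' @param id marker id(s); default all markers in map order.
#' @return named numeric vector of signed positions in bp.
#' @examples
#' signedDistance(makeDefaultMap(), "NcoI")  # -547
#' @export
signedDistance <- function(map, id = markers(map)$id) {
    m <- map@markers
    idx <- match(id, m$id)
    if (anyNA(idx))
        stop("unknown marker id(s): ", paste(id[is.na(idx)], collapse = ", "))
    sd <- ifelse(m$arm[idx] == "LEFT", -1, 1) * m$distance[idx]
    names(sd) <- m$id[idx]
    sd
}

setMethod("show", "MarkerMap", function(object) {
    m <- object@markers
    cat(sprintf("MarkerMap: cassette '%s', arms %g/%g bp, %d markers\n",
                object@cassetteId, object@armLengths["left"],
                object@armLengths["right"], nrow(m)))
    sd <- ifelse(m$arm == "LEFT", -1, 1) * m$distance
    o <- order(sd)
    cat(sprintf("  %-8s %-5s %6s  %s\n", m$id[o], m$arm[o], sd[o], m$kind[o]),
        sep = "")
})
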