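## Plain-text readers/writers. Marker maps use a tab-separated key/value
## header followed by a marker table; clone tables are long-format TSV with
## one row per (clone, marker) and clone-level flags repeated on each row.
## Both writers emit one canonical column order so round trips are
## byte-stable.

#' Read / write a marker-map configuration file
#'
#' The format is tab-separated text: header lines
#' \code{cassette_id}, \code{arm_length_left}, \code{arm_length_right}, then
#' a marker table with columns \code{id}, \code{arm}, \code{distance},
#' \code{kind}. Validation failures are reported with the offending line.
#'
#' @param path file path.
#' @return \code{readMarkerMap}: a [MarkerMap-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeMarkerMap(makeDefaultMap(), f)
#' readMarkerMap(f)
#' @export
readMarkerMap <- function(path) {
    lines <- readLines(path)
    keep <- !grepl("^\\s*(#|$)", lines)
    lineNo <- which(keep)
    lines <- lines[keep]
    hdr <- list()
    i <- 1L
    while (i <= length(lines) && !grepl("^id\t", lines[i])) {
        kv <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(kv) != 2L)
            stop(sprintf("line %d: expected 'key<TAB>value', got '%s'",
                         lineNo[i], lines[i]))
        hdr[[kv[1L]]] <- kv[2L]
        i <- i + 1L
    }
    need <- c("cassette_id", "arm_length_left", "arm_length_right")
    if (!all(need %in% names(hdr)))
        stop("missing header key(s): ",
             paste(setdiff(need, names(hdr)), collapse = ", "))
    if (i > length(lines))
        stop("missing marker table header 'id\tarm\tdistance\tkind'")
    cols <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (!identical(cols, c("id", "arm", "distance", "kind")))
        stop(sprintf("line %d: marker columns must be id, arm, distance, kind",
                     lineNo[i]))
    body <- lines[-seq_len(i)]
    bodyNo <- lineNo[-seq_len(i)]
    parts <- strsplit(body, "\t", fixed = TRUE)
    bad <- lengths(parts) != 4L
    if (any(bad))
        stop(sprintf("line %d: malformed marker line '%s'",
                     bodyNo[bad][1L], body[bad][1L]))
    m <- data.frame(id = vapply(parts, `[[`, "", 1L),
                    arm = vapply(parts, `[[`, "", 2L),
                    distance = as.numeric(vapply(parts, `[[`, "", 3L)),
                    kind = vapply(parts, `[[`, "", 4L))
    dup <- duplicated(m$id)
    if (any(dup))
        stop(sprintf("line %d: duplicate marker id '%s'",
                     bodyNo[dup][1L], m$id[dup][1L]))
    map <- MarkerMap(m, as.numeric(hdr$arm_length_left),
                     as.numeric(hdr$arm_length_right),
                     cassetteId = hdr$cassette_id, validate = FALSE)
    v <- validateMarkerMap(map)
    if (length(v))
        stop("invalid marker map in ", path, ":\n  ",
             paste(v, collapse = "\n  "))
    map
}

#' @rdname readMarkerMap
#' @param map a [MarkerMap-class].
#' @return \code{writeMarkerMap}: \code{path}, invisibly.
#' @export
writeMarkerMap <- function(map, path) {
    stopifnot(is(map, "MarkerMap"))
    m <- map@markers
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("cassette_id\t%s", map@cassetteId),
                 sprintf("arm_length_left\t%g", map@armLengths["left"]),
                 sprintf("arm_length_right\t%g", map@armLengths["right"]),
                 "id\tarm\tdistance\tkind",
                 sprintf("%s\t%s\t%g\t%s", m$id, m$arm, m$distance, m$kind)),
               con)
    invisible(path)
}

#' Read / write a clone genotype table
#'
#' Long-format TSV with header columns \code{clone_id}, \code{parent_id},
#' \code{half_site}, \code{selected}, \code{truth_mechanism},
#' \code{marker_id}, \code{call} and (when colony subclones exist)
#' \code{subclone_a}, \code{subclone_b}; one row per clone and marker, calls
#' in \code{V, C, S, N}, missing clone-level values written as \code{.}.
#' Every clone must carry a call for every SNP/hairpin marker of the map.
#'
#' @param path file path.
#' @param map the [MarkerMap-class] the calls refer to.
#' @return \code{readCloneTable}: a [CloneTable-class].
#' @export
readCloneTable <- function(path, map) {
    stopifnot(is(map, "MarkerMap"))
    df <- utils::read.delim(path, colClasses = "character")
    need <- c("clone_id", "parent_id", "half_site", "selected",
              "truth_mechanism", "marker_id", "call")
    if (!all(need %in% colnames(df)))
        stop("missing column(s): ", paste(setdiff(need, colnames(df)),
                                          collapse = ", "))
    gm <- genotypedMarkers(map)
    unk <- setdiff(unique(df$marker_id), gm$id)
    if (length(unk))
        stop("unknown marker id(s): ", paste(unk, collapse = ", "))
    badCall <- !df$call %in% CALL_SYMBOLS
    if (any(badCall))
        stop(sprintf("clone %s, marker %s: invalid call symbol '%s'",
                     df$clone_id[badCall][1L], df$marker_id[badCall][1L],
                     df$call[badCall][1L]))
    cloneIds <- unique(df$clone_id)
    haveSub <- all(c("subclone_a", "subclone_b") %in% colnames(df))
    mkCalls <- function(col) {
        m <- matrix(NA_character_, nrow = nrow(gm), ncol = length(cloneIds),
                    dimnames = list(gm$id, cloneIds))
        m[cbind(match(df$marker_id, gm$id), match(df$clone_id, cloneIds))] <-
            df[[col]]
        m
    }
    cl <- mkCalls("call")
    if (anyNA(cl)) {
        miss <- which(is.na(cl), arr.ind = TRUE)[1L, ]
        stop(sprintf("clone %s is missing a call for marker %s",
                     colnames(cl)[miss[2L]], rownames(cl)[miss[1L]]))
    }
    first <- df[!duplicated(df$clone_id), ]
    dot2na <- function(x) ifelse(x == ".", NA_character_, x)
    CloneTable(map, cl,
               halfSitePresent = first$half_site == "1",
               selected = first$selected == "1",
               truthMechanism = dot2na(first$truth_mechanism),
               parentId = dot2na(first$parent_id),
               subcloneA = if (haveSub) mkCalls("subclone_a") else NULL,
               subcloneB = if (haveSub) mkCalls("subclone_b") else NULL,
               provenance = sprintf("read from %s", path))
}

#' @rdname readCloneTable
#' @param table a [CloneTable-class].
#' @return \code{writeCloneTable}: \code{path}, invisibly.
#' @export
writeCloneTable <- function(table, path) {
    stopifnot(is(table, "CloneTable"))
    cl <- calls(table)
    cd <- colData(table)
    na2dot <- function(x) ifelse(is.na(x), ".", x)
    df <- data.frame(
        clone_id = rep(colnames(cl), each = nrow(cl)),
        parent_id = rep(na2dot(cd$parentId), each = nrow(cl)),
        half_site = rep(as.integer(cd$halfSitePresent), each = nrow(cl)),
        selected = rep(as.integer(cd$selected), each = nrow(cl)),
        truth_mechanism = rep(na2dot(cd$truthMechanism), each = nrow(cl)),
        marker_id = rep(rownames(cl), times = ncol(cl)),
        call = as.vector(cl))
    if (all(c("subcloneA", "subcloneB") %in% assayNames(table))) {
        df$subclone_a <- as.vector(assay(table, "subcloneA"))
        df$subclone_b <- as.vector(assay(table, "subcloneB"))
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
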