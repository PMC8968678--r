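#' @describeIn Segmentation-class breakpoint vector (0-based, includes both
#'   endpoints).
#' @param x a Segmentation.
#' @export
breakpoints <- function(x) {
    stopifnot(is(x, "Segmentation"))
    x@breakpoints
}

#' @describeIn Segmentation-class number of segments.
#' @export
segmentCount <- function(x) {
    stopifnot(is(x, "Segmentation"))
    length(x@breakpoints) - 1L
}

#' @describeIn Segmentation-class segments as an \link[IRanges]{IRanges}
#'   (1-based closed, the usual Bioconductor convention).
#' @export
segmentRanges <- function(x) {
    stopifnot(is(x, "Segmentation"))
    bp <- x@breakpoints
    n <- length(bp)
    IRanges(start = bp[-n] + 1L, end = bp[-1L])
}

#' @describeIn Segmentation-class segment sequences as a DNAStringSet.
#' @export
segmentStrings <- function(x) {
    stopifnot(is(x, "Segmentation"))
    s <- as.character(x@sequence)
    bp <- x@breakpoints
    n <- length(bp)
    DNAStringSet(substring(s, bp[-n] + 1L, bp[-1L]))
}

#' @describeIn Segmentation-class the underlying sense-strand sequence.
#' @export
geneSequence <- function(x) {
    if (is(x, "Segmentation") || is(x, "OligoSet") || is(x, "DpSelection"))
        return(x@sequence)
    stop("no gene sequence in an object of class ", class(x))
}

setMethod("show", "Segmentation", function(object) {
    L <- segmentCount(object)
    w <- diff(object@breakpoints)
    cat(sprintf("Segmentation: %d segments (%d-%d bp) over a %d bp sequence",
        L, min(w), max(w), length(object@sequence)))
    if (object@remainder > 0L)
        cat(sprintf(", %d bp remainder", object@remainder))
    cat("\n")
})

#' @describeIn OligoSet-class the oligo sequences (DNAStringSet).
#' @param x an OligoSet.
#' @export
oligos <- function(x) {
    stopifnot(is(x, "OligoSet"))
    x@oligos
}

#' @describeIn OligoSet-class per-oligo coordinate/strand/Tm table.
#' @export
oligoLayout <- function(x) {
    stopifnot(is(x, "OligoSet"))
    x@layout
}

#' @describeIn OligoSet-class interior overlap regions with Tm.
#' @export
overlapRegions <- function(x) {
    stopifnot(is(x, "OligoSet"))
    x@overlaps
}

#' @describeIn OligoSet-class Tm summary statistics list.
#' @export
assemblyStats <- function(x) {
    stopifnot(is(x, "OligoSet"))
    x@stats
}

#' @describeIn OligoSet-class gap length (bp) at each segment junction.
#' @export
junctionGaps <- function(x) {
    if (is(x, "OligoSet")) return(x@junctionGaps)
    if (is(x, "DpSelection")) return(x@gaps)
    stop("junctionGaps is defined for OligoSet and DpSelection objects")
}

#' @describeIn OligoSet-class the tail record.
#' @export
tailInfo <- function(x) {
    stopifnot(is(x, "OligoSet"))
    x@tail
}
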