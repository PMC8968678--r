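#' Solution conditions for duplex melting-temperature calculations
#'
#' Holds the reaction conditions entering the nearest-neighbor melting
#' temperature: total single-strand concentration, monovalent cation
#' concentration (Na+ equivalents) and the duplex symmetry factor.
#'
#' @slot oligoConcentration numeric; total strand concentration C_T in mol/L.
#' @slot monovalentSalt numeric; monovalent cation concentration in mol/L.
#' @slot symmetryFactor numeric; 1 for self-complementary duplexes
#'   (the symmetry entropy correction is then also applied), 4 otherwise.
#' @name ThermoConditions-class
#' @aliases ThermoConditions-class
#' @exportClass ThermoConditions
setClass("ThermoConditions",
    slots = c(
        oligoConcentration = "numeric",
        monovalentSalt = "numeric",
        symmetryFactor = "numeric"
    )
)

setValidity("ThermoConditions", function(object) {
    msg <- character()
    if (length(object@oligoConcentration) != 1L ||
        !is.finite(object@oligoConcentration) ||
        object@oligoConcentration <= 0)
        msg <- c(msg, "oligoConcentration must be a single positive number (mol/L)")
    if (length(object@monovalentSalt) != 1L ||
        !is.finite(object@monovalentSalt) || object@monovalentSalt <= 0)
        msg <- c(msg, "monovalentSalt must be a single positive number (mol/L)")
    if (length(object@symmetryFactor) != 1L ||
        !object@symmetryFactor %in% c(1, 4))
        msg <- c(msg, "symmetryFactor must be 1 (self-complementary) or 4")
    if (length(msg)) msg else TRUE
})

#' Construct solution conditions for Tm calculations
#'
#' Defaults correspond to typical assembly-PCR conditions: 0.2 uM total
#' strand concentration, 50 mM Na+, non-self-complementary duplexes.
#'
#' @param oligoConcentration total strand concentration C_T in mol/L.
#' @param monovalentSalt monovalent cation concentration in mol/L.
#' @param symmetryFactor 1 for self-complementary duplexes, else 4.
#' @return A \linkS4class{ThermoConditions} object.
#' @examples
#' ThermoConditions()
#' ThermoConditions(monovalentSalt = 0.1)
#' @export
ThermoConditions <- function(oligoConcentration = 2e-7,
                             monovalentSalt = 0.05,
                             symmetryFactor = 4) {
    new("ThermoConditions",
        oligoConcentration = as.numeric(oligoConcentration),
        monovalentSalt = as.numeric(monovalentSalt),
        symmetryFactor = as.numeric(symmetryFactor))
}

setMethod("show", "ThermoConditions", function(object) {
    cat("ThermoConditions: C_T =", format(object@oligoConcentration),
        "M, [Na+] =", format(object@monovalentSalt),
        "M, symmetry factor =", object@symmetryFactor, "\n")
})

#' Nearest-neighbor duplex thermodynamics
#'
#' Enthalpy and entropy of a perfectly matched DNA duplex under the unified
#' nearest-neighbor parameter set (stacked-pair terms plus terminal
#' initiation terms), before any salt or concentration correction, together
#' with the phosphate count used by the salt correction.
#'
#' @slot deltaH numeric; duplex enthalpy, kcal/mol.
#' @slot deltaS numeric; duplex entropy, cal/(mol*K).
#' @slot tmCelsius numeric; melting temperature in degrees C, or NA when the
#'   object carries uncorrected thermodynamics only.
#' @slot phosphateCount integer; total phosphates in the duplex, 2*(len-1).
#' @name DuplexThermo-class
#' @aliases DuplexThermo-class
#' @exportClass DuplexThermo
setClass("DuplexThermo",
    slots = c(
        deltaH = "numeric",
        deltaS = "numeric",
        tmCelsius = "numeric",
        phosphateCount = "integer"
    )
)

setValidity("DuplexThermo", function(object) {
    msg <- character()
    if (object@phosphateCount >= 2L && (object@deltaH >= 0 || object@deltaS >= 0))
        msg <- c(msg, "deltaH and deltaS must be negative for a duplex of length >= 2")
    if (length(object@tmCelsius) != 1L ||
        (!is.na(object@tmCelsius) && !is.finite(object@tmCelsius)))
        msg <- c(msg, "tmCelsius must be a finite number or NA")
    if (length(msg)) msg else TRUE
})

setMethod("show", "DuplexThermo", function(object) {
    cat(sprintf("DuplexThermo: dH = %.2f kcal/mol, dS = %.2f cal/(mol*K), %d phosphates",
        object@deltaH, object@deltaS, object@phosphateCount))
    if (!is.na(object@tmCelsius)) cat(sprintf(", Tm = %.4f C", object@tmCelsius))
    cat("\n")
})

#' Assembly design configuration
#'
#' Tunable parameters of the three-stage design procedure.
#'
#' @slot minSegmentLen,maxSegmentLen integer; overlap-segment length band in
#'   bp (default 20-30, which yields oligos of roughly 40-60 bp).
#' @slot convergenceTol numeric; refinement stops once the best boundary move
#'   of a sweep improves the Tm standard deviation by less than this (deg C).
#' @slot shrinkMax integer; maximum bases shrunk from each internal segment
#'   end when building dynamic-programming candidates (per-junction gaps are
#'   then bounded by 2*shrinkMax).
#' @slot mode character; "gapless" (LCR / gapless PCR) or "gapped" (PCR).
#' @slot seed integer; seed for synthetic-fixture generation.
#' @slot sweepRadius integer; maximum boundary shift tried per refinement move.
#' @slot refineInGapped logical; whether the gapped pipeline runs the
#'   refinement stage before the dynamic program (default FALSE: the greedy
#'   result feeds the DP directly, which keeps the integrated algorithm cheap).
#' @slot muStep numeric; spacing (deg C) of the reference-temperature grid
#'   scanned by the dynamic program.
#' @slot minCandidateLen integer; floor on candidate-segment length; NA means
#'   minSegmentLen - 2*shrinkMax.
#' @name AssemblyConfig-class
#' @aliases AssemblyConfig-class
#' @exportClass AssemblyConfig
setClass("AssemblyConfig",
    slots = c(
        minSegmentLen = "integer",
        maxSegmentLen = "integer",
        convergenceTol = "numeric",
        shrinkMax = "integer",
        mode = "character",
        seed = "integer",
        sweepRadius = "integer",
        refineInGapped = "logical",
        muStep = "numeric",
        minCandidateLen = "integer"
    )
)

setValidity("AssemblyConfig", function(object) {
    msg <- character()
    if (object@minSegmentLen <= 0L || object@maxSegmentLen < object@minSegmentLen)
        msg <- c(msg, "need 0 < minSegmentLen <= maxSegmentLen")
    if (!is.finite(object@convergenceTol) || object@convergenceTol <= 0)
        msg <- c(msg, "convergenceTol must be > 0")
    if (object@shrinkMax < 0L)
        msg <- c(msg, "shrinkMax must be >= 0")
    if (!object@mode %in% c("gapless", "gapped"))
        msg <- c(msg, "mode must be 'gapless' or 'gapped'")
    if (object@sweepRadius < 1L)
        msg <- c(msg, "sweepRadius must be >= 1")
    if (!is.finite(object@muStep) || object@muStep <= 0)
        msg <- c(msg, "muStep must be > 0")
    if (length(msg)) msg else TRUE
})

#' Construct an assembly design configuration
#'
#' @param minSegmentLen,maxSegmentLen overlap-segment length bounds (bp).
#' @param convergenceTol refinement convergence threshold in deg C (default
#'   0.001).
#' @param shrinkMax maximum bases shrunk per internal segment end for the
#'   dynamic program (default 2).
#' @param mode "gapless" or "gapped".
#' @param seed integer seed for fixture generation.
#' @param sweepRadius maximum boundary shift per refinement move (bp).
#' @param refineInGapped run refinement before the DP in gapped mode?
#' @param muStep reference-temperature grid spacing (deg C).
#' @param minCandidateLen floor on DP candidate length; NA for
#'   minSegmentLen - 2*shrinkMax.
#' @return An \linkS4class{AssemblyConfig} object.
#' @examples
#' AssemblyConfig(mode = "gapped", shrinkMax = 1)
#' @export
AssemblyConfig <- function(minSegmentLen = 20L, maxSegmentLen = 30L,
                           convergenceTol = 0.001, shrinkMax = 2L,
                           mode = c("gapless", "gapped"), seed = 1L,
                           sweepRadius = 3L, refineInGapped = FALSE,
                           muStep = 0.01, minCandidateLen = NA_integer_) {
    mode <- match.arg(mode)
    new("AssemblyConfig",
        minSegmentLen = as.integer(minSegmentLen),
        maxSegmentLen = as.integer(maxSegmentLen),
        convergenceTol = as.numeric(convergenceTol),
        shrinkMax = as.integer(shrinkMax),
        mode = mode,
        seed = as.integer(seed),
        sweepRadius = as.integer(sweepRadius),
        refineInGapped = isTRUE(refineInGapped),
        muStep = as.numeric(muStep),
        minCandidateLen = as.integer(minCandidateLen))
}

setMethod("show", "AssemblyConfig", function(object) {
    cat(sprintf(
        "AssemblyConfig: segments %d-%d bp, tol %g C, shrinkMax %d, mode '%s'\n",
        object@minSegmentLen, object@maxSegmentLen, object@convergenceTol,
        object@shrinkMax, object@mode))
})

#' A partition of a gene into consecutive overlap segments
#'
#' The central data object of the design: the sense strand of the
#' (possibly tail-extended) gene plus an ordered breakpoint vector.
#' Coordinates are 0-based and half-open: segment i is
#' \code{[breakpoints[i], breakpoints[i+1])}. A positive \code{remainder}
#' marks trailing bases shorter than the minimum segment length that the
#' greedy stage could not consume; \code{\link{ensureOddSegments}} resolves
#' it by tail extension.
#'
#' @slot sequence DNAString; the sense strand.
#' @slot breakpoints integer; strictly increasing, starting at 0 and ending
#'   at length(sequence) - remainder.
#' @slot remainder integer; uncovered trailing bases (0 for a full partition).
#' @name Segmentation-class
#' @aliases Segmentation-class
#' @exportClass Segmentation
setClass("Segmentation",
    contains = "Annotated",
    slots = c(
        sequence = "DNAString",
        breakpoints = "integer",
        remainder = "integer"
    )
)

setValidity("Segmentation", function(object) {
    bp <- object@breakpoints
    msg <- character()
    if (length(bp) < 2L)
        msg <- c(msg, "need at least two breakpoints (one segment)")
    if (length(bp) >= 2L && any(diff(bp) <= 0L))
        msg <- c(msg, "breakpoints must be strictly increasing")
    if (length(bp) && bp[1L] != 0L)
        msg <- c(msg, "first breakpoint must be 0")
    if (object@remainder < 0L)
        msg <- c(msg, "remainder must be >= 0")
    if (length(bp) &&
        bp[length(bp)] != length(object@sequence) - object@remainder)
        msg <- c(msg, "last breakpoint must equal sequence length minus remainder")
    if (length(msg)) msg else TRUE
})

#' Construct a Segmentation
#'
#' @param sequence sense strand as a DNAString or character scalar.
#' @param breakpoints integer vector of 0-based half-open segment boundaries,
#'   starting at 0.
#' @param remainder uncovered trailing bases (default 0).
#' @return A \linkS4class{Segmentation}.
#' @examples
#' Segmentation("ACGTACGTACGTACGTACGT", c(0L, 10L, 20L))
#' @export
Segmentation <- function(sequence, breakpoints, remainder = 0L) {
    if (!is(sequence, "DNAString"))
        sequence <- DNAString(toupper(as.character(sequence)))
    new("Segmentation", sequence = sequence,
        breakpoints = as.integer(breakpoints),
        remainder = as.integer(remainder))
}

#' Record of a tail appended to the input gene
#'
#' Bases appended to the 3' end of the sense strand either to force an odd
#' number of segments or to absorb an undersized final remainder. The tail
#' is removable downstream by PCR with primers matching the original gene
#' termini.
#'
#' @slot sequence character; the appended bases ("" when no tail was needed).
#' @slot width integer; number of appended bases.
#' @name TailInfo-class
#' @aliases TailInfo-class
#' @exportClass TailInfo
setClass("TailInfo",
    slots = c(sequence = "character", width = "integer"))

#' @rdname TailInfo-class
#' @param sequence appended bases as a character scalar.
#' @export
TailInfo <- function(sequence = "") {
    new("TailInfo", sequence = as.character(sequence),
        width = nchar(sequence)[1L])
}

#' @rdname TailInfo-class
#' @param x a TailInfo.
#' @export
hasTail <- function(x) x@width > 0L

setMethod("show", "TailInfo", function(object) {
    if (object@width == 0L) cat("TailInfo: no tail\n")
    else cat("TailInfo:", object@width, "bp appended at 3' end:",
             object@sequence, "\n")
})

#' Candidate segment columns for the dynamic program
#'
#' One column per segment position; each column lists the end-shrunk
#' variants of its parent segment (left/right shrink in 0..shrinkMax, outer
#' ends of terminal segments never shrunk), each with a precomputed Tm.
#' Candidates are ordered by total shrink, then left shrink, so candidate 1
#' is always the unshrunk parent.
#'
#' @slot columns list of data.frames with columns start, end (0-based
#'   half-open), leftShrink, rightShrink, tm.
#' @slot sequence DNAString; the parent gene.
#' @name CandidateColumns-class
#' @aliases CandidateColumns-class
#' @exportClass CandidateColumns
setClass("CandidateColumns",
    slots = c(columns = "list", sequence = "DNAString"))

setValidity("CandidateColumns", function(object) {
    msg <- character()
    for (i in seq_along(object@columns)) {
        d <- object@columns[[i]]
        if (!is.data.frame(d) || nrow(d) < 1L) {
            msg <- c(msg, sprintf("column %d is empty", i)); next
        }
        if (d$leftShrink[1L] != 0L || d$rightShrink[1L] != 0L)
            msg <- c(msg, sprintf("column %d: candidate 1 must be the unshrunk parent", i))
        if (any(d$end <= d$start))
            msg <- c(msg, sprintf("column %d: empty candidate interval", i))
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "CandidateColumns", function(object) {
    n <- vapply(object@columns, nrow, 0L)
    cat(sprintf("CandidateColumns: %d columns, %d-%d candidates each\n",
        length(n), min(n), max(n)))
})

#' A dynamic-programming selection of candidate segments
#'
#' One chosen candidate per column, the resulting Tm standard deviation, and
#' the per-junction gap lengths (bases deleted between consecutive chosen
#' candidates; these become single-covered bases of the gapped design).
#'
#' @slot chosen integer; chosen candidate index per column.
#' @slot candidates data.frame; the chosen intervals with start, end,
#'   leftShrink, rightShrink, tm.
#' @slot objective numeric; sample SD of the chosen Tm profile (deg C).
#' @slot gaps integer; junction gap lengths, each in [0, 2*shrinkMax].
#' @slot totalShrink integer; total deleted bases.
#' @slot mu numeric; the reference temperature whose decomposed cost
#'   produced the winning selection.
#' @slot transitions numeric; number of (prev2, prev1, current) transition
#'   triples the Viterbi recurrence ranged over (the O(L N^3) term).
#' @slot sequence DNAString; the parent gene.
#' @name DpSelection-class
#' @aliases DpSelection-class
#' @exportClass DpSelection
setClass("DpSelection",
    slots = c(
        chosen = "integer",
        candidates = "data.frame",
        objective = "numeric",
        gaps = "integer",
        totalShrink = "integer",
        mu = "numeric",
        transitions = "numeric",
        sequence = "DNAString"
    )
)

setValidity("DpSelection", function(object) {
    msg <- character()
    d <- object@candidates
    if (nrow(d) != length(object@chosen))
        msg <- c(msg, "one chosen candidate per column required")
    if (nrow(d) >= 2L) {
        g <- d$start[-1L] - d$end[-nrow(d)]
        if (any(g < 0L))
            msg <- c(msg, "chosen candidates overlap or are out of order")
        if (!identical(as.integer(g), object@gaps))
            msg <- c(msg, "gaps slot inconsistent with chosen intervals")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "DpSelection", function(object) {
    cat(sprintf(
        "DpSelection: %d columns, SD = %.4f C, %d bases deleted over %d gaps (mu = %.4f C)\n",
        length(object@chosen), object@objective, object@totalShrink,
        sum(object@gaps > 0L), object@mu))
})

#' A strand-assigned oligodeoxynucleotide set
#'
#' The final design: oligo j spans segments j and j+1 of the (tail-extended)
#' gene, odd-numbered oligos on the sense (+) strand and even-numbered ones
#' on the antisense (-) strand, so consecutive oligos share exactly one
#' overlap segment on opposite strands (the imbricated, shingle-like layout
#' that an odd segment count guarantees). In gapped mode the overlap regions
#' are the DP-chosen candidates and junction gaps are single-covered.
#'
#' @slot oligos DNAStringSet; strand-adjusted 5'->3' sequences, named
#'   \code{oligo_<j>|strand=<+/->|span=<start>-<end>|role=<top|bottom>}.
#' @slot layout data.frame; per-oligo start, end (0-based half-open, sense
#'   coordinates), strand, spanned segment indices, length and Tm.
#' @slot overlaps data.frame; interior overlap regions with coordinates and Tm.
#' @slot junctionGaps integer; gap length at each segment junction.
#' @slot mode character; "gapless" or "gapped".
#' @slot tail TailInfo.
#' @slot stats list; Tm summary statistics (see \code{\link{reportStats}}).
#' @slot sequence DNAString; the (tail-extended) gene.
#' @name OligoSet-class
#' @aliases OligoSet-class
#' @exportClass OligoSet
setClass("OligoSet",
    slots = c(
        oligos = "DNAStringSet",
        layout = "data.frame",
        overlaps = "data.frame",
        junctionGaps = "integer",
        mode = "character",
        tail = "TailInfo",
        stats = "list",
        sequence = "DNAString"
    )
)

setValidity("OligoSet", function(object) {
    msg <- character()
    st <- object@layout$strand
    if (length(st) >= 2L && any(st[-1L] == st[-length(st)]))
        msg <- c(msg, "oligo strands must strictly alternate")
    if (!object@mode %in% c("gapless", "gapped"))
        msg <- c(msg, "mode must be 'gapless' or 'gapped'")
    if (length(msg)) msg else TRUE
})

setMethod("show", "OligoSet", function(object) {
    s <- object@stats
    cat(sprintf("OligoSet (%s): %d oligos over a %d bp gene\n",
        object@mode, length(object@oligos), length(object@sequence)))
    cat(sprintf("  overlap Tm  %.4f +/- %.4f C (SD, n-1)\n",
        s$overlapTmMean, s$overlapTmSD))
    cat(sprintf("  oligo Tm    %.4f +/- %.4f C; suggested annealing %.4f C\n",
        s$oligoTmMean, s$oligoTmSD, s$annealingTm))
    if (hasTail(object@tail))
        cat("  tail:", object@tail@width, "bp\n")
})
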