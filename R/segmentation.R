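# Greedy initial segmentation.
#
# The first two segments are chosen jointly (all length pairs in the band,
# least |Tm difference|); every later cut picks the length whose segment Tm
# is closest to the running mean of the segments fixed so far. Interior cuts
# are restricted to lengths that leave at least a minimum-length remainder;
# when no such length exists the greedy falls back to the full band and the
# resulting undersized remainder is resolved later by tail extension, never
# by emitting a short segment.

#' Choose the first two segment lengths
#'
#' Enumerates all (len1, len2) pairs within the segment-length band and
#' returns the pair minimising |Tm(segment 1) - Tm(segment 2)|. Ties go to
#' the smaller total length, then the smaller first length.
#'
#' @param sequence DNAString or character scalar; must be at least
#'   2*minSegmentLen bp.
#' @param config an \linkS4class{AssemblyConfig}.
#' @param conditions a \linkS4class{ThermoConditions}.
#' @return Named integer vector \code{c(first = , second = )}.
#' @examples
#' chooseFirstPair(generateFixture(80, seed = 7))
#' @export
chooseFirstPair <- function(sequence, config = AssemblyConfig(),
                            conditions = ThermoConditions()) {
    validObject(config); validObject(conditions)
    s <- .normalizeSeq(sequence)
    .checkSeq(s, 2L * config@minSegmentLen, "input gene")
    n <- nchar(s)
    eng <- .duplexEngine(s, conditions)
    band <- config@minSegmentLen:config@maxSegmentLen
    g <- expand.grid(l1 = band, l2 = band)
    g <- g[g$l1 + g$l2 <= n, , drop = FALSE]
    t1 <- eng$tm(integer(nrow(g)), g$l1)
    t2 <- eng$tm(g$l1, g$l1 + g$l2)
    k <- order(.roundScore(abs(t1 - t2)), g$l1 + g$l2, g$l1)[1L]
    c(first = g$l1[k], second = g$l2[k])
}

#' Greedy division of a gene into overlap segments
#'
#' Starts from \code{\link{chooseFirstPair}}, then repeatedly cuts the next
#' segment at the length (within the band) whose Tm is closest to the
#' running mean Tm of the segments already fixed; length ties go to the
#' shorter cut. A remainder that already fits the band is consumed as the
#' final segment; a remainder below the minimum length is recorded in the
#' \code{remainder} slot for \code{\link{ensureOddSegments}} to absorb.
#'
#' @inheritParams chooseFirstPair
#' @return A \linkS4class{Segmentation} (deterministic for fixed inputs).
#' @examples
#' seg <- greedySegmentation(generateFixture(300, seed = 3))
#' segmentRanges(seg)
#' @export
greedySegmentation <- function(sequence, config = AssemblyConfig(),
                               conditions = ThermoConditions()) {
    validObject(config); validObject(conditions)
    s <- .normalizeSeq(sequence)
    .checkSeq(s, 2L * config@minSegmentLen, "input gene")
    n <- nchar(s)
    eng <- .duplexEngine(s, conditions)
    pair <- chooseFirstPair(s, config, conditions)
    bp <- c(0L, pair[["first"]], pair[["first"]] + pair[["second"]])
    tms <- eng$tm(bp[1:2], bp[2:3])
    band <- config@minSegmentLen:config@maxSegmentLen
    remainder <- 0L
    repeat {
        pos <- bp[length(bp)]
        rem <- n - pos
        if (rem == 0L) break
        if (rem < config@minSegmentLen) { remainder <- rem; break }
        if (rem <= config@maxSegmentLen) {
            bp <- c(bp, n)
            tms <- c(tms, eng$tm(pos, n))
            break
        }
        lens <- band[(rem - band) >= config@minSegmentLen]
        if (!length(lens)) lens <- band  # dead-end band; tail will absorb
        cand <- eng$tm(rep.int(pos, length(lens)), pos + lens)
        k <- which.min(.roundScore(abs(cand - mean(tms))))
        bp <- c(bp, pos + lens[k])
        tms <- c(tms, cand[k])
    }
    Segmentation(DNAString(s), bp, remainder)
}
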