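# From segmentation to oligos.
#
# Oligo j spans segments j and j+1; odd-numbered oligos sit on the sense
# strand, even-numbered ones on the antisense strand, so consecutive oligos
# pair over exactly one shared segment. An odd segment count makes this
# shingle layout close properly, which is why a tail is appended when the
# greedy stage ends on an even count or an undersized remainder.

# Grow a segment from `prefix` (possibly empty) by per-base greedy choice:
# at each position the base (A<C<G<T on ties) whose extended prefix has Tm
# closest to `meanTm` is appended, up to maxLen; the final length is the
# one in [minLen, maxLen] (and beyond the prefix) with least |Tm - meanTm|,
# ties to the shortest.
.growSegment <- function(prefix, minLen, maxLen, meanTm, conditions) {
    bases <- c("A", "C", "G", "T")
    cur <- prefix
    tmAt <- rep(NA_real_, maxLen)
    while (length(cur) < maxLen) {
        sc <- vapply(bases, function(b) .tmSmall(c(cur, b), conditions), 0)
        k <- which.min(.roundScore(abs(sc - meanTm)))
        cur <- c(cur, bases[k])
        tmAt[length(cur)] <- sc[k]
    }
    lens <- max(minLen, length(prefix) + 1L):maxLen
    cur[seq_len(lens[which.min(.roundScore(abs(tmAt[lens] - meanTm)))])]
}

#' Force an odd segment count by tail extension
#'
#' Appends a short tail to the 3' end of the sense strand when the greedy
#' segmentation either left an undersized remainder or produced an even
#' number of segments. Tail bases are chosen greedily, base by base, to
#' bring the Tm of each new final segment as close as possible to the
#' running mean segment Tm. When the remainder case coincides with an odd
#' segment count, two segments are appended (one absorbing the remainder,
#' one pure tail) so the count stays odd. The tail is removable downstream
#' by PCR with primers matching the original termini.
#'
#' @param segmentation a \linkS4class{Segmentation} from
#'   \code{\link{greedySegmentation}}.
#' @param config an \linkS4class{AssemblyConfig}.
#' @param conditions a \linkS4class{ThermoConditions}.
#' @return A list with components \code{segmentation} (odd segment count,
#'   no remainder; the sequence may be tail-extended) and \code{tail}
#'   (a \linkS4class{TailInfo}, zero-width when nothing was appended).
#' @examples
#' res <- ensureOddSegments(greedySegmentation(generateFixture(150, seed = 5)))
#' res$tail
#' @export
ensureOddSegments <- function(segmentation, config = AssemblyConfig(),
                              conditions = ThermoConditions()) {
    stopifnot(is(segmentation, "Segmentation"))
    validObject(config); validObject(conditions)
    L0 <- segmentCount(segmentation)
    r <- segmentation@remainder
    if (r == 0L && L0 %% 2L == 1L)
        return(list(segmentation = segmentation, tail = TailInfo("")))
    s <- as.character(segmentation@sequence)
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    bp <- segmentation@breakpoints
    eng <- .duplexEngine(s, conditions)
    tms <- eng$tm(bp[-(L0 + 1L)], bp[-1L])
    leftover <- if (r > 0L) chars[(bp[L0 + 1L] + 1L):length(chars)] else character()
    nNew <- if (r > 0L && L0 %% 2L == 1L) 2L else 1L
    newSegs <- vector("list", nNew)
    meanTm <- mean(tms)
    newSegs[[1L]] <- .growSegment(leftover, config@minSegmentLen,
                                  config@maxSegmentLen, meanTm, conditions)
    if (nNew == 2L) {
        meanTm <- mean(c(tms, .tmSmall(newSegs[[1L]], conditions)))
        newSegs[[2L]] <- .growSegment(character(), config@minSegmentLen,
                                      config@maxSegmentLen, meanTm, conditions)
    }
    tailBases <- c(newSegs[[1L]][seq_along(newSegs[[1L]]) > length(leftover)],
                   if (nNew == 2L) newSegs[[2L]] else character())
    newSeq <- DNAString(paste(c(chars[seq_len(bp[L0 + 1L])],
                                unlist(newSegs)), collapse = ""))
    newBp <- c(bp, bp[L0 + 1L] + cumsum(lengths(newSegs)))
    list(segmentation = Segmentation(newSeq, newBp, 0L),
         tail = TailInfo(paste(tailBases, collapse = "")))
}

# Shared oligo construction from a table of overlap intervals.
.assembleOligos <- function(gene, intervals, gaps, mode, tail, conditions) {
    L <- nrow(intervals)
    if (L < 3L)
        stop("oligo construction needs at least 3 segments, got ", L)
    if (L %% 2L == 0L)
        stop("even segment count (", L, "); run ensureOddSegments() first")
    s <- as.character(gene)
    eng <- .duplexEngine(s, conditions)
    nO <- L - 1L
    start <- intervals$start[seq_len(nO)]
    end <- intervals$end[seq_len(nO) + 1L]
    strand <- ifelse(seq_len(nO) %% 2L == 1L, "+", "-")
    seqs <- DNAStringSet(substring(s, start + 1L, end))
    minus <- strand == "-"
    seqs[minus] <- reverseComplement(seqs[minus])
    oligoTm <- eng$tm(start, end)
    names(seqs) <- sprintf("oligo_%d|strand=%s|span=%d-%d|role=%s",
                           seq_len(nO), strand, start, end,
                           ifelse(minus, "bottom", "top"))
    layout <- data.frame(
        oligo = seq_len(nO), start = start, end = end, strand = strand,
        segment1 = seq_len(nO), segment2 = seq_len(nO) + 1L,
        length = end - start, tm = oligoTm)
    interior <- seq_len(L)[-c(1L, L)]
    overlaps <- data.frame(
        segment = interior,
        start = intervals$start[interior], end = intervals$end[interior],
        length = intervals$end[interior] - intervals$start[interior],
        tm = intervals$tm[interior])
    stats <- .tmStats(overlaps$tm, oligoTm)
    new("OligoSet", oligos = seqs, layout = layout, overlaps = overlaps,
        junctionGaps = as.integer(gaps), mode = mode, tail = tail,
        stats = stats, sequence = if (is(gene, "DNAString")) gene else DNAString(s))
}

.tmStats <- function(overlapTms, oligoTms) {
    popSD <- function(x) sd(x) * sqrt((length(x) - 1) / length(x))
    list(
        overlapTmMean = mean(overlapTms),
        overlapTmSD = sd(overlapTms),
        overlapTmSDPop = popSD(overlapTms),
        oligoTmMean = mean(oligoTms),
        oligoTmSD = sd(oligoTms),
        oligoTmSDPop = popSD(oligoTms),
        annealingTm = mean(oligoTms),
        nOligos = length(oligoTms),
        nOverlaps = length(overlapTms))
}

#' Build a strand-assigned oligo set
#'
#' From a gapless \linkS4class{Segmentation}, oligo j is the exact
#' concatenation of segments j and j+1; the union of sense oligos and
#' reverse-complemented antisense oligos tiles the (tail-extended) gene with
#' every base covered once (terminal segments) or twice (overlaps). From a
#' gapped \linkS4class{DpSelection}, oligo j runs from the start of chosen
#' candidate j to the end of chosen candidate j+1; bases deleted from the
#' overlap regions remain covered by exactly one strand (the junction gap
#' lies inside oligo j only) and are filled in by polymerase extension
#' during PCR assembly.
#'
#' @param x a \linkS4class{Segmentation} (gapless) or
#'   \linkS4class{DpSelection} (gapped) with an odd number of segments.
#' @param conditions a \linkS4class{ThermoConditions}.
#' @param tail a \linkS4class{TailInfo} to record in the set (as returned by
#'   \code{\link{ensureOddSegments}}).
#' @param ... unused.
#' @return An \linkS4class{OligoSet}.
#' @examples
#' seg <- ensureOddSegments(greedySegmentation(generateFixture(150, seed = 5)))
#' buildOligos(seg$segmentation, tail = seg$tail)
#' @export
setGeneric("buildOligos",
    function(x, conditions = ThermoConditions(), tail = TailInfo(), ...)
        standardGeneric("buildOligos"))

#' @rdname buildOligos
setMethod("buildOligos", "Segmentation", function(x, conditions, tail, ...) {
    validObject(conditions)
    if (x@remainder != 0L)
        stop("segmentation has an unresolved remainder; run ensureOddSegments() first")
    bp <- x@breakpoints
    L <- length(bp) - 1L
    eng <- .duplexEngine(as.character(x@sequence), conditions)
    intervals <- data.frame(start = bp[-(L + 1L)], end = bp[-1L],
                            tm = eng$tm(bp[-(L + 1L)], bp[-1L]))
    .assembleOligos(x@sequence, intervals, integer(L - 1L), "gapless",
                    tail, conditions)
})

#' @rdname buildOligos
setMethod("buildOligos", "DpSelection", function(x, conditions, tail, ...) {
    validObject(conditions)
    .assembleOligos(x@sequence, x@candidates, x@gaps, "gapped",
                    tail, conditions)
})

#' Recompute the Tm summary of an oligo set from its own content
#'
#' Recomputes overlap-region and full-oligo melting temperatures from the
#' stored sequences and coordinates and summarises them: mean and sample SD
#' (divisor n-1, the convention of the printed reports) plus the population
#' SD, and the suggested annealing temperature for the assembly reaction,
#' taken as the mean oligo Tm.
#'
#' @param oligoSet an \linkS4class{OligoSet} with at least 2 oligos.
#' @param conditions a \linkS4class{ThermoConditions}.
#' @return A list; see \code{\link{OligoSet-class}} stats slot.
#' @export
reportStats <- function(oligoSet, conditions = ThermoConditions()) {
    stopifnot(is(oligoSet, "OligoSet"))
    validObject(conditions)
    if (length(oligoSet@oligos) < 2L)
        stop("need at least 2 oligos")
    oligoTms <- vapply(as.character(oligoSet@oligos), meltingTemperature,
                       0, conditions = conditions, USE.NAMES = FALSE)
    s <- as.character(oligoSet@sequence)
    ov <- oligoSet@overlaps
    overlapTms <- vapply(substring(s, ov$start + 1L, ov$end),
                         meltingTemperature, 0, conditions = conditions,
                         USE.NAMES = FALSE)
    .tmStats(overlapTms, oligoTms)
}
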