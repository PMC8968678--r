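# End-to-end driver: greedy -> tail/parity -> (refine) -> (DP) -> oligos.

#' Run the full oligo design pipeline
#'
#' Gapless mode (LCR / gapless PCR): greedy segmentation, tail/parity
#' handling, iterative boundary refinement, oligo construction. Gapped mode
#' (PCR): greedy segmentation, tail/parity handling, optionally refinement
#' (off by default — the dynamic program supersedes it and skipping it keeps
#' the integrated algorithm cheap), candidate-column generation and the
#' Viterbi-style dynamic program, oligo construction. Because the unshrunk
#' selection is always in the DP search space, the gapped design's Tm SD
#' never exceeds that of the segmentation it started from.
#'
#' @param sequence the gene: DNAString, single-record DNAStringSet, or
#'   character scalar.
#' @param config an \linkS4class{AssemblyConfig}; \code{mode} selects the
#'   branch.
#' @param conditions a \linkS4class{ThermoConditions}.
#' @param outPrefix if non-NULL, writes \code{<outPrefix>_oligos.fasta},
#'   \code{<outPrefix>_report.tsv} and \code{<outPrefix>_segments.bed}.
#' @param verbose log per-stage Tm SDs via \code{message()}.
#' @return A list with components \code{oligoSet} (\linkS4class{OligoSet}),
#'   \code{greedy}, \code{segmentation} (the stage feeding oligo
#'   construction), \code{selection} (\linkS4class{DpSelection} or NULL),
#'   \code{tail}, \code{sdTrace} (named per-stage segment-Tm SDs) and
#'   \code{files}.
#' @examples
#' res <- runPipeline(generateFixture(500, seed = 4),
#'                    AssemblyConfig(mode = "gapped"), verbose = FALSE)
#' res$sdTrace
#' assemblyStats(res$oligoSet)$overlapTmSD
#' @export
runPipeline <- function(sequence, config = AssemblyConfig(),
                        conditions = ThermoConditions(),
                        outPrefix = NULL, verbose = TRUE) {
    validObject(config); validObject(conditions)
    gene <- .normalizeSeq(sequence)
    say <- function(...) if (verbose) message(sprintf(...))

    greedy <- greedySegmentation(gene, config, conditions)
    odd <- ensureOddSegments(greedy, config, conditions)
    seg <- odd$segmentation
    sdGreedy <- tmDeviation(overlapTmProfile(seg, conditions))
    say("[greedy] %d segments, segment-Tm SD %.4f C (tail %d bp)",
        segmentCount(seg), sdGreedy, odd$tail@width)

    trace <- c(greedy = sdGreedy)
    selection <- NULL
    if (config@mode == "gapless" || config@refineInGapped) {
        seg <- refineBoundaries(seg, config, conditions)
        trace["refined"] <- tmDeviation(overlapTmProfile(seg, conditions))
        say("[refine] %d accepted moves, segment-Tm SD %.4f C",
            metadata(seg)$sweeps, trace[["refined"]])
    }
    if (config@mode == "gapped") {
        cols <- candidateColumns(seg, config, conditions)
        selection <- dpOptimize(cols, muStep = config@muStep)
        trace["dp"] <- selection@objective
        say("[dp] %d columns, %.0f transition triples, segment-Tm SD %.4f C, %d bases deleted",
            length(selection@chosen), selection@transitions,
            selection@objective, selection@totalShrink)
        oligoSet <- buildOligos(selection, conditions, tail = odd$tail)
    } else {
        oligoSet <- buildOligos(seg, conditions, tail = odd$tail)
    }
    say("[oligos] %d oligos, overlap Tm SD %.4f C, annealing %.4f C",
        length(oligos(oligoSet)), oligoSet@stats$overlapTmSD,
        oligoSet@stats$annealingTm)

    files <- character()
    if (!is.null(outPrefix)) {
        files <- c(
            fasta = writeOligoFasta(oligoSet, paste0(outPrefix, "_oligos.fasta")),
            report = writeAssemblyReport(oligoSet, paste0(outPrefix, "_report.tsv")),
            bed = writeSegmentsBed(
                if (is.null(selection)) seg else selection,
                paste0(outPrefix, "_segments.bed"),
                conditions = conditions))
    }
    list(oligoSet = oligoSet, greedy = greedy, segmentation = seg,
         selection = selection, tail = odd$tail, sdTrace = trace,
         files = files)
}
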