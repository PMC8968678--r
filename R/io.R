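# FASTA / TSV / BED input and output, and seeded fixture generation.

#' Read a single-record gene FASTA
#'
#' @param path path to a FASTA file containing exactly one DNA record of
#'   unambiguous A/C/G/T bases (lowercase is accepted and uppercased).
#' @return A \link[Biostrings]{DNAStringSet} of length 1 (the record id is
#'   kept as its name).
#' @export
readGeneFasta <- function(path) {
    if (!file.exists(path))
        stop("no such file: ", path)
    set <- readDNAStringSet(path)
    if (length(set) != 1L)
        stop("expected exactly 1 FASTA record, got ", length(set))
    .checkSeq(as.character(set[[1L]]), 1L, paste0("record '", names(set), "'"))
    set
}

#' Generate a seeded random DNA fixture
#'
#' Draws an i.i.d. sequence with expected GC content \code{gcFraction};
#' optional motifs (e.g. AT- or GC-rich islands that stress Tm uniformity)
#' are spliced in afterwards at fixed positions. The global RNG state is
#' saved and restored, so the generator is reproducible and side-effect
#' free.
#'
#' @param length sequence length in bp (>= 60).
#' @param gcFraction expected GC fraction in [0, 1].
#' @param seed integer seed.
#' @param motifs optional data.frame with columns \code{start} (1-based) and
#'   \code{seq}; each motif overwrites the fixture at its position.
#' @return A \link[Biostrings]{DNAString}.
#' @examples
#' generateFixture(100, gcFraction = 0.6, seed = 42)
#' generateFixture(100, seed = 1,
#'     motifs = data.frame(start = 41, seq = "AAAAAAAAAAAAAAAAAAAA"))
#' @export
generateFixture <- function(length, gcFraction = 0.5, seed = 1L, motifs = NULL) {
    stopifnot(length >= 60L, gcFraction >= 0, gcFraction <= 1)
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    p <- c((1 - gcFraction) / 2, gcFraction / 2, gcFraction / 2,
           (1 - gcFraction) / 2)
    chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = p)
    if (!is.null(motifs)) {
        for (i in seq_len(nrow(motifs))) {
            m <- strsplit(toupper(motifs$seq[i]), "", fixed = TRUE)[[1L]]
            at <- motifs$start[i]
            stopifnot(at >= 1L, at + length(m) - 1L <= length)
            chars[at:(at + length(m) - 1L)] <- m
        }
    }
    DNAString(paste(chars, collapse = ""))
}

#' Write an oligo set as FASTA
#'
#' Record ids follow
#' \code{oligo_<j>|strand=<+/->|span=<start>-<end>|role=<top|bottom>}
#' with 0-based half-open sense-strand coordinates.
#'
#' @param oligoSet an \linkS4class{OligoSet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeOligoFasta <- function(oligoSet, path) {
    stopifnot(is(oligoSet, "OligoSet"))
    writeXStringSet(oligoSet@oligos, filepath = path)
    invisible(path)
}

#' Write the assembly design report as TSV
#'
#' One row per oligo and per overlap region (type, id, coordinates, strand,
#' length, Tm to four decimals), followed by summary rows with the Tm means,
#' sample and population SDs, the suggested annealing temperature and the
#' tail record.
#'
#' @param oligoSet an \linkS4class{OligoSet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeAssemblyReport <- function(oligoSet, path) {
    stopifnot(is(oligoSet, "OligoSet"))
    lay <- oligoSet@layout
    ov <- oligoSet@overlaps
    f4 <- function(x) sprintf("%.4f", x)
    rows <- rbind(
        data.frame(type = "oligo", id = paste0("oligo_", lay$oligo),
                   start = lay$start, end = lay$end, strand = lay$strand,
                   length = lay$length, tm = f4(lay$tm)),
        data.frame(type = "overlap", id = paste0("overlap_", ov$segment),
                   start = ov$start, end = ov$end, strand = "+",
                   length = ov$length, tm = f4(ov$tm)))
    s <- oligoSet@stats
    summ <- data.frame(
        type = "summary",
        id = c("mode", "mean_overlap_tm", "sd_overlap_tm", "pop_sd_overlap_tm",
               "mean_oligo_tm", "sd_oligo_tm", "pop_sd_oligo_tm",
               "suggested_annealing_tm", "tail_length", "tail_sequence"),
        start = NA_integer_, end = NA_integer_, strand = NA_character_,
        length = NA_integer_,
        tm = c(oligoSet@mode, f4(s$overlapTmMean), f4(s$overlapTmSD),
               f4(s$overlapTmSDPop), f4(s$oligoTmMean), f4(s$oligoTmSD),
               f4(s$oligoTmSDPop), f4(s$annealingTm),
               as.character(oligoSet@tail@width), oligoSet@tail@sequence))
    write.table(rbind(rows, summ), file = path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Export segments (and gaps) as a BED track
#'
#' Segments are written as 0-based half-open BED features named
#' \code{segment_<i>|tm=<Tm>}; for a \linkS4class{DpSelection}, non-empty
#' junction gaps are additionally written as \code{gap_<j>|len=<bp>}.
#'
#' @param x a \linkS4class{Segmentation} or \linkS4class{DpSelection}.
#' @param path output BED file.
#' @param geneName seqname to use for the features.
#' @param conditions a \linkS4class{ThermoConditions} (used to compute
#'   segment Tms for a Segmentation).
#' @return \code{path}, invisibly.
#' @export
writeSegmentsBed <- function(x, path, geneName = "gene",
                             conditions = ThermoConditions()) {
    if (is(x, "Segmentation")) {
        bp <- x@breakpoints
        n <- length(bp)
        starts <- bp[-n]; ends <- bp[-1L]
        tms <- overlapTmProfile(x, conditions)
        nm <- sprintf("segment_%d|tm=%.4f", seq_len(n - 1L), tms)
    } else if (is(x, "DpSelection")) {
        d <- x@candidates
        starts <- d$start; ends <- d$end
        nm <- sprintf("segment_%d|tm=%.4f", seq_len(nrow(d)), d$tm)
        gp <- which(x@gaps > 0L)
        if (length(gp)) {
            starts <- c(starts, d$end[gp])
            ends <- c(ends, d$start[gp + 1L])
            nm <- c(nm, sprintf("gap_%d|len=%d", gp, x@gaps[gp]))
        }
    } else stop("x must be a Segmentation or DpSelection")
    o <- order(starts, ends)
    gr <- GRanges(geneName, IRanges(start = starts[o] + 1L, end = ends[o]))
    names(gr) <- nm[o]
    export(gr, path, format = "bed")
    invisible(path)
}
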