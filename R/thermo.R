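# Nearest-neighbor duplex thermodynamics.
#
# The unified parameter table ships as a plain-text file under extdata so an
# alternate set can be dropped in; it is parsed once per session and cached.
# Tm(K) = 1000 * dH / (dS_corrected + R * ln(C_T / x))
# with the entropic salt correction dS + 0.368 * (phosphates/2) * ln[Na+],
# phosphates = 2 * (len - 1), and the symmetry entropy term added when the
# duplex is declared self-complementary (x = 1).

.nnParams <- function() {
    if (!is.null(.pkgEnv$nn)) return(.pkgEnv$nn)
    path <- system.file("extdata", "nn_santalucia1998_unified.tsv",
                        package = "OligoTiler", mustWork = TRUE)
    tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    rownames(tab) <- tab$pair
    bases <- c("A", "C", "G", "T")
    dinucs <- as.vector(outer(bases, bases, paste0))
    revcomp2 <- function(d) {
        comp <- c(A = "T", C = "G", G = "C", T = "A")
        paste0(comp[substr(d, 2L, 2L)], comp[substr(d, 1L, 1L)])
    }
    key <- ifelse(dinucs %in% tab$pair, dinucs, revcomp2(dinucs))
    dH <- setNames(tab[key, "dH_kcal_mol"], dinucs)
    dS <- setNames(tab[key, "dS_cal_molK"], dinucs)
    initH <- c(A = tab["INIT_AT", "dH_kcal_mol"], T = tab["INIT_AT", "dH_kcal_mol"],
               G = tab["INIT_GC", "dH_kcal_mol"], C = tab["INIT_GC", "dH_kcal_mol"])
    initS <- c(A = tab["INIT_AT", "dS_cal_molK"], T = tab["INIT_AT", "dS_cal_molK"],
               G = tab["INIT_GC", "dS_cal_molK"], C = tab["INIT_GC", "dS_cal_molK"])
    .pkgEnv$nn <- list(dH = dH, dS = dS, initH = initH, initS = initS,
                       symS = tab["SYM", "dS_cal_molK"])
    .pkgEnv$nn
}

.normalizeSeq <- function(x) {
    if (is(x, "DNAString")) return(as.character(x))
    if (is(x, "DNAStringSet")) {
        if (length(x) != 1L)
            stop("expected a single sequence, got ", length(x), " records")
        return(as.character(x[[1L]]))
    }
    toupper(as.character(x))
}

.checkSeq <- function(s, minLen = 8L, what = "sequence") {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% c("A", "C", "G", "T"))
    if (length(bad))
        stop(sprintf("%s contains disallowed base '%s' at position %d %s",
                     what, chars[bad[1L]], bad[1L],
                     "(only unambiguous A/C/G/T are accepted)"))
    if (length(chars) < minLen)
        stop(sprintf("%s must be at least %d bp, got %d",
                     what, minLen, length(chars)))
    invisible(chars)
}

# Precomputes cumulative stack sums so the Tm of any [start0, end0) window
# (0-based half-open) is O(1); `tm` and `thermo` are vectorized over windows.
.duplexEngine <- function(seq, conditions) {
    p <- .nnParams()
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    n <- length(chars)
    if (n >= 2L) {
        di <- paste0(chars[-n], chars[-1L])
        cumH <- c(0, cumsum(unname(p$dH[di])))
        cumS <- c(0, cumsum(unname(p$dS[di])))
    } else {
        cumH <- cumS <- 0
    }
    iH <- unname(p$initH[chars])
    iS <- unname(p$initS[chars])
    symS <- if (conditions@symmetryFactor == 1) p$symS else 0
    RlnCT <- .RGAS * log(conditions@oligoConcentration / conditions@symmetryFactor)
    lnNa <- log(conditions@monovalentSalt)
    list(
        n = n,
        thermo = function(start0, end0) {
            list(dH = cumH[end0] - cumH[start0 + 1L] + iH[start0 + 1L] + iH[end0],
                 dS = cumS[end0] - cumS[start0 + 1L] + iS[start0 + 1L] + iS[end0])
        },
        tm = function(start0, end0) {
            len <- end0 - start0
            dH <- cumH[end0] - cumH[start0 + 1L] + iH[start0 + 1L] + iH[end0]
            dS <- cumS[end0] - cumS[start0 + 1L] + iS[start0 + 1L] + iS[end0] +
                symS + 0.368 * (len - 1) * lnNa
            1000 * dH / (dS + RlnCT) - 273.15
        }
    )
}

# Selection scores are compared after rounding to 1e-6 C: the cumulative
# stack sums accumulate rounding noise of order 1e-8 C, and exact ties
# (homopolymers, repeated windows) must resolve by the documented
# tie-break rules, not by summation order.
.roundScore <- function(x) round(x, 6L)

# Tm of a short character vector without the length-8 floor; used when
# growing tail segments base by base. A 1-mer degenerates to its doubled
# initiation terms, which keeps the per-base greedy choice defined from the
# first base on.
.tmSmall <- function(chars, conditions) {
    p <- .nnParams()
    n <- length(chars)
    if (n >= 2L) {
        di <- paste0(chars[-n], chars[-1L])
        dH <- sum(p$dH[di])
        dS <- sum(p$dS[di])
    } else {
        dH <- dS <- 0
    }
    dH <- dH + p$initH[chars[1L]] + p$initH[chars[n]]
    dS <- dS + p$initS[chars[1L]] + p$initS[chars[n]]
    if (conditions@symmetryFactor == 1) dS <- dS + p$symS
    dS <- dS + 0.368 * (n - 1) * log(conditions@monovalentSalt)
    unname(1000 * dH /
        (dS + .RGAS * log(conditions@oligoConcentration / conditions@symmetryFactor)) -
        273.15)
}

#' Nearest-neighbor enthalpy and entropy of a DNA duplex
#'
#' Sums the stacked-dinucleotide terms of the unified nearest-neighbor table
#' plus the terminal initiation terms. No salt, concentration or symmetry
#' correction is applied; the returned object carries \code{NA} in its
#' \code{tmCelsius} slot.
#'
#' @param sequence a DNAString or character scalar of at least 8 unambiguous
#'   A/C/G/T bases (shorter duplexes are not meaningful overlaps).
#' @return A \linkS4class{DuplexThermo} with deltaH (kcal/mol), deltaS
#'   (cal/(mol*K)) and phosphateCount = 2*(length-1).
#' @examples
#' nnThermodynamics("ACGTACGTACGTACGTACGT")
#' @export
setGeneric("nnThermodynamics", function(sequence) standardGeneric("nnThermodynamics"))

#' @rdname nnThermodynamics
setMethod("nnThermodynamics", "character", function(sequence) {
    s <- .normalizeSeq(sequence)
    .checkSeq(s, 8L)
    eng <- .duplexEngine(s, ThermoConditions())
    th <- eng$thermo(0L, eng$n)
    new("DuplexThermo", deltaH = th$dH, deltaS = th$dS,
        tmCelsius = NA_real_, phosphateCount = 2L * (eng$n - 1L))
})

#' @rdname nnThermodynamics
setMethod("nnThermodynamics", "DNAString", function(sequence) {
    nnThermodynamics(as.character(sequence))
})

#' Duplex melting temperature under assembly conditions
#'
#' Nearest-neighbor Tm with the entropic salt correction (counting the
#' duplex phosphates) and the strand-concentration term:
#' \deqn{T_m = \frac{1000\,\Delta H}{\Delta S + 0.368\,\frac{N_{phos}}{2}\ln[Na^+] + R\ln(C_T/x)} - 273.15}
#'
#' @param sequence a DNAString or character scalar (>= 8 bp, A/C/G/T only).
#' @param conditions a \linkS4class{ThermoConditions}.
#' @return Melting temperature in degrees Celsius.
#' @examples
#' meltingTemperature("GCGCGCGCGCGCGCGCGCGC")
#' meltingTemperature("ATATATATATATATATATAT", ThermoConditions(monovalentSalt = 0.2))
#' @export
setGeneric("meltingTemperature",
    function(sequence, conditions = ThermoConditions())
        standardGeneric("meltingTemperature"))

#' @rdname meltingTemperature
setMethod("meltingTemperature", "character", function(sequence, conditions) {
    validObject(conditions)
    s <- .normalizeSeq(sequence)
    .checkSeq(s, 8L)
    eng <- .duplexEngine(s, conditions)
    eng$tm(0L, eng$n)
})

#' @rdname meltingTemperature
setMethod("meltingTemperature", "DNAString", function(sequence, conditions) {
    meltingTemperature(as.character(sequence), conditions)
})

#' Per-segment melting-temperature profile of a segmentation
#'
#' @param segmentation a \linkS4class{Segmentation}.
#' @param conditions a \linkS4class{ThermoConditions}.
#' @return Numeric vector, one Tm (deg C) per segment, in segment order.
#' @examples
#' seg <- Segmentation(paste(rep("ACGTT", 12), collapse = ""), c(0L, 20L, 40L, 60L))
#' overlapTmProfile(seg)
#' @export
overlapTmProfile <- function(segmentation, conditions = ThermoConditions()) {
    stopifnot(is(segmentation, "Segmentation"))
    validObject(conditions)
    eng <- .duplexEngine(as.character(segmentation@sequence), conditions)
    bp <- segmentation@breakpoints
    n <- length(bp)
    eng$tm(bp[-n], bp[-1L])
}
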