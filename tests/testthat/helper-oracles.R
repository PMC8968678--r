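# Test-local oracles, implemented independently of the package internals.
# They use only exported package entry points (meltingTemperature on plain
# strings) or their own literal copy of the published parameter table.

# Literal unified nearest-neighbor table (the same published values the
# package ships as a data file, re-keyed here by hand so the oracle does not
# share the package's parser or lookup code).
.ORACLE_NN <- local({
    ten <- list(
        AA = c(-7.9, -22.2), AT = c(-7.2, -20.4), TA = c(-7.2, -21.3),
        CA = c(-8.5, -22.7), GT = c(-8.4, -22.4), CT = c(-7.8, -21.0),
        GA = c(-8.2, -22.2), CG = c(-10.6, -27.2), GC = c(-9.8, -24.4),
        GG = c(-8.0, -19.9))
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    all16 <- list()
    for (a in names(comp)) for (b in names(comp)) {
        d <- paste0(a, b)
        rc <- paste0(comp[b], comp[a])
        all16[[d]] <- if (!is.null(ten[[d]])) ten[[d]] else ten[[rc]]
    }
    all16
})

# Hand-summed nearest-neighbor dH/dS (kcal/mol, cal/mol/K), init terms in.
oracle_nn_sum <- function(seq) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
    dH <- dS <- 0
    for (i in seq_len(length(ch) - 1L)) {
        v <- .ORACLE_NN[[paste0(ch[i], ch[i + 1L])]]
        dH <- dH + v[1L]; dS <- dS + v[2L]
    }
    for (b in c(ch[1L], ch[length(ch)])) {
        if (b %in% c("A", "T")) { dH <- dH + 2.3; dS <- dS + 4.1 }
        else { dH <- dH + 0.1; dS <- dS - 2.8 }
    }
    c(dH = dH, dS = dS)
}

# Oracle Tm for arbitrarily short sequences (>= 1 bp), used to replay the
# tail-growth rule; a 1-mer carries its doubled initiation terms.
oracle_tm_small <- function(chars, CT = 2e-7, Na = 0.05) {
    n <- length(chars)
    dH <- dS <- 0
    if (n >= 2L) {
        for (i in seq_len(n - 1L)) {
            v <- .ORACLE_NN[[paste0(chars[i], chars[i + 1L])]]
            dH <- dH + v[1L]; dS <- dS + v[2L]
        }
    }
    for (b in c(chars[1L], chars[n])) {
        if (b %in% c("A", "T")) { dH <- dH + 2.3; dS <- dS + 4.1 }
        else { dH <- dH + 0.1; dS <- dS - 2.8 }
    }
    dS <- dS + 0.368 * (n - 1L) * log(Na)
    1000 * dH / (dS + 1.987 * log(CT / 4)) - 273.15
}

rc_string <- function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
}

rand_dna <- function(n, seed) as.character(generateFixture(max(n, 60L), seed = seed))

rand_short <- function(n, seed) substr(rand_dna(60L, seed), 1L, n)

seg_string <- function(seg, i) {
    bp <- breakpoints(seg)
    substr(as.character(geneSequence(seg)), bp[i] + 1L, bp[i + 1L])
}

# Exhaustive minimum-SD selection over all per-column candidate choices.
oracle_exhaustive_sd <- function(columns) {
    tms <- lapply(columns@columns, `[[`, "tm")
    grid <- do.call(expand.grid, lapply(tms, seq_along))
    mat <- vapply(seq_along(tms),
                  function(i) tms[[i]][grid[[i]]],
                  numeric(nrow(grid)))
    min(apply(mat, 1L, sd))
}

# Independent steepest-descent boundary refinement: same move set and
# stopping rule as the package, recomputing every Tm from scratch through
# the public single-sequence entry point.
oracle_refine <- function(seg, minL = 20L, maxL = 30L, tol = 0.001,
                          radius = 3L, conditions = ThermoConditions()) {
    s <- as.character(geneSequence(seg))
    bp <- breakpoints(seg)
    segTm <- function(b) {
        n <- length(b)
        vapply(seq_len(n - 1L), function(i)
            meltingTemperature(substr(s, b[i] + 1L, b[i + 1L]), conditions), 0)
    }
    L <- length(bp) - 1L
    best <- sd(segTm(bp))
    repeat {
        moves <- list()
        for (i in 2:L) for (d in setdiff(-radius:radius, 0L)) {
            nb <- bp; nb[i] <- nb[i] + d
            w <- diff(nb)
            if (w[i - 1L] < minL || w[i - 1L] > maxL ||
                w[i] < minL || w[i] > maxL) next
            moves[[length(moves) + 1L]] <- list(bp = nb, sd = sd(segTm(nb)))
        }
        if (!length(moves)) break
        sds <- vapply(moves, `[[`, 0, "sd")
        k <- which.min(sds)
        if (!(best - sds[k] >= tol)) break
        bp <- moves[[k]]$bp
        best <- sds[k]
    }
    list(breakpoints = bp, sd = best)
}

# Batch Tm via an independent reference nearest-neighbor implementation
# (biopython's MeltingTemp with the same published table and corrections).
biopython_tm <- function(seqs, CT = 2e-7, Na = 0.05) {
    infile <- tempfile(); outfile <- tempfile()
    writeLines(seqs, infile)
    script <- tempfile(fileext = ".py")
    writeLines(c(
        "import sys",
        "from Bio.SeqUtils import MeltingTemp as mt",
        sprintf("CT = %.17g; Na = %.17g", CT, Na),
        "c = CT / 2 * 1e9",
        "with open(sys.argv[1]) as fh, open(sys.argv[2], 'w') as out:",
        "    for line in fh:",
        "        seq = line.strip()",
        "        if not seq: continue",
        "        tm = mt.Tm_NN(seq, nn_table=mt.DNA_NN3, dnac1=c, dnac2=c,",
        "                      Na=Na*1000, saltcorr=5)",
        "        out.write(repr(tm) + '\\n')"), script)
    status <- system2("python", c(script, infile, outfile), stdout = TRUE,
                      stderr = TRUE)
    as.numeric(readLines(outfile))
}
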