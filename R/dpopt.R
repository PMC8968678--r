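# Viterbi-style dynamic program over end-shrunk candidate segments.
#
# Minimising the SD of the chosen Tm profile is not additive over columns,
# so it cannot feed a dynamic program directly. The standard decomposition
# is used instead: for any reference temperature mu the cost
# sum_i (Tm_i - mu)^2 IS additive, the selection minimising it for
# mu = mean(S*) of the SD-optimal selection S* is S* itself, and the
# per-column argmin as a function of mu is piecewise constant with
# breakpoints at the midpoints of within-column candidate-Tm pairs. Scanning
# a mu grid that contains one point inside every such interval therefore
# recovers the exact global optimum; muGrid() builds that grid (plus the
# fixed-step scan the user controls). For each mu the minimisation runs as
# a Viterbi pass whose state at column i is the pair of choices at columns
# (i-1, i); each transition minimises over the choice at column i-2, so the
# recurrence ranges over N^3 transition triples per column — the O(L N^3)
# window of three consecutive columns. The additive per-candidate cost lets
# the predecessor minimum be evaluated once per (i-1)-choice; the
# `transitions` slot of the result records the full triple count.

#' Build end-shrunk candidate columns for the dynamic program
#'
#' Column i holds every (leftShrink, rightShrink) variant of segment i with
#' shrinks in 0..shrinkMax, except that the outer ends of the first and last
#' segments are never shrunk (the gene termini must stay covered).
#' Candidates shorter than the configured floor are omitted; candidate 1 is
#' always the unshrunk parent segment.
#'
#' @param segmentation a complete \linkS4class{Segmentation}.
#' @param config an \linkS4class{AssemblyConfig}; \code{shrinkMax} and
#'   \code{minCandidateLen} are used.
#' @param conditions a \linkS4class{ThermoConditions}.
#' @return A \linkS4class{CandidateColumns} with per-candidate Tm precomputed.
#' @examples
#' seg <- ensureOddSegments(greedySegmentation(generateFixture(200, seed = 2)))$segmentation
#' candidateColumns(seg)
#' @export
candidateColumns <- function(segmentation, config = AssemblyConfig(),
                             conditions = ThermoConditions()) {
    stopifnot(is(segmentation, "Segmentation"))
    validObject(config); validObject(conditions)
    if (segmentation@remainder != 0L)
        stop("segmentation has an unresolved remainder; run ensureOddSegments() first")
    bp <- segmentation@breakpoints
    L <- length(bp) - 1L
    smax <- config@shrinkMax
    floorLen <- if (is.na(config@minCandidateLen))
        max(1L, config@minSegmentLen - 2L * smax) else config@minCandidateLen
    eng <- .duplexEngine(as.character(segmentation@sequence), conditions)
    cols <- vector("list", L)
    for (i in seq_len(L)) {
        ls <- if (i == 1L) 0L else 0:smax
        rs <- if (i == L) 0L else 0:smax
        g <- expand.grid(leftShrink = ls, rightShrink = rs)
        g <- g[order(g$leftShrink + g$rightShrink, g$leftShrink, g$rightShrink), ,
               drop = FALSE]
        start <- bp[i] + g$leftShrink
        end <- bp[i + 1L] - g$rightShrink
        keep <- (end - start) >= floorLen
        if (!any(keep))
            stop(sprintf(
                "column %d has no candidates: segment of %d bp cannot satisfy the %d bp candidate floor",
                i, bp[i + 1L] - bp[i], floorLen))
        cols[[i]] <- data.frame(
            start = as.integer(start[keep]), end = as.integer(end[keep]),
            leftShrink = as.integer(g$leftShrink[keep]),
            rightShrink = as.integer(g$rightShrink[keep]),
            tm = eng$tm(start[keep], end[keep]),
            row.names = NULL)
    }
    new("CandidateColumns", columns = cols, sequence = segmentation@sequence)
}

#' Reference-temperature grid for the dynamic program
#'
#' Spans [min, max] of all candidate Tms at \code{step}-degree spacing, and
#' always contains both endpoints and the mean Tm of the unshrunk selection.
#' In addition the grid carries one interior point of every interval between
#' consecutive within-column candidate-Tm midpoints, which makes the mu scan
#' exact (see the package vignette); refining \code{step} therefore never
#' worsens — and cannot improve — the returned objective.
#'
#' @param columns a \linkS4class{CandidateColumns}.
#' @param step grid spacing in degrees Celsius (default 0.01).
#' @return Sorted numeric vector of reference temperatures.
#' @export
muGrid <- function(columns, step = 0.01) {
    stopifnot(is(columns, "CandidateColumns"))
    tms <- lapply(columns@columns, `[[`, "tm")
    lo <- min(unlist(tms)); hi <- max(unlist(tms))
    unshrunkMean <- mean(vapply(tms, `[`, numeric(1L), 1L))
    if (hi - lo < 1e-12) return(lo)
    crit <- unlist(lapply(tms, function(t) {
        if (length(t) < 2L) return(numeric())
        m <- outer(t, t, "+") / 2
        m[upper.tri(m)]
    }))
    crit <- sort(unique(crit[crit > lo & crit < hi]))
    bounds <- c(lo, crit, hi)
    reps <- (bounds[-1L] + bounds[-length(bounds)]) / 2
    sort(unique(c(seq(lo, hi, by = step), lo, hi, unshrunkMean, reps)))
}

#' Minimum-SD selection of candidate segments (Viterbi pass)
#'
#' Finds the one-candidate-per-column selection minimising the sample SD of
#' the chosen Tms. For every reference temperature of \code{\link{muGrid}}
#' a Viterbi pass with pair state (choice at column i-1, choice at column i)
#' minimises the decomposed cost \code{sum (Tm - mu)^2}; the mu whose
#' optimal selection has the least true SD wins. Ties across mu go to fewer
#' deleted bases, then grid order; backtracking ties go to the
#' lowest candidate index (candidates are ordered by total shrink).
#'
#' @param columns a \linkS4class{CandidateColumns} with at least 2 columns.
#' @param muStep grid spacing passed to \code{\link{muGrid}}.
#' @return A \linkS4class{DpSelection}; its \code{objective} never exceeds
#'   the SD of the unshrunk (parent) selection, which is always in the
#'   search space.
#' @examples
#' seg <- ensureOddSegments(greedySegmentation(generateFixture(200, seed = 2)))$segmentation
#' sel <- dpOptimize(candidateColumns(seg))
#' sel
#' @export
dpOptimize <- function(columns, muStep = 0.01) {
    stopifnot(is(columns, "CandidateColumns"))
    cols <- columns@columns
    L <- length(cols)
    if (L < 2L)
        stop("the dynamic program needs at least 2 columns, got ", L)
    mus <- muGrid(columns, step = muStep)
    nMu <- length(mus)
    tmsL <- lapply(cols, `[[`, "tm")
    shrL <- lapply(cols, function(d) d$leftShrink + d$rightShrink)
    Ns <- lengths(tmsL)
    costs <- lapply(tmsL, function(t) outer(t, mus, function(a, b) (a - b)^2))
    # init: V[b, c, m] over choices (column 1, column 2)
    V <- .dpOuterSum(matrix(costs[[1L]], nrow = Ns[1L]),
                     matrix(costs[[2L]], nrow = Ns[2L]), nMu)
    transitions <- Ns[1L] * Ns[2L]
    ptrs <- vector("list", L)
    if (L >= 3L) {
        for (i in 3:L) {
            Na <- Ns[i - 2L]; Nb <- Ns[i - 1L]; Nc <- Ns[i]
            Vm <- matrix(V, nrow = Na)           # Na x (Nb*nMu), column-major
            mb <- Vm[1L, ]
            ptr <- rep.int(1L, Nb * nMu)
            if (Na > 1L) {
                for (a in 2:Na) {
                    va <- Vm[a, ]
                    w <- va < mb                 # strict: ties keep smallest index
                    ptr[w] <- a
                    mb[w] <- va[w]
                }
            }
            ptrs[[i]] <- matrix(ptr, nrow = Nb)
            V <- .dpOuterSum(matrix(mb, nrow = Nb),
                             matrix(costs[[i]], nrow = Nc), nMu)
            transitions <- transitions + as.numeric(Na) * Nb * Nc
        }
    }
    Nb <- Ns[L - 1L]; Nc <- Ns[L]
    M <- matrix(V, nrow = Nb * Nc)               # (b,c) pairs x mu
    bestPair <- max.col(-t(M), ties.method = "first")
    ch <- matrix(0L, nrow = L, ncol = nMu)
    ch[L, ] <- (bestPair - 1L) %/% Nb + 1L
    ch[L - 1L, ] <- (bestPair - 1L) %% Nb + 1L
    if (L >= 3L)
        for (i in L:3)
            ch[i - 2L, ] <- ptrs[[i]][cbind(ch[i - 1L, ], seq_len(nMu))]
    tmMat <- matrix(0, L, nMu)
    shMat <- matrix(0L, L, nMu)
    for (i in seq_len(L)) {
        tmMat[i, ] <- tmsL[[i]][ch[i, ]]
        shMat[i, ] <- shrL[[i]][ch[i, ]]
    }
    mu_means <- colMeans(tmMat)
    sds <- sqrt(colSums((tmMat - rep(mu_means, each = L))^2) / (L - 1L))
    best <- order(sds, colSums(shMat), seq_len(nMu))[1L]
    chosen <- ch[, best]
    sel <- do.call(rbind, lapply(seq_len(L), function(i) cols[[i]][chosen[i], ]))
    rownames(sel) <- NULL
    gaps <- as.integer(sel$start[-1L] - sel$end[-L])
    if (any(gaps < 0L))
        stop("internal error: chosen candidates overlap — infeasible adjacency")
    new("DpSelection",
        chosen = chosen, candidates = sel,
        objective = sd(sel$tm),
        gaps = gaps,
        totalShrink = sum(sel$leftShrink + sel$rightShrink),
        mu = mus[best],
        transitions = transitions,
        sequence = columns@sequence)
}

# V[b, c, m] = A[b, m] + B[c, m] as a 3-d array (Nb, Nc, nMu)
.dpOuterSum <- function(A, B, nMu) {
    Nb <- nrow(A); Nc <- nrow(B)
    aperm(array(A, dim = c(Nb, nMu, Nc)), c(1L, 3L, 2L)) +
        aperm(array(B, dim = c(Nc, nMu, Nb)), c(3L, 1L, 2L))
}
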