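# Iterative boundary refinement.
#
# Repeated sweeps over all internal breakpoints: each sweep tentatively
# shifts every internal boundary by +/-1..sweepRadius bp (respecting the
# length band of both flanking segments), and the single best move of the
# sweep is accepted if and only if it lowers the exact sample SD of the
# segment Tm profile by at least the convergence threshold. The SD is
# bounded below by zero and each accepted move improves it by >= tol, so
# termination is guaranteed.

#' Spread of a melting-temperature profile
#'
#' The single objective of the refinement and dynamic-programming stages:
#' the sample standard deviation (divisor n-1) of a Tm profile.
#'
#' @param profile numeric vector of at least two melting temperatures.
#' @return Sample SD in degrees Celsius.
#' @examples
#' tmDeviation(c(49, 51))  # sqrt(2)
#' @export
tmDeviation <- function(profile) {
    if (length(profile) < 2L)
        stop("a Tm deviation needs at least 2 segments, got ", length(profile))
    sd(profile)
}

#' Iteratively refine segment boundaries toward uniform Tm
#'
#' @param segmentation a complete \linkS4class{Segmentation} (no remainder);
#'   run \code{\link{ensureOddSegments}} first if the greedy stage left one.
#' @param config an \linkS4class{AssemblyConfig}; \code{convergenceTol} and
#'   \code{sweepRadius} control the iteration.
#' @param conditions a \linkS4class{ThermoConditions}.
#' @return A \linkS4class{Segmentation} whose segment-Tm SD is no larger
#'   than the input's. \code{metadata()} carries \code{sweeps} (accepted
#'   moves) and \code{sdTrace} (the SD after each accepted move, starting
#'   with the input SD). Running the function on its own output is a no-op.
#' @examples
#' seg <- greedySegmentation(generateFixture(400, seed = 11))
#' seg <- ensureOddSegments(seg)$segmentation
#' ref <- refineBoundaries(seg)
#' S4Vectors::metadata(ref)$sdTrace
#' @export
refineBoundaries <- function(segmentation, config = AssemblyConfig(),
                             conditions = ThermoConditions()) {
    stopifnot(is(segmentation, "Segmentation"))
    validObject(config); validObject(conditions)
    if (segmentation@remainder != 0L)
        stop("segmentation has an unresolved remainder; run ensureOddSegments() first")
    bp <- segmentation@breakpoints
    L <- length(bp) - 1L
    if (L < 2L)
        stop("refinement needs at least 2 segments")
    eng <- .duplexEngine(as.character(segmentation@sequence), conditions)
    tms <- eng$tm(bp[-(L + 1L)], bp[-1L])
    bestSD <- sd(tms)
    trace <- bestSD
    deltas <- setdiff(-config@sweepRadius:config@sweepRadius, 0L)
    minL <- config@minSegmentLen; maxL <- config@maxSegmentLen
    repeat {
        idx <- rep(2:L, each = length(deltas))     # positions in bp vector
        dlt <- rep.int(deltas, L - 1L)
        newb <- bp[idx] + dlt
        leftLen <- newb - bp[idx - 1L]
        rightLen <- bp[idx + 1L] - newb
        ok <- leftLen >= minL & leftLen <= maxL & rightLen >= minL & rightLen <= maxL
        if (!any(ok)) break
        idx <- idx[ok]; newb <- newb[ok]
        tL <- eng$tm(bp[idx - 1L], newb)
        tR <- eng$tm(newb, bp[idx + 1L])
        s1 <- sum(tms); s2 <- sum(tms^2)
        oldL <- tms[idx - 1L]; oldR <- tms[idx]
        n1 <- s1 - oldL - oldR + tL + tR
        n2 <- s2 - oldL^2 - oldR^2 + tL^2 + tR^2
        v <- (n2 - n1^2 / L) / (L - 1L)
        sds <- sqrt(pmax(v, 0))
        k <- which.min(sds)   # ties: first in (breakpoint, delta) order
        # exact re-check of the incremental arithmetic before accepting
        bpTry <- bp; bpTry[idx[k]] <- newb[k]
        tmsTry <- tms; tmsTry[idx[k] - 1L] <- tL[k]; tmsTry[idx[k]] <- tR[k]
        sdTry <- sd(tmsTry)
        if (!(bestSD - sdTry >= config@convergenceTol)) break
        bp <- bpTry; tms <- tmsTry; bestSD <- sdTry
        trace <- c(trace, bestSD)
    }
    out <- Segmentation(segmentation@sequence, bp, 0L)
    metadata(out) <- list(sweeps = length(trace) - 1L, sdTrace = trace)
    out
}
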