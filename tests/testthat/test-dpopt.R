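cond <- ThermoConditions()

odd_segmentation <- function(n, seed, cfg = AssemblyConfig()) {
    ensureOddSegments(greedySegmentation(rand_dna(n, seed), cfg, cond),
                      cfg, cond)$segmentation
}

test_that("candidate columns have the expected shapes", {
    seg <- odd_segmentation(120L, 12L)
    L <- segmentCount(seg)
    cols2 <- candidateColumns(seg, AssemblyConfig(shrinkMax = 2L), cond)
    n <- vapply(cols2@columns, nrow, 0L)
    expect_identical(n[1L], 3L)                 # left terminus fixed
    expect_identical(n[L], 3L)                  # right terminus fixed
    expect_true(all(n[-c(1L, L)] == 9L))        # (2+1)^2 internal
    # candidate 1 is always the unshrunk parent
    bp <- breakpoints(seg)
    for (i in seq_len(L)) {
        expect_identical(cols2@columns[[i]]$start[1L], bp[i])
        expect_identical(cols2@columns[[i]]$end[1L], bp[i + 1L])
    }
    cols0 <- candidateColumns(seg, AssemblyConfig(shrinkMax = 0L), cond)
    expect_true(all(vapply(cols0@columns, nrow, 0L) == 1L))
})

test_that("shrinkMax 0 makes the DP return the input segmentation", {
    seg <- odd_segmentation(140L, 21L)
    cols <- candidateColumns(seg, AssemblyConfig(shrinkMax = 0L), cond)
    sel <- dpOptimize(cols)
    expect_true(all(sel@chosen == 1L))
    expect_identical(sel@candidates$start, breakpoints(seg)[-(segmentCount(seg) + 1L)])
    expect_equal(sel@objective, tmDeviation(overlapTmProfile(seg, cond)))
    expect_true(all(sel@gaps == 0L))
})

test_that("the DP never does worse than the unshrunk selection", {
    for (seed in c(3L, 14L, 62L)) {
        seg <- odd_segmentation(500L, seed)
        sel <- dpOptimize(candidateColumns(seg, AssemblyConfig(shrinkMax = 2L), cond))
        expect_lte(sel@objective,
                   tmDeviation(overlapTmProfile(seg, cond)) + 1e-12)
        expect_true(all(sel@gaps >= 0L & sel@gaps <= 4L))
    }
})

test_that("the DP selection equals exhaustive enumeration on small instances", {
    lens <- c(100L, 106L, 112L, 118L, 124L, 130L)
    found <- 0L
    seed <- 0L
    while (found < 8L) {
        seed <- seed + 1L
        seg <- odd_segmentation(lens[seed %% 6L + 1L], 700L + seed)
        if (segmentCount(seg) > 6L) next
        found <- found + 1L
        smax <- if (found %% 2L) 1L else 2L
        cols <- candidateColumns(seg, AssemblyConfig(shrinkMax = smax), cond)
        sel <- dpOptimize(cols)
        expect_equal(sel@objective, oracle_exhaustive_sd(cols), tolerance = 1e-9)
    }
})

test_that("the mu grid spans the candidate Tm range", {
    seg <- odd_segmentation(120L, 33L)
    cols <- candidateColumns(seg, AssemblyConfig(shrinkMax = 1L), cond)
    tms <- unlist(lapply(cols@columns, `[[`, "tm"))
    grid <- muGrid(cols)
    expect_equal(min(grid), min(tms))
    expect_equal(max(grid), max(tms))
    # degenerate: all candidates share one Tm
    flat <- new("CandidateColumns",
        columns = rep(list(data.frame(start = 0L, end = 20L, leftShrink = 0L,
                                      rightShrink = 0L, tm = 55)), 3L),
        sequence = Biostrings::DNAString(paste(rep("A", 60L), collapse = "")))
    expect_identical(muGrid(flat), 55)
    # refining the scan step never worsens the objective
    coarse <- dpOptimize(cols, muStep = 0.1)@objective
    fine <- dpOptimize(cols, muStep = 0.01)@objective
    expect_lte(fine, coarse + 1e-12)
})

test_that("transition work scales with the cube of the column width", {
    seg <- odd_segmentation(700L, 9L)
    L <- segmentCount(seg)
    t1 <- dpOptimize(candidateColumns(seg, AssemblyConfig(shrinkMax = 1L), cond))@transitions
    t2 <- dpOptimize(candidateColumns(seg, AssemblyConfig(shrinkMax = 2L), cond))@transitions
    # interior columns have N = (s+1)^2 candidates; the recurrence ranges
    # over N^3 triples per column, so widening 4 -> 9 multiplies the count
    # by ~ (9/4)^3 = 11.4 (terminal columns dilute it slightly)
    expect_gt(t2 / t1, 8)
    expect_lt(t2 / t1, 11.5)
    expect_gt(t2, (L - 4L) * 9^3)   # at least the interior bulk
    expect_lt(t2, L * 9^3)          # never more than N^3 per column
})

test_that("degenerate inputs are rejected", {
    seg <- odd_segmentation(120L, 12L)
    one <- candidateColumns(seg, AssemblyConfig(shrinkMax = 0L), cond)
    one@columns <- one@columns[1L]
    expect_error(dpOptimize(one), "at least 2 columns")
    expect_error(candidateColumns(seg,
        AssemblyConfig(shrinkMax = 0L, minCandidateLen = 50L), cond),
        "no candidates")
})
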