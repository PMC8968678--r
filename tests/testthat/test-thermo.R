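test_that("nearest-neighbor sums match an independent hand-summation oracle", {
    polyA <- paste(rep("A", 20L), collapse = "")
    th <- nnThermodynamics(polyA)
    # 19 AA/TT stacks plus two terminal A:T initiation terms
    expect_equal(th@deltaH, 19 * (-7.9) + 2 * 2.3)
    expect_equal(th@deltaS, 19 * (-22.2) + 2 * 4.1)
    expect_identical(th@phosphateCount, 38L)
    expect_true(is.na(th@tmCelsius))

    for (seed in 1:20) {
        s <- rand_short(sample(8:40, 1L), seed)
        th <- nnThermodynamics(s)
        o <- oracle_nn_sum(s)
        expect_equal(th@deltaH, o[["dH"]], tolerance = 1e-12)
        expect_equal(th@deltaS, o[["dS"]], tolerance = 1e-12)
        expect_lt(th@deltaH, 0)
        expect_lt(th@deltaS, 0)
    }
})

test_that("Tm agrees with a frozen independent nearest-neighbor reference", {
    expect_equal(meltingTemperature("ACGTACGTACGTACGTACGT"),
                 54.92564330076783, tolerance = 1e-9)
    expect_equal(meltingTemperature("GATTACAGATTACAGATTACAGATT"),
                 48.4226557754418, tolerance = 1e-9)
    expect_equal(
        meltingTemperature("CCGGTTAACCGGTTAACCGG",
            ThermoConditions(oligoConcentration = 1e-6, monovalentSalt = 0.2)),
        66.25280471657993, tolerance = 1e-9)
})

test_that("dH, dS and Tm are reverse-complement symmetric", {
    cond <- ThermoConditions()
    for (seed in 1:100) {
        s <- rand_short(sample(8:40, 1L), seed + 500L)
        r <- rc_string(s)
        expect_equal(nnThermodynamics(s)@deltaH, nnThermodynamics(r)@deltaH)
        expect_equal(nnThermodynamics(s)@deltaS, nnThermodynamics(r)@deltaS)
        expect_equal(meltingTemperature(s, cond), meltingTemperature(r, cond))
    }
})

test_that("Tm rises with salt and strand concentration, and with GC content", {
    s <- "ACGGATTTACCAGGATCAAT"
    salts <- c(0.01, 0.05, 0.1, 0.3, 1)
    tms <- vapply(salts, function(na)
        meltingTemperature(s, ThermoConditions(monovalentSalt = na)), 0)
    expect_true(all(diff(tms) > 0))
    cts <- c(1e-8, 1e-7, 1e-6, 1e-5)
    tms <- vapply(cts, function(ct)
        meltingTemperature(s, ThermoConditions(oligoConcentration = ct)), 0)
    expect_true(all(diff(tms) > 0))
    expect_gt(meltingTemperature("GCGCGCGCGCGCGCGCGCGC"),
              meltingTemperature("ATATATATATATATATATAT"))
})

test_that("ambiguous bases, short input and bad conditions are rejected", {
    expect_error(meltingTemperature("ACGTACGTNACGTACGT"), "'N' at position 9")
    expect_error(nnThermodynamics("ACGTRCGTACGTACGT"), "'R' at position 5")
    expect_error(meltingTemperature("ACGTACG"), "at least 8")
    expect_error(ThermoConditions(oligoConcentration = 0))
    expect_error(ThermoConditions(monovalentSalt = -0.1))
    expect_error(ThermoConditions(symmetryFactor = 2))
})

test_that("overlapTmProfile matches per-segment Tm and tracks boundary moves locally", {
    cond <- ThermoConditions()
    s <- rand_dna(60L, 31L)
    seg <- Segmentation(s, c(0L, 20L, 40L, 60L))
    prof <- overlapTmProfile(seg, cond)
    expect_length(prof, 3L)
    for (i in 1:3)
        expect_equal(prof[i], meltingTemperature(seg_string(seg, i), cond))

    # homopolymer with equal segments: flat profile
    homo <- Segmentation(paste(rep("A", 60L), collapse = ""), c(0L, 20L, 40L, 60L))
    expect_equal(tmDeviation(overlapTmProfile(homo, cond)), 0)

    # moving one internal boundary only changes the two flanking segments
    s2 <- rand_dna(120L, 77L)
    a <- Segmentation(s2, c(0L, 25L, 50L, 75L, 100L, 120L))
    b <- Segmentation(s2, c(0L, 25L, 53L, 75L, 100L, 120L))
    pa <- overlapTmProfile(a, cond); pb <- overlapTmProfile(b, cond)
    expect_equal(pa[c(1L, 4L, 5L)], pb[c(1L, 4L, 5L)])
    expect_false(isTRUE(all.equal(pa[2:3], pb[2:3])))
})

test_that("self-complementary symmetry factor applies the symmetry entropy term", {
    pal <- "GCGCATATGCGC"
    expect_identical(pal, rc_string(pal))  # truly self-complementary
    th <- oracle_nn_sum(pal)
    n <- nchar(pal)
    expected <- 1000 * th[["dH"]] /
        (th[["dS"]] - 1.4 + 0.368 * (n - 1) * log(0.05) +
         1.987 * log(2e-7 / 1)) - 273.15
    expect_equal(meltingTemperature(pal, ThermoConditions(symmetryFactor = 1)),
                 expected, tolerance = 1e-12)
})
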