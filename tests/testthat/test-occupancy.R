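test_that("normalization follows the stated order of operations", {
    lib <- toyLibrary(n = 1, id = "norm")
    keys <- names(libraryVariants(lib))           # "1", "0"
    # three technical repeats whose per-million values are 10, 20, 30
    # (for the "1" variant) must average to 20 before the log2
    cnt <- cbind(t0a = c(10L, 999990L), t0b = c(20L, 999980L),
                 t0c = c(30L, 999970L),
                 p1 = c(20L, 999980L), p2 = c(20L, 999980L),
                 p3 = c(20L, 999980L))
    cd <- data.frame(sample_id = colnames(cnt), tf_name = "TF1",
                     timepoint = rep(c(0, 180), each = 3),
                     bio_rep = 1L, tech_rep = rep(1:3, 2))
    vc <- VariantCounts(cnt, data.frame(library_id = "norm", key = keys),
                        cd)
    norm <- normalizeCounts(vc, pseudocount = 0)
    d <- SummarizedExperiment::assay(norm, "delta")
    # tech-rep average is exactly 20 cpm at both timepoints -> delta 0
    expect_equal(unname(d[1, 1]), 0)
    # post counts identical to t0 -> delta 0 everywhere
    expect_true(all(abs(d) < 1e-12))
})

test_that("halved post-activation abundance gives delta of -1", {
    lib <- toyLibrary(n = 1, id = "half")
    vc <- exactCounts(lib, keepFrac = c(0.5, 1))
    d <- SummarizedExperiment::assay(normalizeCounts(vc, pseudocount = 0),
                                     "delta")
    # per-million rescaling makes the contrast relative: the "1" variant
    # halves while "0" is retained, so their difference is exactly -1
    expect_equal(unname(d[1, 1] - d[2, 1]), -1)
})

test_that("missing pre-activation pairs and zero-depth samples are hard
           errors", {
    lib <- toyLibrary(n = 1, id = "err")
    keys <- names(libraryVariants(lib))
    cnt <- cbind(a = c(10L, 10L), b = c(5L, 10L))
    cd <- data.frame(sample_id = c("a", "b"), tf_name = "TF1",
                     timepoint = c(180, 180), bio_rep = 1:2,
                     tech_rep = 1L)
    vc <- VariantCounts(cnt, data.frame(library_id = "err", key = keys),
                        cd)
    expect_error(normalizeCounts(vc), "paired timepoint-0")
    cd2 <- data.frame(sample_id = c("a", "b"), tf_name = "TF1",
                      timepoint = c(0, 180), bio_rep = 1L, tech_rep = 1L)
    vc2 <- VariantCounts(cbind(a = c(0L, 0L), b = c(5L, 10L)),
                         data.frame(library_id = "err", key = keys), cd2)
    expect_error(normalizeCounts(vc2), "zero assigned reads")
})

test_that("occupancy conversion satisfies its defining identities and is
           strictly decreasing", {
    expect_equal(occupancyFromDepletion(-2.3, -2.3), 0)
    expect_equal(occupancyFromDepletion(-1, 0), 0.5)
    expect_equal(occupancyFromDepletion(0, -1), -1)   # negative allowed
    grid <- seq(-5, 1, length.out = 1000)
    occ <- occupancyFromDepletion(grid, 0)
    expect_true(all(diff(occ) < 0))
    expect_true(all(occ <= 1))
})

test_that("per-variant occupancies: fully mutated pinned at 0, known
           depletions recovered, clipping optional", {
    lib <- toyLibrary(n = 2, id = "occ")
    # bound fractions 0.75/0.5/0.5/0 with complete cleavage
    vc <- exactCounts(lib, keepFrac = c(0.25, 0.5, 0.5, 1))
    occ <- occupancies(normalizeCounts(vc, pseudocount = 0))
    expect_equal(occ$occupancy[occ$key == "00"], 0)
    expect_equal(occ$occupancy[occ$key == "11"], 0.75, tolerance = 1e-9)
    expect_equal(occ$occupancy[occ$key == "10"], 0.5, tolerance = 1e-9)
    # a variant retained better than the reference goes negative...
    vc2 <- exactCounts(lib, keepFrac = c(1.2, 1, 1, 1))
    occ2 <- occupancies(normalizeCounts(vc2, pseudocount = 0))
    expect_lt(occ2$occupancy[occ2$key == "11"], 0)
    # ...unless clipped on request
    occ2c <- occupancies(normalizeCounts(vc2, pseudocount = 0),
                         clip = TRUE)
    expect_equal(occ2c$occupancy[occ2c$key == "11"], 0)
})

test_that("row and replicate order do not change the results", {
    lib <- toyLibrary(n = 2, id = "perm")
    model <- BindingModel(p = c(0.5, 0.3), efficiency = c("180" = 0.8))
    vc <- simulateCounts(lib, model, depth = 1e5, seed = 77)
    occ <- occupancies(normalizeCounts(vc))
    perm <- withr::with_seed(1, sample(ncol(vc)))
    vcP <- VariantCounts(
        SummarizedExperiment::assay(vc, "counts")[4:1, perm],
        as.data.frame(SummarizedExperiment::rowData(vc))[4:1, ],
        as.data.frame(SummarizedExperiment::colData(vc))[perm, ])
    occP <- occupancies(normalizeCounts(vcP))
    m <- match(occ$key, occP$key)
    expect_identical(occ$occupancy, occP$occupancy[m])
    expect_identical(occ$sem, occP$sem[m])
})

test_that("nucleosome anchor is the 99th percentile of sliding window
           sums and caps region occupancy at 1", {
    # constant track: every window sums to the same value -> every
    # region is at 100% occupancy
    trk <- SignalTrack("chrI", rep(2, 1000))
    prom <- data.frame(chrom = "chrI", start = c(0L, 500L),
                       end = c(400L, 900L))
    an <- nucleosomeAnchor(trk, prom)
    expect_equal(an$anchor, 2 * 164)
    expect_equal(genomicOccupancy(trk, 100, 264, an), 1)
    # hand-computed 99th percentile on a synthetic ramp
    vals <- rep(seq(0.5, 5, length.out = 100), each = 10)
    trk2 <- SignalTrack("chrI", vals)
    an2 <- nucleosomeAnchor(trk2, data.frame(chrom = "chrI", start = 0L,
                                             end = 1000L))
    starts <- seq(0, 1000 - 164, by = 10)
    csum <- c(0, cumsum(vals))
    expected <- unname(stats::quantile(csum[starts + 165] - csum[starts + 1],
                                       0.99, type = 7))
    expect_equal(an2$anchor, expected)
    # short promoters are skipped with a warning
    expect_warning(
        nucleosomeAnchor(trk, data.frame(chrom = "chrI",
                                         start = c(0L, 10L),
                                         end = c(400L, 50L))),
        "shorter than")
})

test_that("histone occupancy rescales wild-type fold-changes by the
           genomic anchor occupancy", {
    expect_equal(histoneOccupancy(0, 0.8), 0.8)
    expect_equal(histoneOccupancy(1, 0.4), 0.8)
    expect_equal(histoneOccupancy(-1, 0.8), 0.4)
    # the literal published exponent form, for comparison
    expect_equal(histoneOccupancy(-1, 0.5, literal = TRUE), 2^0.5)
    expect_equal(histoneOccupancy(0, 0.8, literal = TRUE), 1)
})
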