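# exact (noise-free) depletion table for a binding model with complete
# cleavage: keep fraction of variant k is 1 - boundFraction(k)
exactNorm <- function(lib, model) {
    bf <- variantBoundFraction(model, names(libraryVariants(lib)))
    normalizeCounts(exactCounts(lib, keepFrac = 1 - as.numeric(bf)),
                    pseudocount = 0)
}

test_that("context occupancy is the generic contrast behind all
           interaction statistics", {
    lib <- toyLibrary(n = 2, id = "ctx")
    vc <- exactCounts(lib, keepFrac = c(0.25, 0.5, 0.5, 1))
    norm <- normalizeCounts(vc, pseudocount = 0)
    # identical target and reference values -> 0
    expect_equal(contextOccupancy(norm, "ctx", "TF1", 180, "10", "01"), 0)
    # single-key sets with a delta difference of -1 -> 0.5
    expect_equal(contextOccupancy(norm, "ctx", "TF1", 180, "10", "00"),
                 0.5)
    expect_error(contextOccupancy(norm, "ctx", "TF1", 180, "10", "10"),
                 "disjoint")
    expect_error(contextOccupancy(norm, "ctx", "TF1", 180, "22", "00"),
                 "missing")
})

test_that("independence expectation equals brute-force
           inclusion-exclusion over the four joint binding states", {
    grid <- expand.grid(a = seq(0, 1, 0.1), b = seq(0, 1, 0.1))
    # oracle: P(bound) over states {neither, A only, B only, both} with
    # independent marginals
    oracle <- with(grid, a * (1 - b) + (1 - a) * b + a * b)
    expect_lt(max(abs(expectedPairOccupancy(grid$a, grid$b) - oracle)),
              1e-12)
    expect_equal(expectedPairOccupancy(0.5, 0.5), 0.75)
})

test_that("cooperativity score recovers injected interactions exactly on
           noise-free data and is symmetric", {
    lib <- toyLibrary(n = 3, id = "coop3")
    cm <- matrix(0, 3, 3); cm[1, 2] <- cm[2, 1] <- 0.15
    model <- BindingModel(p = c(0.3, 0.4, 0.2), interaction = cm,
                          efficiency = c("180" = 1))
    norm <- exactNorm(lib, model)
    cs <- cooperativityScore(norm, lib, "TF1", 180, c(1, 2))
    expect_equal(nrow(cs$contexts), 2L)           # 2^(3-2) contexts
    # closed form: in the all-mutated context the score is c itself; in
    # the site-3-intact context the reference keeps only (1 - p3) of the
    # pool, so the same additive c appears as c / (1 - p3)
    expect_equal(cs$score, mean(c(0.15, 0.15 / (1 - 0.2))),
                 tolerance = 1e-9)
    # symmetry in the pair
    cs2 <- cooperativityScore(norm, lib, "TF1", 180, c(2, 1))
    expect_equal(cs2$score, cs$score)
    # the (1,2) interaction leaks into the (1,3) pair only through the
    # site-2-intact context, by c * p3 / (1 - p2) there
    cs13 <- cooperativityScore(norm, lib, "TF1", 180, c(1, 3))
    expect_equal(cs13$score, 0.15 * 0.2 / (1 - 0.4) / 2,
                 tolerance = 1e-9)
    # observed equal to expected in every context under independence
    m0 <- BindingModel(p = c(0.3, 0.4, 0.2), efficiency = c("180" = 1))
    cs0 <- cooperativityScore(exactNorm(lib, m0), lib, "TF1", 180,
                              c(1, 2))
    expect_lt(max(abs(cs0$contexts$observed - cs0$contexts$expected)),
              1e-9)
    expect_error(cooperativityScore(norm, toyLibrary(n = 1, id = "x1"),
                                    "TF1", 180, c(1, 2)), ">= 2 sites")
})

test_that("all-pair table flags scores above the 10% report cutoff", {
    lib <- toyLibrary(n = 3, id = "all3")
    cm <- matrix(0, 3, 3); cm[1, 3] <- cm[3, 1] <- 0.2
    model <- BindingModel(p = c(0.3, 0.3, 0.3), interaction = cm,
                          efficiency = c("180" = 1))
    tab <- allPairCooperativity(exactNorm(lib, model), lib, "TF1", 180)
    expect_identical(nrow(tab), 3L)
    expect_identical(tab$cooperative,
                     tab$site_A == 1 & tab$site_B == 3)
    expect_true(all(tab$n_contexts == 2L))
})

test_that("motif distance follows the gap convention (0 = adjacent)", {
    sites <- data.frame(start = c(10L, 20L, 15L), end = c(15L, 26L, 20L))
    expect_identical(motifDistance(sites, 1, 3), 0L)  # adjacent spans
    expect_identical(motifDistance(sites, 1, 2), 5L)
    expect_identical(motifDistance(sites, 2, 1), 5L)  # order-free
})

test_that("recruitment measures a non-canonical motif with all self
           sites mutated", {
    region <- toyRegion()
    sites <- toySites(region, 3, tf = c("Msn2", "Msn2", "Tec1"))
    lib <- makeLibrary(region, sites, "rec")
    model <- BindingModel(p = c(0.5, 0.4, 0.3),
                          efficiency = c("180" = 1))
    norm <- exactNorm(lib, model)
    r <- recruitmentScore(norm, lib, "TF1", 180, site = 3,
                          testedTf = "Msn2")
    expect_equal(r$recruitment, 0.3, tolerance = 1e-9)
    expect_identical(r$site_tf, "Tec1")
    # a motif with no effect contributes 0
    m0 <- BindingModel(p = c(0.5, 0.4, 0), efficiency = c("180" = 1))
    r0 <- recruitmentScore(exactNorm(lib, m0), lib, "TF1", 180, site = 3,
                           testedTf = "Msn2")
    expect_lt(abs(r0$recruitment), 1e-9)
    expect_error(recruitmentScore(norm, lib, "TF1", 180, site = 1,
                                  testedTf = "Msn2"), "canonical site")
    expect_error(recruitmentScore(norm, lib, "TF1", 180, site = 3,
                                  testedTf = "Gal4"), "no canonical")
})

test_that("self-motif region occupancy matches the closed-form
           independence oracle", {
    region <- toyRegion()
    sites <- toySites(region, 3, tf = c("Msn2", "Msn2", "Tec1"))
    lib <- makeLibrary(region, sites, "self")
    model <- BindingModel(p = c(0.4, 0.4, 0.25),
                          efficiency = c("180" = 1))
    s <- selfMotifOccupancy(exactNorm(lib, model), lib, "TF1", 180,
                            testedTf = "Msn2")
    expect_identical(s$n_self_sites, 2L)
    expect_equal(s$occupancy, 1 - 0.6^2, tolerance = 1e-9)
    # a single self site with no other sites reduces to its own
    # single-motif occupancy
    lib1 <- toyLibrary(n = 1, id = "s1")
    m1 <- BindingModel(p = 0.35, efficiency = c("180" = 1))
    s1 <- selfMotifOccupancy(exactNorm(lib1, m1), lib1, "TF1", 180,
                             testedTf = "Msn2")
    expect_equal(s1$occupancy, 0.35, tolerance = 1e-9)
})

test_that("TF pairs sharing a driving motif correlate above the screen
           threshold; independent profiles do not", {
    lib <- toyLibrary(n = 2, id = "corr")
    mA <- BindingModel(p = c(0.6, 0.05), efficiency = c("180" = 1))
    mB <- BindingModel(p = c(0.5, 0.00), efficiency = c("180" = 1))
    occA <- occupancies(exactNorm(lib, mA))
    occB <- occupancies(exactNorm(lib, mB))
    res <- tfPairCorrelation(occA, occB, "corr")
    expect_true(res$correlated)
    expect_gt(res$r, 0.4)
    # identical occupancy vectors give r = 1
    expect_equal(tfPairCorrelation(occA, occA, "corr")$r, 1)
    # opposite drivers anti-correlate
    mC <- BindingModel(p = c(0.0, 0.55), efficiency = c("180" = 1))
    occC <- occupancies(exactNorm(lib, mC))
    expect_false(tfPairCorrelation(occA, occC, "corr")$correlated)
    expect_error(tfPairCorrelation(occA[1:2, ], occB, "corr"),
                 "fewer than 3")
})
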