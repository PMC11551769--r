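test_that("every variant sequence maps back to its own key, exhaustively
           for small libraries", {
    for (n in c(2L, 4L, 6L)) {
        lib <- toyLibrary(n = n, id = paste0("L", n))
        v <- libraryVariants(lib)
        res <- countReads(as.character(v), lib)
        expect_identical(res$counts$count, rep(1L, length(v)))
        # and assignRead agrees on a single read
        one <- assignRead(as.character(v[[3]]), lib)
        expect_identical(one$category, "assigned")
        expect_identical(one$key, names(v)[3])
    }
})

test_that("assignment categories partition every read stream", {
    lib <- toyLibrary(n = 3, id = "cons")
    ctrl <- controlSequence(lib, seed = 4)
    v <- libraryVariants(lib)
    cnt <- stats::setNames(rep(5L, length(v)), names(v))
    reads <- simulateReads(lib, cnt, subRate = 0.01, indelRate = 0.15,
                           control = ctrl, controlCount = 12L, seed = 9)
    res <- countReads(reads, lib, control = ctrl)
    expect_identical(sum(res$tallies), length(reads))
    expect_identical(unname(res$tallies["assigned"]),
                     sum(res$counts$count))
    expect_identical(unname(res$tallies["control"]),
                     as.integer(res$control))
    expect_gt(res$tallies["filtered_indel"], 0)
})

test_that("single-base indels are never assigned to a wrong variant", {
    lib <- toyLibrary(n = 3, id = "indel")
    v <- as.character(libraryVariants(lib))
    L <- nchar(v[1])
    # exhaustive 1-bp deletions of every variant at several positions
    for (k in seq_along(v)) {
        for (pos in c(1L, 10L, 80L, L - 10L, L)) {
            del <- paste0(substr(v[k], 1, pos - 1),
                          substr(v[k], pos + 1, L))
            a <- assignRead(del, lib)
            expect_true(a$category %in% c("filtered_indel", "unassigned"))
        }
        # 1-bp insertion
        ins <- paste0(substr(v[k], 1, 40), "A", substr(v[k], 41, L))
        a <- assignRead(ins, lib)
        expect_true(a$category %in% c("filtered_indel", "unassigned"))
    }
})

test_that("off-library variable-position bases are unassigned, not
           misassigned", {
    lib <- toyLibrary(n = 2, id = "off")
    sites <- as.data.frame(motifSites(lib))
    v <- as.character(libraryVariants(lib)[["11"]])
    third <- setdiff(c("A", "C", "G", "T"),
                     c(sites$wt_base[1], sites$mut_base[1]))[1]
    vp <- sites$variable_position[1]
    bad <- paste0(substr(v, 1, vp), third, substr(v, vp + 2, nchar(v)))
    expect_identical(assignRead(bad, lib)$category, "unassigned")
})

test_that("scaffold mismatches are tolerated up to the budget", {
    lib <- toyLibrary(n = 2, id = "mm")
    v <- as.character(libraryVariants(lib)[["10"]])
    sites <- as.data.frame(motifSites(lib))
    # two substitutions away from variable positions and the 3' anchor
    mutateAt <- function(s, pos) {
        b <- substr(s, pos, pos)
        paste0(substr(s, 1, pos - 1), transversion[b],
               substr(s, pos + 1, nchar(s)))
    }
    safe <- setdiff(seq(30, 60), sites$variable_position + 1L)
    r2 <- mutateAt(mutateAt(v, safe[1]), safe[5])
    expect_identical(assignRead(r2, lib)$category, "assigned")
    expect_identical(assignRead(r2, lib)$key, "10")
    r3 <- mutateAt(r2, safe[10])
    expect_identical(assignRead(r3, lib)$category, "unassigned")
})

test_that("simulated multinomial streams are recovered within sampling
           error", {
    lib <- toyLibrary(n = 2, id = "sim")
    v <- libraryVariants(lib)
    withr::with_seed(21, {
        prob <- c(0.4, 0.3, 0.2, 0.1)
        cnt <- stats::setNames(
            as.integer(stats::rmultinom(1, 4000, prob)), names(v))
        reads <- simulateReads(lib, cnt)
        res <- countReads(reads, lib)
        expect_identical(res$counts$count[match(names(v),
                                                res$counts$key)],
                         unname(cnt))
    })
})

test_that("per-sample count results assemble into a valid container", {
    lib <- toyLibrary(n = 2, id = "bind")
    ctrl <- controlSequence(lib, seed = 1)
    v <- libraryVariants(lib)
    mk <- function(cnt, nCtrl) countReads(
        c(rep(as.character(v), cnt), rep(ctrl, nCtrl)), lib,
        control = ctrl)
    sc <- list(s1 = mk(c(4L, 3L, 2L, 1L), 2L),
               s2 = mk(c(1L, 2L, 3L, 4L), 0L))
    meta <- data.frame(sample_id = c("s1", "s2"), tf_name = "TF1",
                       timepoint = c(0, 180), bio_rep = 1L,
                       tech_rep = 1L)
    vc <- bindSampleCounts(sc, meta)
    expect_s4_class(vc, "VariantCounts")
    expect_identical(unname(controlCounts(vc)), c(2L, 0L))
    expect_identical(
        unname(SummarizedExperiment::assay(vc, "counts")[, "s2"]),
        c(1L, 2L, 3L, 4L))
    expect_identical(assignmentTallies(vc)$assigned, c(10L, 10L))
})

test_that("QC drops shallow and decorrelated samples with reasons", {
    lib <- toyLibrary(n = 4, id = "qc")
    model <- BindingModel(p = rep(0.4, 4), efficiency = c("180" = 0.8))
    # a skewed pre-abundance pool so technical repeats share real
    # structure for the correlation check
    vc <- simulateCounts(lib, model, depth = 2e5, bioReps = 1L,
                         techReps = 3L, dirichlet = 5, seed = 31)
    cnt <- SummarizedExperiment::assay(vc, "counts")
    # deep, concordant samples: nothing dropped
    clean <- qcFilterSamples(vc, minReads = 1000, minTechCorr = 0.7)
    expect_identical(ncol(clean), ncol(vc))
    expect_identical(nrow(S4Vectors::metadata(clean)$qc), 0L)
    # shuffling one technical repeat's counts destroys its correlation
    withr::with_seed(5, cnt[, 2] <- sample(cnt[, 2]))
    cnt[, 4] <- 0L                       # and one sample with no reads
    vc2 <- VariantCounts(cnt,
        as.data.frame(SummarizedExperiment::rowData(vc)),
        as.data.frame(SummarizedExperiment::colData(vc)))
    filt <- qcFilterSamples(vc2, minReads = 1000, minTechCorr = 0.7)
    qc <- S4Vectors::metadata(filt)$qc
    expect_identical(ncol(filt), ncol(vc) - 2L)
    expect_true(any(grepl("assigned reads", qc$reason)))
    expect_true(any(grepl("correlation", qc$reason)))
    # dropping everything is an error, not an empty object
    expect_error(qcFilterSamples(vc, minReads = 1e9), "every sample")
})
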