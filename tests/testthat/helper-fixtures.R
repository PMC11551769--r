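# Fixtures are built in code: a deterministic 164 bp region with evenly
# spaced 5 bp motif sites, and a complementary-transversion mutant base
# per site.

toyRegion <- function(len = 164L, seed = 11L) {
    withr::with_seed(seed,
        paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""))
}

transversion <- c(A = "C", C = "A", G = "T", T = "G")

toySites <- function(region, n = 2L, tf = "Msn2") {
    len <- nchar(region)
    starts <- as.integer(round(seq(10, len - 20, length.out = n)))
    vp <- starts + 2L
    wt <- substring(region, vp + 1L, vp + 1L)
    data.frame(tf_name = if (length(tf) == n) tf else rep(tf, n),
               start = starts, end = starts + 5L, strand = "+",
               variable_position = vp, wt_base = wt,
               mut_base = unname(transversion[wt]),
               canonical_for = NA_character_,
               stringsAsFactors = FALSE)
}

toyLibrary <- function(n = 2L, tf = "Msn2", id = "toy", seed = 11L,
                       len = 164L) {
    region <- toyRegion(len, seed)
    suppressWarnings(makeLibrary(region, toySites(region, n, tf), id))
}

uniformPWM <- function(L, tf = "u") PWM(tf, matrix(0.25, 4, L))

randomPWM <- function(L, tf = "r") {
    m <- matrix(stats::rexp(4 * L), 4, L)
    PWM(tf, sweep(m, 2, colSums(m), "/"))
}

# exact per-variant depletion: counts built by hand so that
# every variant's log2 fold change vs t0 is known without sampling noise
exactCounts <- function(lib, keepFrac, tf = "TF1", timepoint = 180,
                        base = 1e5) {
    keys <- names(libraryVariants(lib))
    stopifnot(length(keepFrac) == length(keys))
    cnt <- cbind(t0 = rep(base, length(keys)),
                 t1 = as.integer(round(base * keepFrac)))
    cd <- data.frame(sample_id = c("s_t0", "s_t1"), tf_name = tf,
                     timepoint = c(0, timepoint), bio_rep = 1L,
                     tech_rep = 1L)
    VariantCounts(cnt,
                  data.frame(library_id = regionId(lib), key = keys),
                  cd)
}
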