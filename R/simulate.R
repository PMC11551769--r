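#' Fraction of cells in which a variant region is bound
#'
#' Under the generative model, the fraction of cells in which the TF is
#' bound anywhere on a variant is the inclusion-exclusion combination of
#' its intact sites' independent binding probabilities,
#' \eqn{1 - \prod_{i\,intact}(1 - p_i)}, plus the additive pairwise
#' cooperativity terms \eqn{c_{ij}} of intact site pairs, clamped into
#' [0, 1].
#'
#' @param model a [BindingModel-class].
#' @param key variant key (0/1 string over the model's sites); vectorized.
#' @return bound fraction(s) in [0, 1]; the \code{"clamped"} attribute
#'   counts keys whose raw value fell outside [0, 1].
#' @examples
#' m <- BindingModel(p = c(0.5, 0.5), efficiency = c("180" = 1))
#' variantBoundFraction(m, c("11", "10", "00"))  # 0.75 0.50 0.00
#' @export
variantBoundFraction <- function(model, key) {
    stopifnot(is(model, "BindingModel"))
    validObject(model)
    n <- length(model@p)
    raw <- vapply(key, function(k) {
        bits <- keyBits(k)
        if (length(bits) != n)
            stop("key length ", length(bits), " does not match the ",
                 n, "-site model")
        intact <- which(bits == 1L)
        base <- 1 - prod(1 - model@p[intact])
        coop <- 0
        if (length(intact) > 1L) {
            prs <- utils::combn(intact, 2)
            coop <- sum(model@interaction[t(prs)])
        }
        base + coop
    }, numeric(1), USE.NAMES = FALSE)
    out <- pmin(pmax(raw, 0), 1)
    attr(out, "clamped") <- sum(raw < 0 | raw > 1)
    names(out) <- key
    out
}

#' Simulate an MPBA sequencing experiment with known ground truth
#'
#' Generative twin of the assay: each biological replicate draws
#' pre-activation variant abundances from a symmetric Dirichlet; after
#' MNase activation for time t, a variant's expected abundance is its
#' pre-activation abundance times \eqn{1 - bound \cdot e_t} (bound
#' plasmids are cleaved with efficiency \eqn{e_t} and drop out of the
#' amplicon pool).  Technical replicates are independent
#' gamma-multinomial count draws (gamma perturbation of the expected
#' proportions, shape \code{overdispersion}, emulating PCR jackpotting)
#' from the same biological abundances.  A poorly bound control sequence
#' is spiked at \code{controlFrac} of the pre-activation pool and never
#' cleaved.  All ground-truth parameters are recorded in
#' \code{metadata()$ground_truth}.
#'
#' @param design a [MotifLibrary-class].
#' @param model a [BindingModel-class] with one binding probability per
#'   design site.
#' @param tf name of the MNase-fused TF (default \code{"TF1"}).
#' @param depth reads per sample (default 1e6).
#' @param bioReps,techReps biological and technical replicates (defaults
#'   3 and 2).
#' @param dirichlet symmetric Dirichlet concentration of pre-activation
#'   abundances (default 50; larger = more even library).
#' @param overdispersion gamma shape of the per-sample count noise
#'   (default 50; \code{Inf} = pure multinomial).
#' @param controlFrac control-sequence fraction of the pre-activation
#'   pool (default 0.05).
#' @param seed RNG seed recorded in the output (default: leave the RNG
#'   state untouched).
#' @return a [VariantCounts-class] with samples for timepoint 0 and
#'   every activation timepoint of the model, per replicate.
#' @seealso [simulateReads()], [normalizeCounts()]
#' @export
simulateCounts <- function(design, model, tf = "TF1", depth = 1e6,
                           bioReps = 3L, techReps = 2L, dirichlet = 50,
                           overdispersion = 50, controlFrac = 0.05,
                           seed = NULL) {
    stopifnot(is(design, "MotifLibrary"), is(model, "BindingModel"))
    if (length(model@p) != nSites(design))
        stop("model has ", length(model@p), " sites, design has ",
             nSites(design))
    if (!is.null(seed)) set.seed(seed)
    keys <- names(libraryVariants(design))
    nv <- length(keys)
    bf <- variantBoundFraction(model, keys)
    timepoints <- c(0, as.numeric(names(model@efficiency)))
    eff <- c(0, unname(model@efficiency))
    cols <- list(); cnts <- list(); ctrl <- integer(0)
    pre <- matrix(NA_real_, nv, bioReps,
                  dimnames = list(keys, seq_len(bioReps)))
    for (b in seq_len(bioReps)) {
        g <- stats::rgamma(nv, shape = dirichlet)
        pre[, b] <- g / sum(g)
        for (it in seq_along(timepoints)) {
            keepFrac <- 1 - bf * eff[it]
            w <- c(pre[, b] * keepFrac * (1 - controlFrac), controlFrac)
            for (r in seq_len(techReps)) {
                wNoisy <- if (is.finite(overdispersion))
                    w * stats::rgamma(nv + 1L, shape = overdispersion) /
                        overdispersion
                else w
                draw <- stats::rmultinom(1, size = depth, prob = wNoisy)
                sid <- sprintf("%s_t%g_b%d_r%d", tf, timepoints[it], b, r)
                cols[[sid]] <- data.frame(
                    sample_id = sid, tf_name = tf,
                    timepoint = timepoints[it], bio_rep = b,
                    tech_rep = r, stringsAsFactors = FALSE)
                cnts[[sid]] <- draw[seq_len(nv), 1]
                ctrl[sid] <- draw[nv + 1L, 1]
            }
        }
    }
    cd <- do.call(rbind, cols)
    cnt <- do.call(cbind, cnts)
    rd <- data.frame(library_id = regionId(design), key = keys,
                     stringsAsFactors = FALSE)
    out <- VariantCounts(cnt, rd, cd, controlCounts = ctrl)
    metadata(out)$ground_truth <- list(
        p = model@p, interaction = model@interaction,
        efficiency = model@efficiency,
        bound_fraction = stats::setNames(as.numeric(bf), keys),
        clamped = attr(bf, "clamped"),
        pre_abundance = pre, seed = seed)
    out
}

# inject one substitution/indel set into a single read
.mutateRead <- function(read, nSub, indel) {
    L <- nchar(read)
    s <- strsplit(read, "")[[1]]
    if (nSub > 0) {
        pos <- sample.int(L, nSub)
        for (p in pos)
            s[p] <- sample(setdiff(DNA_BASES4, s[p]), 1)
    }
    if (indel) {
        p <- sample.int(L, 1)
        if (stats::runif(1) < 0.5) s <- s[-p]          # deletion
        else s <- append(s, sample(DNA_BASES4, 1), p)  # insertion
    }
    paste(s, collapse = "")
}

#' Emit simulated amplicon reads for one sample
#'
#' Expands a per-variant count vector into a read stream, optionally
#' injecting per-base substitution errors and 1-bp indels (which the
#' 3'-anchor filter of [assignRead()] is expected to catch).
#'
#' @param design a [MotifLibrary-class].
#' @param counts named integer vector of reads per variant key (e.g. one
#'   column of [simulateCounts()] output).
#' @param subRate per-base substitution error rate (default 0).
#' @param indelRate per-read probability of one 1-bp insertion or
#'   deletion (default 0).
#' @param control optional control sequence; \code{controlCount} reads of
#'   it are appended (subject to the same errors).
#' @param controlCount number of control reads (default 0).
#' @param seed optional RNG seed.
#' @return character vector of reads in shuffled order.
#' @export
simulateReads <- function(design, counts, subRate = 0, indelRate = 0,
                          control = NULL, controlCount = 0L,
                          seed = NULL) {
    stopifnot(is(design, "MotifLibrary"))
    if (!is.null(seed)) set.seed(seed)
    v <- libraryVariants(design)
    stopifnot(all(names(counts) %in% names(v)))
    reads <- rep(as.character(v[names(counts)]), counts)
    if (controlCount > 0) {
        stopifnot(!is.null(control))
        reads <- c(reads, rep(as.character(control), controlCount))
    }
    if (subRate > 0 || indelRate > 0) {
        L <- nchar(reads)
        nSub <- stats::rbinom(length(reads), L, subRate)
        hasIndel <- stats::runif(length(reads)) < indelRate
        touch <- which(nSub > 0 | hasIndel)
        for (i in touch)
            reads[i] <- .mutateRead(reads[i], nSub[i], hasIndel[i])
    }
    sample(reads)
}

#' Scaffold-shuffled poorly bound control sequence
#'
#' Builds an idealized control: the region's bases in permuted order, so
#' base composition is preserved but every annotated motif is destroyed.
#' The permutation is rejected (and redrawn) while any site's wild-type
#' variable base context survives verbatim.
#'
#' @param design a [MotifLibrary-class].
#' @param seed optional RNG seed.
#' @return a single character sequence of the region's length.
#' @export
controlSequence <- function(design, seed = NULL) {
    stopifnot(is(design, "MotifLibrary"))
    if (!is.null(seed)) set.seed(seed)
    region <- as.character(regionSeq(design))
    s <- strsplit(region, "")[[1]]
    sites <- as.data.frame(motifSites(design))
    motifs <- substring(region, sites$start + 1L, sites$end)
    for (i in 1:100) {
        cand <- paste(sample(s), collapse = "")
        hit <- any(vapply(motifs, function(m)
            grepl(m, cand, fixed = TRUE) ||
            grepl(revcompChar(m), cand, fixed = TRUE), logical(1)))
        if (!hit) return(cand)
    }
    stop("could not shuffle away all motifs; region too repetitive")
}
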