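# mean delta over a set of variant keys and the condition's biological
# replicates (log-space mean), for one library
.meanDelta <- function(norm, library, tf, timepoint, keys) {
    delta <- SummarizedExperiment::assay(norm, "delta")
    rd <- SummarizedExperiment::rowData(norm)
    cd <- SummarizedExperiment::colData(norm)
    cols <- which(cd$tf_name == tf & cd$timepoint == timepoint)
    if (!length(cols))
        stop("no condition (", tf, ", t=", timepoint, ") in the table")
    rows <- match(paste(library, keys, sep = "|"),
                  paste(rd$library_id, rd$key, sep = "|"))
    if (anyNA(rows))
        stop("key(s) missing from library '", library, "': ",
             paste(keys[is.na(rows)], collapse = ", "))
    mean(delta[rows, cols])
}

#' Occupancy of one key set contrasted against another
#'
#' The generic contrast underlying every interaction statistic: the mean
#' log2 depletion over the target keys (averaged in log space over keys
#' and biological replicates) is contrasted against the mean over the
#' reference keys and converted to an occupancy fraction with
#' [occupancyFromDepletion()].
#'
#' @param norm a [DepletionTable-class].
#' @param library library id.
#' @param tf,timepoint the (TF, activation time) condition.
#' @param targetKeys,referenceKeys disjoint, non-empty sets of variant
#'   keys.
#' @return occupancy fraction of the target set relative to the
#'   reference set.
#' @export
contextOccupancy <- function(norm, library, tf, timepoint, targetKeys,
                             referenceKeys) {
    stopifnot(is(norm, "DepletionTable"),
              length(targetKeys) > 0, length(referenceKeys) > 0)
    if (length(intersect(targetKeys, referenceKeys)))
        stop("target and reference key sets must be disjoint")
    occupancyFromDepletion(
        .meanDelta(norm, library, tf, timepoint, targetKeys),
        .meanDelta(norm, library, tf, timepoint, referenceKeys))
}

#' Independence expectation for a motif pair
#'
#' The occupancy expected for a sequence with both motifs intact if the
#' two motifs contribute independently:
#' \eqn{1 - (1 - Occ_A)(1 - Occ_B)}.
#'
#' @param occA,occB single-motif occupancy fractions; vectorized.
#' @return expected joint occupancy.
#' @examples
#' expectedPairOccupancy(0.5, 0.5)  # 0.75
#' @export
expectedPairOccupancy <- function(occA, occB) {
    1 - (1 - occA) * (1 - occB)
}

# keys for a context: fix sites A and B to the given states, all other
# sites to the context's bits
.pairKey <- function(n, A, B, a, b, context) {
    bits <- integer(n)
    bits[-c(A, B)] <- context
    bits[A] <- a; bits[B] <- b
    paste(bits, collapse = "")
}

#' Gap between two motif sites
#'
#' The number of bases separating two motif spans (0 when the second
#' motif starts one base after the end of the first; overlapping spans
#' also give 0).
#'
#' @param sites site table of a [MotifLibrary-class].
#' @param A,B site indices.
#' @return integer distance in bp.
#' @export
motifDistance <- function(sites, A, B) {
    sites <- as.data.frame(sites)
    first <- if (sites$start[A] <= sites$start[B]) A else B
    second <- if (first == A) B else A
    max(0L, sites$start[second] - sites$end[first])
}

#' Cooperativity score of a motif pair
#'
#' For every context (each of the \eqn{2^{n-2}} intact/mutated
#' assignments of the other sites) the single-motif occupancies are
#' measured against the both-mutated sequence of the same context,
#' combined into the independence expectation
#' ([expectedPairOccupancy()]), and compared with the observed occupancy
#' of the both-intact sequence.  The cooperativity score is the mean of
#' (observed - expected) over all contexts, with its SEM; positive
#' scores indicate cooperative stabilization, negative ones inhibition.
#'
#' @param norm a [DepletionTable-class].
#' @param design the [MotifLibrary-class] the keys refer to.
#' @param tf,timepoint the condition to score.
#' @param pair integer vector of two site indices (1-based, in site
#'   order).
#' @return list with \code{library_id}, \code{pair}, \code{tf_name},
#'   \code{timepoint}, \code{score}, \code{sem}, \code{distance} (bp gap
#'   between the motifs), \code{contexts}: a data.frame of per-context
#'   \code{context}, \code{occ_A}, \code{occ_B}, \code{observed},
#'   \code{expected}.
#' @export
cooperativityScore <- function(norm, design, tf, timepoint, pair) {
    stopifnot(is(norm, "DepletionTable"), is(design, "MotifLibrary"),
              length(pair) == 2L)
    n <- nSites(design)
    if (n < 2L) stop("cooperativity needs a library with >= 2 sites")
    A <- pair[1]; B <- pair[2]
    lib <- regionId(design)
    contexts <- if (n == 2L) list(integer(0)) else
        lapply(variantKeys(n - 2L), keyBits)
    recs <- lapply(contexts, function(ctx) {
        k00 <- .pairKey(n, A, B, 0L, 0L, ctx)
        ref <- .meanDelta(norm, lib, tf, timepoint, k00)
        occA <- occupancyFromDepletion(
            .meanDelta(norm, lib, tf, timepoint,
                       .pairKey(n, A, B, 1L, 0L, ctx)), ref)
        occB <- occupancyFromDepletion(
            .meanDelta(norm, lib, tf, timepoint,
                       .pairKey(n, A, B, 0L, 1L, ctx)), ref)
        obs <- occupancyFromDepletion(
            .meanDelta(norm, lib, tf, timepoint,
                       .pairKey(n, A, B, 1L, 1L, ctx)), ref)
        data.frame(context = paste(ctx, collapse = ""),
                   occ_A = occA, occ_B = occB, observed = obs,
                   expected = expectedPairOccupancy(occA, occB))
    })
    ctxTab <- do.call(rbind, recs)
    diff <- ctxTab$observed - ctxTab$expected
    list(library_id = lib, pair = c(A, B), tf_name = tf,
         timepoint = timepoint,
         score = mean(diff),
         sem = if (length(diff) > 1L)
             stats::sd(diff) / sqrt(length(diff)) else NA_real_,
         distance = motifDistance(motifSites(design), A, B),
         contexts = ctxTab)
}

#' Cooperativity scores of all motif pairs in a library
#'
#' @inheritParams cooperativityScore
#' @param minScore report threshold used for the \code{cooperative}
#'   flag (default 0.1, i.e. a 10% occupancy gain over independence).
#' @return data.frame with one row per unordered site pair:
#'   \code{library_id}, \code{site_A}, \code{site_B}, \code{tf_A},
#'   \code{tf_B}, \code{distance}, \code{n_contexts}, \code{score},
#'   \code{sem}, \code{observed_mean}, \code{expected_mean},
#'   \code{cooperative}.
#' @export
allPairCooperativity <- function(norm, design, tf, timepoint,
                                 minScore = 0.1) {
    n <- nSites(design)
    if (n < 2L) stop("cooperativity needs a library with >= 2 sites")
    sites <- as.data.frame(motifSites(design))
    pairs <- utils::combn(n, 2)
    rows <- lapply(seq_len(ncol(pairs)), function(i) {
        cs <- cooperativityScore(norm, design, tf, timepoint, pairs[, i])
        data.frame(library_id = cs$library_id,
                   site_A = pairs[1, i], site_B = pairs[2, i],
                   tf_A = sites$tf_name[pairs[1, i]],
                   tf_B = sites$tf_name[pairs[2, i]],
                   distance = cs$distance,
                   n_contexts = nrow(cs$contexts),
                   score = cs$score, sem = cs$sem,
                   observed_mean = mean(cs$contexts$observed),
                   expected_mean = mean(cs$contexts$expected),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$cooperative <- out$score > minScore
    out
}

.selfSites <- function(design, testedTf) {
    sites <- as.data.frame(motifSites(design))
    self <- which(sites$tf_name == testedTf |
                  (!is.na(sites$canonical_for) &
                   sites$canonical_for == testedTf))
    if (!length(self))
        stop("no canonical ('self') site of ", testedTf,
             " annotated in library ", regionId(design))
    self
}

# all keys with the given sites fixed and every other site free
.keysWithFixed <- function(n, fixedIdx, fixedBits) {
    free <- setdiff(seq_len(n), fixedIdx)
    if (!length(free)) {
        bits <- integer(n); bits[fixedIdx] <- fixedBits
        return(paste(bits, collapse = ""))
    }
    vapply(variantKeys(length(free)), function(k) {
        bits <- integer(n)
        bits[fixedIdx] <- fixedBits
        bits[free] <- keyBits(k)
        paste(bits, collapse = "")
    }, character(1), USE.NAMES = FALSE)
}

#' Non-cooperative recruitment by a non-canonical motif
#'
#' Measures how much occupancy a motif of another factor contributes to
#' the tested TF on its own: over all sequences in which every canonical
#' ("self") site of the tested TF is mutated, the mean log2 depletion
#' with the non-canonical motif intact is contrasted against the mean
#' with it mutated, and converted to an occupancy fraction.
#'
#' @param norm a [DepletionTable-class].
#' @param design the [MotifLibrary-class].
#' @param tf,timepoint the measured condition (the MNase-fused TF and
#'   activation time).
#' @param testedTf the TF whose self sites are mutated; defaults to
#'   \code{tf}.
#' @param site index of the non-canonical site under test (must not be a
#'   self site of \code{testedTf}).
#' @return list with \code{library_id}, \code{site}, \code{tested_tf},
#'   \code{site_tf}, \code{recruitment} (occupancy fraction).
#' @export
recruitmentScore <- function(norm, design, tf, timepoint, site,
                             testedTf = tf) {
    n <- nSites(design)
    sites <- as.data.frame(motifSites(design))
    self <- .selfSites(design, testedTf)
    if (site %in% self)
        stop("site ", site, " is a canonical site of ", testedTf)
    target <- .keysWithFixed(n, c(self, site),
                             c(rep(0L, length(self)), 1L))
    ref <- .keysWithFixed(n, c(self, site),
                          c(rep(0L, length(self)), 0L))
    list(library_id = regionId(design), site = site,
         tested_tf = testedTf, site_tf = sites$tf_name[site],
         recruitment = contextOccupancy(norm, regionId(design), tf,
                                        timepoint, target, ref))
}

#' Occupancy attributable to a TF's own motifs jointly
#'
#' Contrasts sequences in which every canonical ("self") site of the
#' tested TF is intact against those in which every self site is
#' mutated, averaging over the states of all other sites, and converts
#' the contrast to an occupancy fraction.
#'
#' @inheritParams recruitmentScore
#' @return list with \code{library_id}, \code{tested_tf},
#'   \code{n_self_sites}, \code{occupancy}.
#' @export
selfMotifOccupancy <- function(norm, design, tf, timepoint,
                               testedTf = tf) {
    n <- nSites(design)
    self <- .selfSites(design, testedTf)
    target <- .keysWithFixed(n, self, rep(1L, length(self)))
    ref <- .keysWithFixed(n, self, rep(0L, length(self)))
    list(library_id = regionId(design), tested_tf = testedTf,
         n_self_sites = length(self),
         occupancy = contextOccupancy(norm, regionId(design), tf,
                                      timepoint, target, ref))
}

#' Correlation of two TFs' occupancy profiles on one library
#'
#' Pearson correlation of per-variant occupancies of two TFs measured on
#' the same library; correlated pairs (r > \code{rThreshold}, default
#' 0.4) are candidates for sharing a driving motif.
#'
#' @param occ1,occ2 occupancy tables from [occupancies()] (possibly for
#'   several conditions; the relevant TF rows are selected).
#' @param library library id.
#' @param tf1,tf2 TF names; defaults: the single TF present in each
#'   table.
#' @param rThreshold flag threshold on Pearson's r (default 0.4).
#' @return list with \code{library_id}, \code{tf1}, \code{tf2}, \code{r},
#'   \code{n} (shared variants), \code{correlated}.
#' @export
tfPairCorrelation <- function(occ1, occ2, library, tf1 = NULL,
                              tf2 = NULL, rThreshold = 0.4) {
    pick <- function(occ, tfWanted) {
        occ <- occ[occ$library_id == library, , drop = FALSE]
        if (is.null(tfWanted)) {
            tfs <- unique(occ$tf_name)
            if (length(tfs) != 1L)
                stop("several TFs present; name the one to use")
            tfWanted <- tfs
        }
        occ <- occ[occ$tf_name == tfWanted, , drop = FALSE]
        if (length(unique(occ$timepoint)) > 1L)
            occ <- occ[occ$timepoint == max(occ$timepoint), , drop = FALSE]
        list(tf = tfWanted, occ = occ)
    }
    a <- pick(occ1, tf1); b <- pick(occ2, tf2)
    m <- merge(a$occ[, c("key", "occupancy")],
               b$occ[, c("key", "occupancy")], by = "key")
    if (nrow(m) < 3L)
        stop("fewer than 3 shared variants; correlation undefined")
    r <- stats::cor(m$occupancy.x, m$occupancy.y)
    list(library_id = library, tf1 = a$tf, tf2 = b$tf, r = r,
         n = nrow(m), correlated = r > rThreshold)
}
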