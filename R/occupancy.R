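#' Per-variant log2 depletion after MNase activation
#'
#' A \code{DepletionTable} is a [SummarizedExperiment::SummarizedExperiment]
#' with one \code{delta} assay: rows are library variants, columns are
#' (TF, activation timepoint, biological replicate) conditions, and each
#' cell is the variant's log2 fold-change between the MNase-activated
#' sample and its paired pre-activation (timepoint 0) sample, after
#' per-million depth scaling and technical-repeat averaging.  Negative
#' values mean depletion (cleavage of bound variants).
#'
#' @seealso [normalizeCounts()], [occupancies()], [cooperativityScore()]
#' @exportClass DepletionTable
setClass("DepletionTable", contains = "SummarizedExperiment")

setValidity("DepletionTable", function(object) {
    if (!"delta" %in% SummarizedExperiment::assayNames(object))
        return("a 'delta' assay is required")
    cd <- SummarizedExperiment::colData(object)
    need <- c("tf_name", "timepoint", "bio_rep")
    if (!all(need %in% names(cd)))
        return(paste("colData lacks:",
                     paste(setdiff(need, names(cd)), collapse = ", ")))
    if (any(cd$timepoint <= 0))
        return("depletion columns must be post-activation (timepoint > 0)")
    TRUE
})

#' Normalize raw variant counts to log2 depletion values
#'
#' The normalization chain: (i) each sample's counts are scaled to
#' reads-per-million of its assigned total; (ii) technical repeats of the
#' same (TF, timepoint, biological replicate) are averaged on the
#' per-million scale; (iii) values are log2-transformed after adding
#' \code{pseudocount}; (iv) each activated condition is normalized to the
#' paired timepoint-0 condition of the same TF and biological replicate
#' (log2 difference).  Biological replicates are kept as separate
#' columns; downstream summaries ([occupancies()], the interaction
#' scores) average them in log space.
#'
#' @param x a [VariantCounts-class].
#' @param pseudocount value added on the per-million scale before log2
#'   (default 1).  A fully mutated reference variant with zero counts in
#'   any sample triggers a warning, since every occupancy is contrasted
#'   against it.
#' @return a [DepletionTable-class].
#' @export
normalizeCounts <- function(x, pseudocount = 1) {
    stopifnot(is(x, "VariantCounts"))
    validObject(x)
    cnt <- SummarizedExperiment::assay(x, "counts")
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    tot <- colSums(cnt)
    if (any(tot == 0))
        stop("sample(s) with zero assigned reads: ",
             paste(cd$sample_id[tot == 0], collapse = ", "),
             " (remove them with qcFilterSamples())")
    cpm <- sweep(cnt, 2, tot, "/") * 1e6
    grp <- paste(cd$tf_name, cd$timepoint, cd$bio_rep, sep = "\r")
    ugrp <- unique(grp)
    avg <- vapply(ugrp, function(g)
        rowMeans(cpm[, grp == g, drop = FALSE]),
        numeric(nrow(cpm)))
    rd <- SummarizedExperiment::rowData(x)
    fmRows <- grepl("^0*$", rd$key)
    if (any(avg[fmRows, , drop = FALSE] == 0))
        warning("fully mutated reference variant has zero counts in at ",
                "least one condition; its depletion (and every occupancy ",
                "contrasted against it) rests on the pseudocount alone")
    lg <- log2(avg + pseudocount)
    meta <- data.frame(do.call(rbind, strsplit(ugrp, "\r")),
                       stringsAsFactors = FALSE)
    names(meta) <- c("tf_name", "timepoint", "bio_rep")
    meta$timepoint <- as.numeric(meta$timepoint)
    meta$bio_rep <- as.integer(meta$bio_rep)
    act <- which(meta$timepoint > 0)
    if (!length(act)) stop("no MNase-activated (timepoint > 0) samples")
    delta <- vapply(act, function(i) {
        t0 <- which(meta$timepoint == 0 &
                    meta$tf_name == meta$tf_name[i] &
                    meta$bio_rep == meta$bio_rep[i])
        if (length(t0) != 1L)
            stop("no unique paired timepoint-0 condition for ",
                 meta$tf_name[i], " bio rep ", meta$bio_rep[i])
        lg[, i] - lg[, t0]
    }, numeric(nrow(lg)))
    cdOut <- meta[act, , drop = FALSE]
    cdOut$condition_id <- sprintf("%s_t%g_b%d", cdOut$tf_name,
                                  cdOut$timepoint, cdOut$bio_rep)
    colnames(delta) <- cdOut$condition_id
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(delta = delta), rowData = rd,
        colData = DataFrame(cdOut))
    metadata(se)$pseudocount <- pseudocount
    new("DepletionTable", se)
}

#' Convert a depletion contrast to an occupancy fraction
#'
#' Occupancy is defined against the fully mutated reference: a variant
#' depleted by \eqn{\Delta} log2 units relative to the reference carrying
#' no motif has occupancy \eqn{1 - 0.5^{-(\Delta_v - \Delta_{fm})} =
#' 1 - 2^{\Delta_v - \Delta_{fm}}} — the fraction of cells in which the
#' variant was bound (and hence cleaved).  It is 0 when the variant is
#' depleted exactly as much as the reference, approaches 1 under complete
#' depletion, and is negative when the variant is retained better than
#' the reference.
#'
#' @param delta log2 depletion of the variant (activated vs timepoint 0).
#' @param deltaFm log2 depletion of the fully mutated reference in the
#'   same condition.
#' @return occupancy fraction in \eqn{(-\infty, 1]}; vectorized.
#' @examples
#' occupancyFromDepletion(-1, 0)  # 0.5
#' @export
occupancyFromDepletion <- function(delta, deltaFm) {
    1 - 2^(delta - deltaFm)
}

#' Per-variant occupancy fractions
#'
#' For each (TF, timepoint) condition, biological-replicate depletion
#' values are averaged in log space and converted to occupancy relative
#' to the library's fully mutated variant
#' ([occupancyFromDepletion()]).  The SEM is taken across
#' per-biological-replicate occupancies.
#'
#' @param norm a [DepletionTable-class].
#' @param clip clip occupancies into [0, 1]?  Default \code{FALSE}:
#'   negative values (variant retained better than the fully mutated
#'   reference) are reported as-is, since silent clipping would bias the
#'   cooperativity null.
#' @return data.frame with columns \code{library_id}, \code{key},
#'   \code{tf_name}, \code{timepoint}, \code{occupancy}, \code{sem},
#'   \code{n_bio}.
#' @export
occupancies <- function(norm, clip = FALSE) {
    stopifnot(is(norm, "DepletionTable"))
    delta <- SummarizedExperiment::assay(norm, "delta")
    rd <- as.data.frame(SummarizedExperiment::rowData(norm))
    cd <- as.data.frame(SummarizedExperiment::colData(norm))
    out <- list()
    for (cond in unique(paste(cd$tf_name, cd$timepoint, sep = "\r"))) {
        parts <- strsplit(cond, "\r")[[1]]
        cols <- which(cd$tf_name == parts[1] &
                      cd$timepoint == as.numeric(parts[2]))
        d <- delta[, cols, drop = FALSE]
        for (lib in unique(rd$library_id)) {
            rows <- which(rd$library_id == lib)
            fm <- rows[grepl("^0+$|^$", rd$key[rows])]
            dm <- rowMeans(d[rows, , drop = FALSE])
            occ <- occupancyFromDepletion(dm, mean(d[fm, , drop = FALSE]))
            perRep <- vapply(seq_along(cols), function(j)
                occupancyFromDepletion(d[rows, j], d[fm, j]),
                numeric(length(rows)))
            perRep <- matrix(perRep, nrow = length(rows))
            sem <- if (length(cols) > 1L)
                apply(perRep, 1, stats::sd) / sqrt(length(cols))
            else rep(NA_real_, length(rows))
            if (clip) occ <- pmin(pmax(occ, 0), 1)
            out[[length(out) + 1L]] <- data.frame(
                library_id = lib, key = rd$key[rows],
                tf_name = parts[1], timepoint = as.numeric(parts[2]),
                occupancy = occ, sem = sem, n_bio = length(cols),
                stringsAsFactors = FALSE)
        }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Genomic nucleosome-occupancy anchor from MNase-seq
#'
#' Slides a library-sized window (default 164 bp) in 10-bp steps over
#' every promoter, sums the MNase-seq signal in each window, and takes
#' the 99th percentile (linear interpolation) of the window-sum
#' distribution as the value of 100% nucleosome occupancy.  A library
#' region's genomic occupancy is its signal sum divided by this anchor,
#' capped at 1.
#'
#' @param track a [SignalTrack-class] of MNase-seq coverage.
#' @param promoters promoter intervals (GRanges or data.frame with
#'   chrom/start/end, 0-based half-open).
#' @param window window width in bp (default 164).
#' @param step slide step in bp (default 10).
#' @return list with \code{anchor} (the 100%-occupancy window sum),
#'   \code{windowSums} (all window sums) and \code{nSkipped} (promoters
#'   shorter than the window).
#' @seealso [genomicOccupancy()], [histoneOccupancy()]
#' @export
nucleosomeAnchor <- function(track, promoters, window = 164L,
                             step = 10L) {
    stopifnot(is(track, "SignalTrack"))
    prom <- asIntervalFrame(promoters)
    prom <- prom[prom$chrom == track@chrom, , drop = FALSE]
    csum <- c(0, cumsum(track@values))
    t0 <- track@origin; t1 <- t0 + length(track@values)
    sums <- list(); skipped <- 0L
    for (r in seq_len(nrow(prom))) {
        p0 <- max(prom$start[r], t0); p1 <- min(prom$end[r], t1)
        if (p1 - p0 < window) { skipped <- skipped + 1L; next }
        ws <- seq(p0, p1 - window, by = step)
        sums[[length(sums) + 1L]] <-
            csum[ws + window - t0 + 1L] - csum[ws - t0 + 1L]
    }
    if (skipped)
        warning(skipped, " promoter(s) shorter than the ", window,
                " bp window skipped")
    if (!length(sums)) stop("no promoter long enough for the window")
    allSums <- unlist(sums)
    anchor <- unname(stats::quantile(allSums, 0.99, type = 7))
    if (anchor <= 0) stop("the 99th-percentile anchor is not positive")
    list(anchor = anchor, windowSums = allSums, nSkipped = skipped)
}

#' Genomic occupancy of a library source region
#'
#' @param track a [SignalTrack-class].
#' @param start,end 0-based half-open span of the library's source region
#'   on the track's chromosome.
#' @param anchor the 100%-occupancy reference from [nucleosomeAnchor()]
#'   (the list or its \code{anchor} element).
#' @return the region's signal sum divided by the anchor, capped at 1.
#' @export
genomicOccupancy <- function(track, start, end, anchor) {
    stopifnot(is(track, "SignalTrack"))
    if (is.list(anchor)) anchor <- anchor$anchor
    a <- start - track@origin; b <- end - track@origin
    if (a < 0 || b > length(track@values))
        stop("region extends past the track")
    min(sum(track@values[(a + 1L):b]) / anchor, 1)
}

#' Nucleosome occupancy of a library variant on the genomic scale
#'
#' Rescales a variant's histone (H3-MNase) signal onto the genomic
#' nucleosome-occupancy scale: the variant's fold-change relative to the
#' wild-type sequence, times the library region's genomic occupancy.  A
#' variant behaving like wild type therefore scores the region's genomic
#' occupancy itself.  The literal published expression, which places the
#' genomic occupancy in the exponent
#' (\eqn{0.5^{\Delta \cdot occ_{lib}}}), is available with
#' \code{literal = TRUE} for comparison.
#'
#' @param deltaVsWt the variant's log2 value relative to the wild-type
#'   variant (post/t0 normalized); vectorized.
#' @param libraryOccupancy the library region's genomic nucleosome
#'   occupancy from [genomicOccupancy()], in [0, 1].
#' @param literal use the literal exponent form (default \code{FALSE}).
#' @return nucleosome occupancy fraction(s).
#' @examples
#' histoneOccupancy(0, 0.8)   # wild-type-like variant -> 0.8
#' histoneOccupancy(-1, 0.8)  # 2x less retained -> 0.4
#' @export
histoneOccupancy <- function(deltaVsWt, libraryOccupancy,
                             literal = FALSE) {
    if (literal)
        0.5^(deltaVsWt * libraryOccupancy)
    else
        2^deltaVsWt * libraryOccupancy
}
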