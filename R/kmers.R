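#' Strand-collapsed canonical index of DNA k-mers
#'
#' Encodes each k-mer in base 4 (A=0, C=1, G=2, T=3) and assigns it the
#' smaller of its own code and its reverse complement's, so a k-mer and
#' its reverse complement always share one index.  For odd k there are no
#' palindromes, hence exactly \eqn{4^k/2} distinct indices (8192 for
#' k = 7).
#'
#' @param kmer character vector of ACGT k-mers (one common length).
#' @return integer vector of 0-based canonical indices.
#' @examples
#' canonicalKmerIndex("AAAAAAA") == canonicalKmerIndex("TTTTTTT")
#' @export
canonicalKmerIndex <- function(kmer) {
    kmer <- toupper(as.character(kmer))
    k <- unique(nchar(kmer))
    if (length(k) != 1L)
        stop("all k-mers must have the same length")
    chars <- matrix(unlist(strsplit(kmer, ""), use.names = FALSE),
                    nrow = k)
    dig <- match(chars, DNA_BASES4) - 1L
    if (anyNA(dig))
        stop("k-mers must contain only A, C, G, T")
    dim(dig) <- dim(chars)
    w <- 4^((k - 1):0)
    fwd <- as.vector(w %*% dig)
    rc <- as.vector(w %*% (3L - dig[k:1, , drop = FALSE]))
    as.integer(pmin(fwd, rc))
}

#' Representative k-mer of a canonical index
#'
#' Inverse of [canonicalKmerIndex()]: decodes the index back to the
#' lexicographically smaller member of the forward/reverse-complement pair.
#'
#' @param index integer vector of 0-based canonical indices.
#' @param k k-mer length (default 7).
#' @return character vector of k-mers.
#' @export
kmerFromIndex <- function(index, k = 7L) {
    vapply(as.integer(index), function(ix) {
        dig <- integer(k)
        for (i in k:1) { dig[i] <- ix %% 4L; ix <- ix %/% 4L }
        paste(DNA_BASES4[dig + 1L], collapse = "")
    }, character(1))
}

revcompChar <- function(x) {
    as.character(reverseComplement(DNAStringSet(x)))
}

asIntervalFrame <- function(x) {
    if (is(x, "GRanges")) {
        data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                   start = GenomicRanges::start(x) - 1L,   # to 0-based
                   end   = GenomicRanges::end(x),
                   stringsAsFactors = FALSE)
    } else {
        x <- as.data.frame(x)
        stopifnot(all(c("chrom", "start", "end") %in% names(x)))
        if (any(x$start >= x$end) || any(x$start < 0))
            stop("intervals must satisfy 0 <= start < end")
        x
    }
}

#' Relative binding score of every k-mer over promoter signal
#'
#' Scores each k-mer by the genomic binding signal at its occurrences:
#' for every k-mer occurrence fully inside a promoter interval, the track
#' signal is averaged over a window centred on the occurrence midpoint
#' (default 20 bp: midpoint - 10 to midpoint + 9); the per-k-mer score is
#' the mean over all its occurrences, with forward and reverse-complement
#' occurrences collapsed onto one canonical index.  Occurrences whose
#' window extends past the track, or containing non-ACGT bases, are
#' skipped and tallied in the \code{"skipped"} attribute.
#'
#' @param track a [SignalTrack-class] covering the promoters.
#' @param promoters promoter intervals: a \code{GRanges} or a data.frame
#'   with columns chrom, start, end (0-based, half-open).
#' @param genome a named [Biostrings::DNAStringSet] of chromosome
#'   sequences (coordinate 0 = first base), or a single
#'   \code{DNAString}/character for the track's chromosome.
#' @param k k-mer length (default 7).
#' @param window averaging window width in bp (default 20).
#' @return data.frame with columns \code{index} (canonical 0-based
#'   index), \code{kmer} (representative), \code{score}, \code{n}
#'   (occurrences); only indices with >= 1 occurrence appear.
#' @seealso [motifEnrichment()]
#' @export
kmerBindingScores <- function(track, promoters, genome, k = 7L,
                              window = 20L) {
    stopifnot(is(track, "SignalTrack"))
    validObject(track)
    prom <- asIntervalFrame(promoters)
    prom <- prom[prom$chrom == track@chrom, , drop = FALSE]
    if (!nrow(prom))
        stop("no promoter intervals on the track's chromosome")
    if (is(genome, "DNAStringSet")) {
        if (!track@chrom %in% names(genome))
            stop("genome lacks chromosome ", track@chrom)
        chromSeq <- as.character(genome[[track@chrom]])
    } else {
        chromSeq <- as.character(genome)
    }
    halfL <- window %/% 2L                 # bases left of the midpoint
    trkStart <- track@origin
    trkEnd <- track@origin + length(track@values)
    csum <- c(0, cumsum(track@values))
    sums <- counts <- new.env(parent = emptyenv())
    acc <- list()
    skipped <- 0L
    for (r in seq_len(nrow(prom))) {
        p0 <- prom$start[r]; p1 <- prom$end[r]
        if (p1 - p0 < k) next
        starts <- p0:(p1 - k)              # 0-based occurrence starts
        kmers <- substring(chromSeq, starts + 1L, starts + k)
        ok <- !grepl("[^ACGT]", kmers)
        mids <- starts + (k %/% 2L)        # central base, odd k
        ws <- mids - halfL                 # window start (0-based)
        we <- ws + window                  # half-open end
        inside <- ws >= trkStart & we <= trkEnd
        skipped <- skipped + sum(!inside | !ok)
        keep <- ok & inside
        if (!any(keep)) next
        means <- (csum[we[keep] - trkStart + 1L] -
                  csum[ws[keep] - trkStart + 1L]) / window
        idx <- canonicalKmerIndex(kmers[keep])
        acc[[length(acc) + 1L]] <- data.frame(index = idx, val = means)
    }
    if (!length(acc))
        stop("no scorable k-mer occurrence in any promoter")
    occ <- do.call(rbind, acc)
    agg <- stats::aggregate(val ~ index, data = occ,
                            FUN = function(v) c(mean(v), length(v)))
    out <- data.frame(index = agg$index,
                      kmer = kmerFromIndex(agg$index, k),
                      score = agg$val[, 1],
                      n = as.integer(agg$val[, 2]))
    out <- out[order(out$index), ]
    rownames(out) <- NULL
    attr(out, "skipped") <- skipped
    out
}

# "GAATG[CT]" -> "GAATGY": collapse bracketed base sets to IUPAC codes
bracketToIUPAC <- function(pattern) {
    iupac <- c(A = "A", C = "C", G = "G", T = "T",
               AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
               ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")
    while (grepl("\\[", pattern)) {
        grp <- regmatches(pattern, regexpr("\\[[ACGT]+\\]", pattern))
        if (!length(grp)) stop("malformed bracket group in pattern")
        bases <- paste(sort(unique(strsplit(gsub("\\[|\\]", "", grp),
                                            "")[[1]])), collapse = "")
        pattern <- sub("\\[[ACGT]+\\]", iupac[[bases]], pattern)
    }
    pattern
}

#' Motif enrichment over k-mer relative binding scores
#'
#' The mean relative binding score of all canonical k-mer classes whose
#' k-mer (on either strand) contains a match to the motif pattern,
#' divided by the mean score of all classes present.  A value of 1 means
#' the motif draws no more signal than an average k-mer.
#'
#' @param scores output of [kmerBindingScores()].
#' @param pattern motif as an IUPAC-degenerate string; bracket sets such
#'   as \code{"GAATG[CT]"} are accepted.
#' @return list with \code{enrichment}, \code{nMatching} (matching
#'   classes) and \code{pattern} (IUPAC form).
#' @examples
#' sc <- data.frame(index = 0:2, kmer = c("AAAAAAA", "AAAAAAC", "AAAAAAG"),
#'                  score = c(2, 1, 1), n = 1L)
#' motifEnrichment(sc, "AAAAA")
#' @export
motifEnrichment <- function(scores, pattern) {
    stopifnot(is.data.frame(scores),
              all(c("kmer", "score") %in% names(scores)),
              nrow(scores) > 0)
    pat <- bracketToIUPAC(toupper(pattern))
    subj <- DNAStringSet(scores$kmer)
    hits <- Biostrings::vcountPattern(pat, subj, fixed = FALSE) > 0 |
        Biostrings::vcountPattern(pat, reverseComplement(subj),
                                  fixed = FALSE) > 0
    if (!any(hits))
        stop("no k-mer class matches pattern '", pattern, "'")
    list(enrichment = mean(scores$score[hits]) / mean(scores$score),
         nMatching = sum(hits),
         pattern = pat)
}

#' Number of TFs bound at a promoter by z-score
#'
#' Each TF's per-promoter summed signal is z-scored across promoters
#' (population standard deviation); the function counts how many TFs
#' exceed the z threshold at the given promoter.  TFs with zero variance
#' across promoters are excluded with a warning.
#'
#' @param signal numeric matrix, promoters x TFs, of summed binding
#'   signal; dimnames identify promoters and TFs.
#' @param promoter promoter row name or index.
#' @param zThreshold strict lower bound on the z-score (default 3).
#' @return integer count of TFs with z-score > \code{zThreshold}.
#' @export
promoterZscoreTFCount <- function(signal, promoter, zThreshold = 3) {
    signal <- as.matrix(signal)
    mu <- colMeans(signal)
    sdp <- sqrt(colMeans(sweep(signal, 2, mu)^2))
    bad <- sdp == 0
    if (any(bad)) {
        warning(sum(bad), " TF(s) with zero variance excluded: ",
                paste(utils::head(colnames(signal)[bad], 5),
                      collapse = ", "))
        signal <- signal[, !bad, drop = FALSE]
        mu <- mu[!bad]; sdp <- sdp[!bad]
    }
    if (!ncol(signal)) return(0L)
    z <- (signal[promoter, ] - mu) / sdp
    sum(z > zThreshold)
}

#' Read a bedGraph file into a SignalTrack
#'
#' Imports a bedGraph with \pkg{rtracklayer} and densifies it into
#' per-base values over the covered span of one chromosome (gaps filled
#' with 0).
#'
#' @param path bedGraph file path, or a \code{GRanges} with a
#'   \code{score} column.
#' @param chrom chromosome to extract; default: the only chromosome
#'   present (error if several and unspecified).
#' @return a [SignalTrack-class].
#' @export
trackFromBedGraph <- function(path, chrom = NULL) {
    gr <- if (is(path, "GRanges")) path else
        rtracklayer::import(path, format = "bedGraph")
    chroms <- unique(as.character(GenomicRanges::seqnames(gr)))
    if (is.null(chrom)) {
        if (length(chroms) != 1L)
            stop("several chromosomes present; specify 'chrom'")
        chrom <- chroms
    }
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
    if (!length(gr)) stop("no intervals on chromosome ", chrom)
    s0 <- min(GenomicRanges::start(gr)) - 1L      # 0-based origin
    e0 <- max(GenomicRanges::end(gr))
    vals <- numeric(e0 - s0)
    for (i in seq_along(gr)) {
        a <- GenomicRanges::start(gr)[i] - 1L - s0
        b <- GenomicRanges::end(gr)[i] - s0
        vals[(a + 1L):b] <- gr$score[i]
    }
    SignalTrack(chrom, vals, s0)
}

#' Read a BED3/BED4 file into a promoter interval table
#'
#' @param path BED file path.
#' @return data.frame with columns chrom, start, end (0-based, half-open)
#'   and name (when present).
#' @export
readPromoters <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    out <- asIntervalFrame(gr)
    if (!is.null(gr$name)) out$name <- gr$name
    out
}
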