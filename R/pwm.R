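#' Per-column information content of a PWM
#'
#' Information content of column j is \eqn{IC_j = 2 + \sum_b p_{bj}
#' \log_2 p_{bj}} bits, with \eqn{0 \log_2 0 = 0}: 0 bits for a uniform
#' column, 2 bits for a deterministic one.  Used to pick the most
#' constrained ("variable") position of a motif for mutagenesis.
#'
#' @param pwm a [PWM-class].
#' @return numeric vector of per-column information content in [0, 2] bits.
#' @examples
#' pwm <- PWM("x", cbind(c(1, 0, 0, 0), c(.5, .5, 0, 0), rep(.25, 4)))
#' columnInfoContent(pwm)  # 2, 1, 0
#' @export
columnInfoContent <- function(pwm) {
    stopifnot(is(pwm, "PWM"))
    validObject(pwm)
    p <- pwmProbs(pwm)
    plogp <- ifelse(p > 0, p * log2(p), 0)
    2 + colSums(plogp)
}

#' Most informative position of a motif occurrence
#'
#' Returns the absolute region coordinate of the motif column with maximal
#' information content — the position whose single-base mutation is
#' expected to abolish binding.  Ties are broken by proximity to the motif
#' midpoint, then by the leftmost column.
#'
#' @param pwm a [PWM-class].
#' @param spanStart 0-based start of the motif occurrence in region
#'   coordinates (forward strand).
#' @return single integer, the 0-based region coordinate of the chosen
#'   column.
#' @export
centralVariablePosition <- function(pwm, spanStart = 0L) {
    ic <- columnInfoContent(pwm)
    L <- length(ic)
    cand <- which(abs(ic - max(ic)) < 1e-12)
    mid <- (L - 1) / 2                    # 0-based midpoint, may be half-int
    d <- abs((cand - 1L) - mid)
    cand <- cand[d == min(d)]
    as.integer(spanStart) + (min(cand) - 1L)
}

#' Hamming distance between two equal-length DNA strings
#'
#' @param motif,canonical character DNA strings of equal length.
#' @return integer count of mismatching positions.
#' @examples
#' hammingDistance("AGGGT", "AGGGG")  # 1
#' @export
hammingDistance <- function(motif, canonical) {
    motif <- toupper(as.character(motif))
    canonical <- toupper(as.character(canonical))
    if (nchar(motif) != nchar(canonical))
        stop("sequences must have equal length")
    sum(strsplit(motif, "")[[1]] != strsplit(canonical, "")[[1]])
}

#' Euclidean distance between two PWMs
#'
#' The square root of the summed squared differences over all 4 x L
#' probability entries.  PWMs of unequal length are compared by sliding
#' the shorter over the longer and taking the minimum distance over the
#' compared columns (offsets that leave columns of the longer PWM
#' unmatched ignore those columns).
#'
#' @param a,b [PWM-class] objects.
#' @return non-negative numeric distance; 0 iff the aligned matrices are
#'   identical.
#' @export
pwmDistance <- function(a, b) {
    stopifnot(is(a, "PWM"), is(b, "PWM"))
    pa <- pwmProbs(a); pb <- pwmProbs(b)
    if (ncol(pa) == ncol(pb))
        return(sqrt(sum((pa - pb)^2)))
    if (ncol(pa) > ncol(pb)) { tmp <- pa; pa <- pb; pb <- tmp }
    Ls <- ncol(pa); Ll <- ncol(pb)
    d <- vapply(0:(Ll - Ls), function(off) {
        sqrt(sum((pa - pb[, (off + 1):(off + Ls), drop = FALSE])^2))
    }, numeric(1))
    min(d)
}

#' Read a position probability matrix from a file
#'
#' Supports plain tabular text (whitespace-separated, either 4 columns
#' A, C, G, T with one row per position, or 4 rows by L columns) and the
#' MEME minimal motif format (first motif of the file).
#'
#' @param path file path.
#' @param tfName factor name; defaults to the file base name or, for MEME
#'   input, the MOTIF identifier.
#' @return a [PWM-class].
#' @export
readPWM <- function(path, tfName = NULL) {
    lines <- readLines(path, warn = FALSE)
    if (any(grepl("^MEME version", lines))) {
        i <- grep("^MOTIF", lines)[1]
        if (is.na(i)) stop("no MOTIF block in MEME file")
        if (is.null(tfName))
            tfName <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
        j <- grep("letter-probability matrix", lines)
        j <- j[j > i][1]
        rows <- list()
        k <- j + 1
        while (k <= length(lines) && grepl("^\\s*[0-9.eE+-]", lines[k])) {
            rows[[length(rows) + 1]] <-
                as.numeric(strsplit(trimws(lines[k]), "\\s+")[[1]])
            k <- k + 1
        }
        mat <- t(do.call(rbind, rows))     # MEME rows are positions
    } else {
        lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
        header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
        hasHeader <- all(toupper(header) %in% c(DNA_BASES4, "POS", "PO"))
        body <- if (hasHeader) lines[-1] else lines
        mat <- do.call(rbind, lapply(body, function(l)
            as.numeric(grep("^[0-9.eE+-]+$",
                            strsplit(trimws(l), "\\s+")[[1]], value = TRUE))))
        if (ncol(mat) == 4L) mat <- t(mat) # positions-as-rows layout
        rownames(mat) <- DNA_BASES4
    }
    if (is.null(tfName))
        tfName <- sub("\\.[^.]*$", "", basename(path))
    # renormalise away count-matrix rounding
    mat <- sweep(mat, 2, colSums(mat), "/")
    PWM(tfName, mat)
}
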