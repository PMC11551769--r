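#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#' @importClassesFrom Biostrings DNAString DNAStringSet
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

#' Position probability matrix of a transcription-factor binding motif
#'
#' A \code{PWM} holds the in-vitro base preferences of a transcription
#' factor as a 4 x L matrix of probabilities (rows A, C, G, T; one column
#' per motif position, each column summing to 1).  It is the input for
#' information-content based selection of the variable position within a
#' motif and for motif-to-motif Euclidean distances.
#'
#' @slot tfName single character, the transcription factor name.
#' @slot probs numeric matrix, 4 rows (A, C, G, T) by L >= 1 columns; each
#'   column sums to one.
#'
#' @seealso [PWM()], [columnInfoContent()], [pwmDistance()]
#' @exportClass PWM
setClass("PWM", representation(tfName = "character", probs = "matrix"))

setValidity("PWM", function(object) {
    p <- object@probs
    if (length(object@tfName) != 1L || is.na(object@tfName))
        return("'tfName' must be a single non-NA string")
    if (!is.numeric(p) || nrow(p) != 4L || ncol(p) < 1L)
        return("'probs' must be a numeric 4 x L matrix with L >= 1")
    if (anyNA(p) || any(p < 0) || any(p > 1))
        return("all probabilities must lie in [0, 1]")
    cs <- colSums(p)
    if (any(abs(cs - 1) > 1e-9))
        return(sprintf("column(s) %s do not sum to 1",
                       paste(which(abs(cs - 1) > 1e-9), collapse = ", ")))
    TRUE
})

#' Construct a PWM
#'
#' @param tfName transcription factor name.
#' @param probs 4 x L matrix of base probabilities; rows are taken to be in
#'   A, C, G, T order (rownames, if present, are used to reorder).
#' @return a [PWM-class] object.
#' @examples
#' pwm <- PWM("Msn2", matrix(c(.7, .1, .1, .1, .25, .25, .25, .25), 4))
#' columnInfoContent(pwm)
#' @export
PWM <- function(tfName, probs) {
    probs <- as.matrix(probs)
    if (!is.null(rownames(probs))) {
        rn <- toupper(rownames(probs))
        if (setequal(rn, DNA_BASES4))
            probs <- probs[match(DNA_BASES4, rn), , drop = FALSE]
    }
    rownames(probs) <- DNA_BASES4
    new("PWM", tfName = as.character(tfName), probs = probs)
}

setMethod("show", "PWM", function(object) {
    cat(sprintf("PWM for %s, %d positions\n", object@tfName,
                ncol(object@probs)))
    print(round(object@probs, 3))
})

#' @describeIn PWM motif length (number of columns).
#' @param x,object a \code{PWM}.
#' @export
setMethod("length", "PWM", function(x) ncol(x@probs))

#' Accessors for PWM slots
#'
#' @param x a [PWM-class].
#' @return \code{pwmProbs} returns the 4 x L probability matrix;
#'   \code{tfName} the factor name.
#' @export
pwmProbs <- function(x) x@probs

#' @rdname pwmProbs
#' @export
tfName <- function(x) x@tfName

#' A combinatorial motif-mutation library for one regulatory region
#'
#' A \code{MotifLibrary} couples a regulatory-region sequence (nominally
#' 164 bp) with its annotated transcription-factor motif sites and the full
#' set of \eqn{2^n} variant sequences obtained by leaving each of the n
#' motifs intact or carrying a single-base mutation at its variable
#' position.  Variants are keyed by an n-character 0/1 string in 5'-to-3'
#' site order: bit i = 1 means site i intact, 0 mutated.  The all-ones key
#' is the wild type; the all-zeros key is the fully mutated reference
#' lacking every motif.
#'
#' @slot regionId single character identifier of the source region.
#' @slot sequence [Biostrings::DNAString] of the region.
#' @slot sites a [S4Vectors::DataFrame] of motif sites with columns
#'   \code{tf_name}, \code{start}, \code{end} (0-based, half-open),
#'   \code{strand}, \code{variable_position} (0-based), \code{wt_base},
#'   \code{mut_base}, \code{canonical_for}.
#' @slot variants named [Biostrings::DNAStringSet], one entry per key.
#'
#' @seealso [makeLibrary()], [annotateSites()], [variantKeys()]
#' @exportClass MotifLibrary
setClass("MotifLibrary", representation(
    regionId = "character",
    sequence = "DNAString",
    sites    = "DataFrame",
    variants = "DNAStringSet"))

setValidity("MotifLibrary", function(object) {
    n <- nrow(object@sites)
    msg <- validateSites(as.character(object@sequence),
                         as.data.frame(object@sites))
    if (!isTRUE(msg)) return(msg)
    if (length(object@variants) != 2L^n)
        return(sprintf("expected %d variants for %d sites, got %d",
                       2L^n, n, length(object@variants)))
    if (anyDuplicated(names(object@variants)))
        return("duplicated variant keys")
    wid <- unique(Biostrings::width(object@variants))
    if (length(wid) > 1L || wid != length(object@sequence))
        return("all variants must have the region's length")
    wt <- paste(rep("1", n), collapse = "")
    if (n > 0L &&
        as.character(object@variants[[wt]]) != as.character(object@sequence))
        return("the all-intact variant must equal the region sequence")
    TRUE
})

setMethod("show", "MotifLibrary", function(object) {
    cat(sprintf("MotifLibrary '%s': %d bp, %d motif sites, %d variants\n",
                object@regionId, length(object@sequence),
                nrow(object@sites), length(object@variants)))
    if (nrow(object@sites))
        print(as.data.frame(object@sites))
})

#' Accessors for MotifLibrary slots
#'
#' @param x a [MotifLibrary-class].
#' @return \code{regionId}: the region identifier; \code{regionSeq}: the
#'   region [Biostrings::DNAString]; \code{motifSites}: the site table;
#'   \code{libraryVariants}: the named [Biostrings::DNAStringSet] of all
#'   variant sequences; \code{nSites}: the number of motif sites.
#' @export
regionId <- function(x) x@regionId

#' @rdname regionId
#' @export
regionSeq <- function(x) x@sequence

#' @rdname regionId
#' @export
motifSites <- function(x) x@sites

#' @rdname regionId
#' @export
libraryVariants <- function(x) x@variants

#' @rdname regionId
#' @export
nSites <- function(x) nrow(x@sites)

#' Per-base signal over a contiguous genomic interval
#'
#' A thin container for a dense, per-base, non-negative signal (e.g.
#' ChEC-seq or MNase-seq coverage) over one contiguous stretch of one
#' chromosome.  Coordinates are 0-based, half-open: base i of
#' \code{values} covers genomic position \code{origin + i - 1} (0-based).
#'
#' @slot chrom chromosome name.
#' @slot origin 0-based start coordinate of the first value.
#' @slot values numeric vector of per-base signal, all >= 0.
#'
#' @seealso [SignalTrack()], [trackFromBedGraph()], [kmerBindingScores()]
#' @exportClass SignalTrack
setClass("SignalTrack", representation(
    chrom = "character", origin = "integer", values = "numeric"))

setValidity("SignalTrack", function(object) {
    if (length(object@chrom) != 1L) return("'chrom' must be length 1")
    if (length(object@origin) != 1L || object@origin < 0L)
        return("'origin' must be a single non-negative integer")
    if (length(object@values) < 1L) return("empty signal")
    if (anyNA(object@values) || any(object@values < 0))
        return("signal values must be non-negative and non-missing")
    TRUE
})

#' Construct a SignalTrack
#'
#' @param chrom chromosome name.
#' @param values numeric per-base signal.
#' @param origin 0-based coordinate of the first base (default 0).
#' @return a [SignalTrack-class].
#' @export
SignalTrack <- function(chrom, values, origin = 0L) {
    new("SignalTrack", chrom = as.character(chrom),
        origin = as.integer(origin), values = as.numeric(values))
}

setMethod("show", "SignalTrack", function(object) {
    cat(sprintf("SignalTrack %s:[%d, %d) (%d bp), mean signal %.3g\n",
                object@chrom, object@origin,
                object@origin + length(object@values),
                length(object@values), mean(object@values)))
})

#' @describeIn SignalTrack number of covered bases.
#' @param x,object a \code{SignalTrack}.
#' @export
setMethod("length", "SignalTrack", function(x) length(x@values))

#' Ground-truth generative model of TF binding to a variant library
#'
#' A \code{BindingModel} parameterizes the simulator: each intact motif
#' site i is bound in a fraction \eqn{p_i} of cells; the fraction of cells
#' in which a variant region is bound by the TF is the independence
#' (inclusion-exclusion) combination of its intact sites plus additive
#' pairwise deviations \eqn{c_{ij}}; a bound plasmid is cleaved by
#' activation time t with efficiency \eqn{e_t}.
#'
#' @slot p numeric vector, per-site binding probability in [0, 1].
#' @slot interaction symmetric n x n matrix of additive pairwise
#'   cooperativity terms (0 = independent binding).
#' @slot efficiency named numeric vector of cleavage efficiencies in
#'   [0, 1]; names are activation timepoints in seconds.
#'
#' @seealso [BindingModel()], [variantBoundFraction()], [simulateCounts()]
#' @exportClass BindingModel
setClass("BindingModel", representation(
    p = "numeric", interaction = "matrix", efficiency = "numeric"))

setValidity("BindingModel", function(object) {
    n <- length(object@p)
    if (n < 1L) return("at least one site probability required")
    if (anyNA(object@p) || any(object@p < 0) || any(object@p > 1))
        return("site probabilities must lie in [0, 1]")
    if (!all(dim(object@interaction) == c(n, n)))
        return("'interaction' must be an n x n matrix")
    if (any(abs(object@interaction - t(object@interaction)) > 1e-12))
        return("'interaction' must be symmetric")
    if (any(diag(object@interaction) != 0))
        return("'interaction' diagonal must be zero")
    e <- object@efficiency
    if (length(e) < 1L || is.null(names(e)) || any(names(e) == ""))
        return("'efficiency' must be named by activation timepoint")
    if (anyNA(e) || any(e < 0) || any(e > 1))
        return("cleavage efficiencies must lie in [0, 1]")
    TRUE
})

#' Construct a BindingModel
#'
#' @param p per-site binding probabilities (fraction of cells bound at each
#'   intact site).
#' @param interaction optional n x n symmetric matrix of additive pairwise
#'   cooperativity terms; default all zero (independent binding).
#' @param efficiency named numeric vector of per-timepoint cleavage
#'   efficiencies; default \code{c("60" = 0.5, "180" = 0.8)}, increasing
#'   with MNase activation time.
#' @return a [BindingModel-class].
#' @examples
#' m <- BindingModel(p = c(0.5, 0.5), efficiency = c("180" = 1))
#' variantBoundFraction(m, "11")
#' @export
BindingModel <- function(p, interaction = NULL,
                         efficiency = c("60" = 0.5, "180" = 0.8)) {
    n <- length(p)
    if (is.null(interaction))
        interaction <- matrix(0, n, n)
    new("BindingModel", p = as.numeric(p),
        interaction = as.matrix(interaction),
        efficiency = efficiency)
}

setMethod("show", "BindingModel", function(object) {
    cat(sprintf("BindingModel: %d sites, p = [%s]\n", length(object@p),
                paste(format(object@p, digits = 3), collapse = ", ")))
    nz <- which(object@interaction != 0 & upper.tri(object@interaction),
                arr.ind = TRUE)
    if (nrow(nz))
        cat(sprintf("  %d pairwise interaction term(s)\n", nrow(nz)))
    cat(sprintf("  cleavage efficiency: %s\n",
                paste(sprintf("t=%ss: %.2f", names(object@efficiency),
                              object@efficiency), collapse = ", ")))
})
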