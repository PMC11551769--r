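PURINES <- c("A", "G")

# TRUE/message validator shared with the MotifLibrary validity method
validateSites <- function(region, sites) {
    need <- c("tf_name", "start", "end", "variable_position",
              "wt_base", "mut_base")
    if (nrow(sites) == 0L) return(TRUE)
    if (!all(need %in% names(sites)))
        return(paste("site table lacks column(s):",
                     paste(setdiff(need, names(sites)), collapse = ", ")))
    L <- nchar(region)
    if (any(sites$start < 0) || any(sites$end > L) ||
        any(sites$start >= sites$end))
        return("motif spans must satisfy 0 <= start < end <= region length")
    vp <- sites$variable_position
    if (any(vp < sites$start) || any(vp >= sites$end))
        return("variable positions must lie inside their motif spans")
    if (anyDuplicated(vp))
        return("two sites share a variable position")
    regBase <- substring(region, vp + 1L, vp + 1L)
    if (any(sites$wt_base != regBase))
        return(sprintf(
            "wt_base disagrees with the region sequence at site(s) %s",
            paste(which(sites$wt_base != regBase), collapse = ", ")))
    if (any(!sites$mut_base %in% DNA_BASES4) ||
        any(!sites$wt_base %in% DNA_BASES4))
        return("wt_base and mut_base must be single A/C/G/T characters")
    if (any(sites$mut_base == sites$wt_base))
        return("mut_base must differ from wt_base")
    TRUE
}

# reverse-complement a PWM so a minus-strand motif reads on the forward strand
pwmRevComp <- function(pwm) {
    p <- pwmProbs(pwm)[4:1, ncol(pwmProbs(pwm)):1, drop = FALSE]
    rownames(p) <- DNA_BASES4
    PWM(tfName(pwm), p)
}

# default mutant base: minimal PWM probability at the variable column;
# ties prefer a transversion from wt, then alphabetical order
chooseMutBase <- function(colProbs, wtBase) {
    names(colProbs) <- DNA_BASES4
    cand <- setdiff(DNA_BASES4, wtBase)
    pr <- colProbs[cand]
    cand <- cand[abs(pr - min(pr)) < 1e-12]
    if (length(cand) > 1L) {
        tv <- xor(wtBase %in% PURINES, cand %in% PURINES)
        if (any(tv)) cand <- cand[tv]
    }
    sort(cand)[1]
}

#' Annotate motif sites on a regulatory region
#'
#' Turns motif hits into fully specified mutable sites.  Each hit either
#' states its variable position and mutant base explicitly (passed through
#' unchanged) or names a PWM, in which case the variable position is the
#' motif column with the highest information content
#' ([centralVariablePosition()]) and the mutant base is the base with the
#' lowest PWM probability there (ties: transversion from the wild-type
#' base preferred, then alphabetical).
#'
#' @param region region sequence (character or [Biostrings::DNAString]).
#' @param hits data.frame with columns \code{tf_name}, \code{start},
#'   \code{end} (0-based, half-open, forward-strand coordinates) and
#'   optionally \code{strand} ("+"/"-", default "+"),
#'   \code{variable_position} (0-based; NA to derive from a PWM),
#'   \code{mut_base} (NA to derive), \code{canonical_for}.
#' @param pwms named list of [PWM-class] objects (by \code{tf_name}) for
#'   hits whose variable position or mutant base must be derived.  A
#'   minus-strand hit's PWM is reverse-complemented internally.
#' @return a [S4Vectors::DataFrame] of sites ordered by variable
#'   position, suitable for [makeLibrary()].
#' @export
annotateSites <- function(region, hits, pwms = list()) {
    region <- toupper(as.character(region))
    hits <- as.data.frame(hits)
    if (is.null(hits$strand)) hits$strand <- "+"
    if (is.null(hits$variable_position)) hits$variable_position <- NA_integer_
    if (is.null(hits$mut_base)) hits$mut_base <- NA_character_
    if (is.null(hits$canonical_for)) hits$canonical_for <- NA_character_
    out <- lapply(seq_len(nrow(hits)), function(i) {
        h <- hits[i, ]
        span <- c(h$start, h$end)
        needPWM <- is.na(h$variable_position) || is.na(h$mut_base)
        pwm <- NULL
        if (needPWM) {
            pwm <- pwms[[h$tf_name]]
            if (is.null(pwm))
                stop("hit ", i, " (", h$tf_name, ") needs a PWM to derive ",
                     "its variable position or mutant base")
            if (h$strand == "-") pwm <- pwmRevComp(pwm)
            if (length(pwm) != h$end - h$start)
                stop("PWM length (", length(pwm),
                     ") does not match span length (", h$end - h$start,
                     ") for hit ", i)
        }
        vp <- h$variable_position
        if (is.na(vp)) vp <- centralVariablePosition(pwm, h$start)
        wt <- substring(region, vp + 1L, vp + 1L)
        mb <- h$mut_base
        if (is.na(mb))
            mb <- chooseMutBase(pwmProbs(pwm)[, vp - h$start + 1L], wt)
        data.frame(tf_name = h$tf_name, start = h$start, end = h$end,
                   strand = h$strand, variable_position = as.integer(vp),
                   wt_base = wt, mut_base = mb,
                   canonical_for = h$canonical_for,
                   stringsAsFactors = FALSE)
    })
    sites <- do.call(rbind, out)
    sites <- sites[order(sites$variable_position), , drop = FALSE]
    rownames(sites) <- NULL
    msg <- validateSites(region, sites)
    if (!isTRUE(msg)) stop(msg)
    DataFrame(sites)
}

#' All intact/mutated keys for n motif sites
#'
#' Keys are n-character 0/1 strings in 5'-to-3' site order (character i
#' refers to site i; 1 = intact, 0 = mutated), enumerated from the
#' all-ones wild type down to the all-zeros fully mutated reference.
#'
#' @param n number of motif sites (0 gives the single empty key).
#' @return character vector of \eqn{2^n} keys.
#' @examples
#' variantKeys(2)  # "11" "10" "01" "00"
#' @export
variantKeys <- function(n) {
    n <- as.integer(n)
    stopifnot(n >= 0L, n <= 30L)
    if (n == 0L) return("")
    vapply((2L^n - 1L):0L, function(v)
        paste(as.integer(bitwAnd(bitwShiftR(v, (n - 1L):0L), 1L)),
              collapse = ""), character(1))
}

keyBits <- function(key) {
    as.integer(strsplit(key, "")[[1]])
}

applyKey <- function(region, sites, key) {
    bits <- keyBits(key)
    s <- strsplit(region, "")[[1]]
    mut <- which(bits == 0L)
    s[sites$variable_position[mut] + 1L] <- sites$mut_base[mut]
    paste(s, collapse = "")
}

#' Enumerate the full combinatorial variant library
#'
#' Builds all \eqn{2^n} variant sequences of a region with n annotated
#' motif sites: variant \code{key} carries each site's mutant base
#' exactly where its key bit is 0 and is otherwise identical to the
#' region.  Regions are nominally 164 bp; other lengths are accepted with
#' a warning.
#'
#' @param region region sequence (character or [Biostrings::DNAString]).
#' @param sites site table from [annotateSites()] (or a data.frame with
#'   the same columns).
#' @param regionId identifier recorded in the library (default
#'   \code{"region"}).
#' @return a [MotifLibrary-class].
#' @examples
#' sites <- data.frame(tf_name = c("a", "b"), start = c(0L, 2L),
#'                     end = c(2L, 4L), strand = "+",
#'                     variable_position = c(1L, 3L),
#'                     wt_base = "A", mut_base = c("C", "G"),
#'                     canonical_for = NA_character_)
#' lib <- makeLibrary("AAAA", sites, "toy")
#' as.character(libraryVariants(lib))
#' @export
makeLibrary <- function(region, sites, regionId = "region") {
    region <- toupper(as.character(region))
    sites <- as.data.frame(sites)
    if (nrow(sites))
        sites <- sites[order(sites$variable_position), , drop = FALSE]
    rownames(sites) <- NULL
    msg <- validateSites(region, sites)
    if (!isTRUE(msg)) stop(msg)
    if (nchar(region) != 164L)
        warning("region is ", nchar(region), " bp, not the nominal 164 bp")
    keys <- variantKeys(nrow(sites))
    seqs <- vapply(keys, function(k) applyKey(region, sites, k),
                   character(1))
    if (anyDuplicated(seqs))
        stop("duplicate variant sequences; sites are not independent")
    variants <- DNAStringSet(seqs)
    names(variants) <- keys
    new("MotifLibrary", regionId = as.character(regionId),
        sequence = DNAString(region), sites = DataFrame(sites),
        variants = variants)
}

#' Write a library to disk (FASTA + site manifest)
#'
#' Emits \code{<regionId>.variants.fa} (every variant, headers
#' \code{regionId|key} with the key in site order),
#' \code{<regionId>.region.fa} and a TSV site manifest
#' \code{<regionId>.sites.tsv}.  [readLibrary()] reverses the operation.
#'
#' @param design a [MotifLibrary-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeLibrary <- function(design, dir) {
    stopifnot(is(design, "MotifLibrary"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    id <- regionId(design)
    fa <- file.path(dir, paste0(id, ".variants.fa"))
    rg <- file.path(dir, paste0(id, ".region.fa"))
    tsv <- file.path(dir, paste0(id, ".sites.tsv"))
    v <- libraryVariants(design)
    names(v) <- paste0(id, "|", names(v))
    Biostrings::writeXStringSet(v, fa)
    reg <- DNAStringSet(as.character(regionSeq(design)))
    names(reg) <- id
    Biostrings::writeXStringSet(reg, rg)
    utils::write.table(as.data.frame(motifSites(design)), tsv,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(variants = fa, region = rg, sites = tsv))
}

#' Read a library written by [writeLibrary()]
#'
#' @param dir directory holding the three files.
#' @param regionId library identifier (file prefix); default: the unique
#'   prefix found in \code{dir}.
#' @return a [MotifLibrary-class]; an error is raised if the FASTA
#'   variants disagree with re-enumeration from the region and manifest.
#' @export
readLibrary <- function(dir, regionId = NULL) {
    if (is.null(regionId)) {
        ids <- unique(sub("\\.region\\.fa$", "",
                          basename(Sys.glob(file.path(dir, "*.region.fa")))))
        if (length(ids) != 1L)
            stop("specify 'regionId'; found: ", paste(ids, collapse = ", "))
        regionId <- ids
    }
    reg <- Biostrings::readDNAStringSet(
        file.path(dir, paste0(regionId, ".region.fa")))
    sites <- utils::read.table(
        file.path(dir, paste0(regionId, ".sites.tsv")),
        sep = "\t", header = TRUE, stringsAsFactors = FALSE,
        colClasses = c(canonical_for = "character"))
    sites$canonical_for[sites$canonical_for == "NA"] <- NA_character_
    design <- makeLibrary(as.character(reg[[1]]), sites, regionId)
    fa <- Biostrings::readDNAStringSet(
        file.path(dir, paste0(regionId, ".variants.fa")))
    keys <- sub("^.*\\|", "", names(fa))
    if (!setequal(keys, names(libraryVariants(design))) ||
        !all(as.character(fa[order(match(keys,
                names(libraryVariants(design))))]) ==
             as.character(libraryVariants(design))))
        stop("variant FASTA disagrees with the region + manifest")
    design
}
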