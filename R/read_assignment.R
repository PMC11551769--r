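#' Variant read counts across samples
#'
#' A \code{VariantCounts} is a [SummarizedExperiment::SummarizedExperiment]
#' holding one \code{counts} assay of non-negative integer read counts:
#' rows are library variants (rowData columns \code{library_id},
#' \code{key}; every library's full \eqn{2^n} key set is present,
#' zero-filled), columns are sequencing samples (colData columns
#' \code{sample_id}, \code{tf_name}, \code{timepoint} in seconds with 0 =
#' pre-activation, \code{bio_rep}, \code{tech_rep}).  Per-sample counts
#' of the poorly bound control sequence and read-assignment tallies live
#' in \code{metadata(x)$control_counts} and \code{metadata(x)$tallies}.
#'
#' @seealso [VariantCounts()], [countReads()], [simulateCounts()],
#'   [normalizeCounts()]
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass VariantCounts
setClass("VariantCounts", contains = "SummarizedExperiment")

setValidity("VariantCounts", function(object) {
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("a 'counts' assay is required")
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt)))
        return("counts must be non-negative integers")
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("library_id", "key") %in% names(rd)))
        return("rowData must have 'library_id' and 'key'")
    cd <- SummarizedExperiment::colData(object)
    need <- c("sample_id", "tf_name", "timepoint", "bio_rep", "tech_rep")
    if (!all(need %in% names(cd)))
        return(paste("colData lacks:", paste(setdiff(need, names(cd)),
                                             collapse = ", ")))
    if (any(cd$timepoint < 0)) return("timepoints must be >= 0")
    for (lib in unique(rd$library_id)) {
        keys <- rd$key[rd$library_id == lib]
        n <- unique(nchar(keys))
        if (length(n) != 1L || length(keys) != 2L^n ||
            anyDuplicated(keys))
            return(sprintf("library '%s' must carry its full 2^n key set",
                           lib))
    }
    TRUE
})

#' Construct a VariantCounts object
#'
#' @param counts integer matrix, variants x samples.
#' @param rowData data.frame with \code{library_id} and \code{key} per row
#'   of \code{counts}.
#' @param colData data.frame of sample metadata (\code{sample_id},
#'   \code{tf_name}, \code{timepoint}, \code{bio_rep}, \code{tech_rep}).
#' @param controlCounts per-sample counts of the poorly bound control
#'   sequence (default 0).
#' @param tallies optional per-sample read-assignment tallies.
#' @return a [VariantCounts-class].
#' @export
VariantCounts <- function(counts, rowData, colData,
                          controlCounts = NULL, tallies = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (is.null(controlCounts))
        controlCounts <- stats::setNames(rep(0L, ncol(counts)),
                                         colData$sample_id)
    colnames(counts) <- colData$sample_id
    rownames(counts) <- paste(rowData$library_id, rowData$key, sep = "|")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(rowData), colData = DataFrame(colData))
    metadata(se)$control_counts <- controlCounts
    metadata(se)$tallies <- tallies
    new("VariantCounts", se)
}

#' @rdname VariantCounts
#' @param x a \code{VariantCounts}.
#' @return \code{controlCounts}: named per-sample control-sequence read
#'   counts; \code{assignmentTallies}: the per-sample assignment-category
#'   tallies (or NULL).
#' @export
controlCounts <- function(x) metadata(x)$control_counts

#' @rdname VariantCounts
#' @export
assignmentTallies <- function(x) metadata(x)$tallies

# per-design matching of a block of reads; internal work-horse of
# assignRead()/countReads().  Returns, per read: key (NA if not
# assignable), anchorOK flag.
.matchDesign <- function(reads, design, maxMismatch, anchor) {
    region <- as.character(regionSeq(design))
    L <- nchar(region)
    sites <- as.data.frame(motifSites(design))
    vp <- sites$variable_position              # 0-based
    n <- length(reads)
    key <- rep(NA_character_, n)
    anchorOK <- rep(FALSE, n)
    lenOK <- nchar(reads) == L
    if (!any(lenOK))
        return(list(key = key, anchorOK = anchorOK))
    idx <- which(lenOK)
    m <- matrix(unlist(strsplit(reads[idx], ""), use.names = FALSE),
                nrow = L)
    regChars <- strsplit(region, "")[[1]]
    mmAll <- colSums(m != regChars)
    # 3' terminal anchor: last `anchor` non-variable bases must be exact
    anchorRows <- setdiff((L - anchor + 1L):L, vp + 1L)
    aok <- colSums(m[anchorRows, , drop = FALSE] !=
                   regChars[anchorRows]) == 0L
    anchorOK[idx] <- aok
    if (length(vp)) {
        vb <- m[vp + 1L, , drop = FALSE]       # variable-position bases
        bits <- matrix(NA_integer_, nrow(vb), ncol(vb))
        bits[vb == sites$wt_base] <- 1L
        bits[vb == sites$mut_base] <- 0L
        bitsOK <- colSums(is.na(bits)) == 0L
        varMM <- colSums(vb != sites$wt_base)
    } else {
        bits <- matrix(integer(0), 0, length(idx))
        bitsOK <- rep(TRUE, length(idx))
        varMM <- rep(0L, length(idx))
    }
    scaffMM <- mmAll - varMM                   # mismatches off the
    hit <- aok & bitsOK & scaffMM <= maxMismatch # variable positions
    if (any(hit)) {
        kk <- apply(bits[, hit, drop = FALSE], 2, paste, collapse = "")
        if (!length(vp)) kk <- rep("", sum(hit))
        key[idx[hit]] <- kk
    }
    list(key = key, anchorOK = anchorOK)
}

#' Assign one read to a library variant
#'
#' A read is assigned to a library variant when (i) it has the region's
#' length and its last \code{anchor} bases match the region's 3' end at
#' the expected offset (the indel filter: any 1-bp insertion or deletion
#' shifts the 3' anchor), (ii) every variable-position base equals that
#' site's wild-type or mutant base (together defining the variant key),
#' and (iii) the remaining scaffold carries at most \code{maxMismatch}
#' mismatches.  Reads matching the scaffold but carrying a
#' variable-position base that is neither wild type nor mutant are
#' \code{unassigned} (combinations absent from the library); reads
#' failing the 3' anchor against every design are \code{filtered_indel};
#' reads matching the control sequence are \code{control}.
#'
#' @param read a single read (character, 5'-to-3' forward amplicon after
#'   primer removal).
#' @param designs a [MotifLibrary-class] or list of them.
#' @param control optional control sequence (character).
#' @param maxMismatch scaffold mismatch budget (default 2).
#' @param anchor 3' anchor length in bases (default 6).
#' @return list with \code{category} (one of \code{assigned},
#'   \code{control}, \code{unassigned}, \code{filtered_indel}) and, when
#'   assigned, \code{library_id} and \code{key}.
#' @export
assignRead <- function(read, designs, control = NULL, maxMismatch = 2L,
                       anchor = 6L) {
    res <- countReads(read, designs, control, maxMismatch, anchor)
    tal <- res$tallies
    cat <- names(tal)[which(tal == 1L)][1]
    out <- list(category = cat, library_id = NA_character_,
                key = NA_character_)
    if (cat == "assigned") {
        hit <- res$counts[res$counts$count > 0L, ]
        out$library_id <- hit$library_id
        out$key <- hit$key
    }
    out
}

#' Count a stream of reads against variant libraries
#'
#' Applies the [assignRead()] matching rules to every read and returns
#' the per-variant count table for one sample, the control-sequence
#' count, and the assignment-category tallies.  The four categories
#' partition the input: assigned + control + unassigned + filtered_indel
#' = total reads.
#'
#' @param reads character vector of reads, or a
#'   [Biostrings::DNAStringSet], or a FASTA/FASTQ path.
#' @inheritParams assignRead
#' @return list with \code{counts} (data.frame \code{library_id},
#'   \code{key}, \code{count} over every key of every design),
#'   \code{control} (integer) and \code{tallies} (named integer vector).
#' @export
countReads <- function(reads, designs, control = NULL, maxMismatch = 2L,
                       anchor = 6L) {
    if (is(designs, "MotifLibrary")) designs <- list(designs)
    stopifnot(length(designs) > 0,
              all(vapply(designs, is, logical(1), "MotifLibrary")))
    if (is.character(reads) && length(reads) == 1L && file.exists(reads))
        reads <- Biostrings::readDNAStringSet(
            reads, format = if (grepl("f(ast)?q($|\\.gz$)", reads))
                "fastq" else "fasta")
    reads <- toupper(as.character(reads))
    if (any(!nzchar(reads))) stop("empty read in input")
    n <- length(reads)
    libIds <- vapply(designs, regionId, character(1))
    if (anyDuplicated(libIds)) stop("duplicated library ids in 'designs'")
    assignedLib <- rep(NA_character_, n)
    assignedKey <- rep(NA_character_, n)
    nAssign <- integer(n)
    anyAnchor <- rep(FALSE, n)
    for (d in seq_along(designs)) {
        md <- .matchDesign(reads, designs[[d]], maxMismatch, anchor)
        hit <- !is.na(md$key)
        nAssign <- nAssign + hit
        assignedLib[hit] <- libIds[d]
        assignedKey[hit] <- md$key[hit]
        anyAnchor <- anyAnchor | md$anchorOK
    }
    ambiguous <- nAssign > 1L
    if (any(ambiguous))
        warning(sum(ambiguous), " read(s) matched several library ",
                "scaffolds; counted as unassigned")
    isAssigned <- nAssign == 1L
    isControl <- rep(FALSE, n)
    if (!is.null(control)) {
        control <- toupper(as.character(control))
        cand <- !isAssigned & nchar(reads) == nchar(control)
        if (any(cand)) {
            cc <- strsplit(control, "")[[1]]
            mm <- colSums(matrix(unlist(strsplit(reads[cand], ""),
                                        use.names = FALSE),
                                 nrow = nchar(control)) != cc)
            isControl[cand] <- mm <= maxMismatch
        }
    }
    isIndel <- !isAssigned & !isControl & !anyAnchor
    isUnassigned <- !isAssigned & !isControl & !isIndel
    keyTab <- do.call(rbind, lapply(designs, function(d)
        data.frame(library_id = regionId(d),
                   key = names(libraryVariants(d)),
                   stringsAsFactors = FALSE)))
    id <- paste(assignedLib[isAssigned], assignedKey[isAssigned],
                sep = "|")
    cnt <- table(factor(id, levels = paste(keyTab$library_id, keyTab$key,
                                           sep = "|")))
    keyTab$count <- as.integer(cnt)
    list(counts = keyTab,
         control = sum(isControl),
         tallies = c(assigned = sum(isAssigned),
                     control = sum(isControl),
                     unassigned = sum(isUnassigned),
                     filtered_indel = sum(isIndel)))
}

#' Assemble per-sample count results into a VariantCounts object
#'
#' @param sampleCounts named list (by sample_id) of [countReads()]
#'   results.
#' @param sampleMeta data.frame of sample metadata with a row per entry
#'   of \code{sampleCounts} (columns \code{sample_id}, \code{tf_name},
#'   \code{timepoint}, \code{bio_rep}, \code{tech_rep}).
#' @return a [VariantCounts-class].
#' @export
bindSampleCounts <- function(sampleCounts, sampleMeta) {
    sampleMeta <- as.data.frame(sampleMeta)
    stopifnot(setequal(names(sampleCounts), sampleMeta$sample_id))
    sampleCounts <- sampleCounts[sampleMeta$sample_id]
    keyTab <- sampleCounts[[1]]$counts[, c("library_id", "key")]
    cnt <- vapply(sampleCounts, function(x) x$counts$count,
                  integer(nrow(keyTab)))
    ctrl <- vapply(sampleCounts, function(x) as.integer(x$control),
                   integer(1))
    tal <- do.call(rbind, lapply(sampleCounts, function(x) x$tallies))
    VariantCounts(cnt, keyTab, sampleMeta, controlCounts = ctrl,
                  tallies = as.data.frame(tal))
}

#' Drop low-quality samples from a count table
#'
#' Removes samples with fewer than \code{minReads} assigned reads, then
#' samples whose log-scale count profile correlates below
#' \code{minTechCorr} (Pearson, on \code{log2(count + 1)}) with every
#' sibling technical repeat of the same factor, timepoint and biological
#' replicate.
#'
#' @param x a [VariantCounts-class].
#' @param minReads minimum assigned reads per sample (default 50000).
#' @param minTechCorr minimum Pearson correlation with at least one
#'   sibling technical repeat (default 0.7); samples without siblings are
#'   kept.
#' @return the filtered [VariantCounts-class]; the QC report (dropped
#'   samples and reasons) is in \code{metadata(x)$qc}.
#' @export
qcFilterSamples <- function(x, minReads = 50000, minTechCorr = 0.7) {
    stopifnot(is(x, "VariantCounts"))
    cnt <- SummarizedExperiment::assay(x, "counts")
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    depth <- colSums(cnt)
    drop <- data.frame(sample_id = character(0), reason = character(0))
    shallow <- depth < minReads
    if (any(shallow))
        drop <- rbind(drop, data.frame(
            sample_id = cd$sample_id[shallow],
            reason = sprintf("assigned reads %d < %g", depth[shallow],
                             minReads)))
    keep <- !shallow
    lg <- log2(cnt + 1)
    grp <- interaction(cd$tf_name, cd$timepoint, cd$bio_rep, drop = TRUE)
    for (g in levels(grp)) {
        members <- which(grp == g & keep)
        if (length(members) < 2L) next
        for (i in members) {
            sib <- setdiff(members, i)
            r <- vapply(sib, function(j) stats::cor(lg[, i], lg[, j]),
                        numeric(1))
            if (all(r < minTechCorr)) {
                drop <- rbind(drop, data.frame(
                    sample_id = cd$sample_id[i],
                    reason = sprintf(
                        "max technical-repeat correlation %.3f < %g",
                        max(r), minTechCorr)))
                keep[i] <- FALSE
            }
        }
    }
    if (!any(keep))
        stop("QC removed every sample (",
             paste(drop$reason, collapse = "; "), ")")
    out <- x[, keep]
    metadata(out)$control_counts <- controlCounts(x)[keep]
    if (!is.null(assignmentTallies(x)))
        metadata(out)$tallies <- assignmentTallies(x)[keep, , drop = FALSE]
    metadata(out)$qc <- drop
    out
}
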