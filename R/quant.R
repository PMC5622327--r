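## Barcode-based quantification of targeted RNA-seq reads: a read is counted
## iff its first 10 bases match a library tag exactly and the following 26
## bases match the reporter constant exactly.

#' Default 26-base reporter constant
#'
#' The study's reporter constant is not printed; this configurable stand-in
#' is used by the synthetic-read generator and the counting defaults.
#' @return A 26-base DNA string.
#' @export
defaultReporter <- function() "TCTAGAGGGTATATAATGGAAGCTCG"

#' Build a tag index from a library or manifest
#'
#' @param x an \linkS4class{MpraLibrary}, or a data.frame with columns
#'   \code{tag} and \code{region_id} (e.g. a read manifest).
#' @param reporter the reporter constant expected downstream of the tag.
#' @return A \linkS4class{TagIndex}.
#' @examples
#' regs <- genEndogenousRegions(simConfig(seed = 1), n = 2)
#' lib <- buildLibrary(regs, nRandom = 0, tagsPerRegion = 2, seed = 1)
#' tagIndex(lib)
#' @export
tagIndex <- function(x, reporter = defaultReporter()) {
    if (is(x, "MpraLibrary")) {
        o <- libOligos(x)
        map <- structure(o$region_id, names = o$tag)
    } else {
        x <- as.data.frame(x)
        stopifnot(all(c("tag", "region_id") %in% colnames(x)))
        map <- structure(x$region_id, names = x$tag)
    }
    .assertDna(names(map), "tag")
    .assertDna(reporter, "reporter")
    new("TagIndex", tag2region = map, reporter = reporter)
}

#' Count reads per tag from targeted sequencing reads
#'
#' A read increments exactly one tag's count iff its first \code{tagLength}
#' bases match a tag in the index perfectly and the following bases match the
#' reporter constant perfectly (Hamming distance 0 for both; no error
#' correction). All other reads are discarded and tallied in the QC summary.
#'
#' @param reads a FASTQ file path, a \code{DNAStringSet}, or a character
#'   vector of read sequences.
#' @param index a \linkS4class{TagIndex}.
#' @return A list with \code{counts} (named integer vector over all index
#'   tags, in index order, zero-filled) and \code{qc} (named integer vector:
#'   \code{total}, \code{matched}, \code{tag_fail}, \code{reporter_fail},
#'   \code{length_fail}).
#' @examples
#' idx <- tagIndex(data.frame(tag = "ACGTACGTAC", region_id = "r1"))
#' countReads(paste0("ACGTACGTAC", defaultReporter(), "AAAA"), idx)$counts
#' @export
countReads <- function(reads, index) {
    stopifnot(is(index, "TagIndex"))
    if (is.character(reads) && length(reads) == 1L && file.exists(reads))
        reads <- readDNAStringSet(reads, format = "fastq")
    if (is(reads, "XStringSet")) reads <- as.character(reads)
    stopifnot(is.character(reads))
    tl <- nchar(names(index@tag2region)[1L])
    rl <- nchar(index@reporter)
    total <- length(reads)
    lengthOk <- nchar(reads) >= tl + rl
    tag <- substr(reads[lengthOk], 1L, tl)
    tagOk <- tag %in% names(index@tag2region)
    repOk <- substr(reads[lengthOk], tl + 1L, tl + rl)[tagOk] ==
        index@reporter
    matchedTags <- tag[tagOk][repOk]
    counts <- table(factor(matchedTags, levels = names(index@tag2region)))
    counts <- structure(as.integer(counts), names = names(index@tag2region))
    qc <- c(total = total,
            matched = length(matchedTags),
            tag_fail = sum(!tagOk),
            reporter_fail = sum(!repOk),
            length_fail = sum(!lengthOk))
    list(counts = counts, qc = qc)
}

#' Assemble per-sample tag counts into a count matrix
#'
#' @param sampleCounts named list of per-sample named count vectors (e.g. the
#'   \code{counts} element of \code{\link{countReads}} output); all samples
#'   must cover the same tag set.
#' @return Integer matrix, tags x samples.
#' @export
bindCounts <- function(sampleCounts) {
    stopifnot(is.list(sampleCounts), length(sampleCounts) >= 1L)
    tags <- names(sampleCounts[[1L]])
    m <- vapply(sampleCounts, function(x) {
        stopifnot(identical(names(x), tags))
        as.integer(x)
    }, integer(length(tags)))
    rownames(m) <- tags
    m
}

#' Aggregate tag-level counts to region level
#'
#' The expression of a variable region is the sum of the reads mapping to its
#' distinct tags. The output covers the full region set of the index,
#' zero-filled for regions with no reads.
#'
#' @param tagCounts named integer vector (one sample) or matrix (tags x
#'   samples) of tag-level counts; names/rownames are tags.
#' @param index a \linkS4class{TagIndex}; every tag in \code{tagCounts} must
#'   be present.
#' @return Region-level counts in the same shape (vector or matrix), rows
#'   sorted by region id.
#' @export
aggregateTags <- function(tagCounts, index) {
    stopifnot(is(index, "TagIndex"))
    vec <- is.null(dim(tagCounts))
    m <- if (vec) matrix(tagCounts, dimnames = list(names(tagCounts), NULL))
         else tagCounts
    if (is.null(rownames(m))) stop("tag counts must be named by tag")
    unknown <- setdiff(rownames(m), names(index@tag2region))
    if (length(unknown))
        stop("tag(s) absent from index: ",
             paste(utils::head(unknown, 3L), collapse = ", "))
    regionLevels <- sort(unique(unname(index@tag2region)))
    f <- factor(unname(index@tag2region[rownames(m)]), levels = regionLevels)
    out <- rowsum(m, f)  # drops no levels present; zero-fill below
    full <- matrix(0L, nrow = length(regionLevels), ncol = ncol(m),
                   dimnames = list(regionLevels, colnames(m)))
    full[rownames(out), ] <- out
    storage.mode(full) <- "integer"
    if (vec) structure(as.integer(full[, 1L]), names = rownames(full))
    else full
}

#' Basal reporter activity normalised to the input pool
#'
#' Per-region normalised log2 ratio of RNA counts to plasmid input pool
#' counts: \code{log2((rna + pc) / sum(rna)) - log2((input + pc) /
#' sum(input))}. Library-size normalisation makes proportional columns give
#' a ratio of exactly 0; the pseudocount keeps the ratio finite at zero
#' counts.
#'
#' @param rnaCounts,inputCounts named numeric vectors of region-level counts
#'   over the same region set.
#' @param pseudocount added to each count before the log ratio (default 1).
#' @return Named numeric vector of log2 ratios.
#' @export
basalActivity <- function(rnaCounts, inputCounts, pseudocount = 1) {
    stopifnot(length(rnaCounts) == length(inputCounts))
    if (!is.null(names(rnaCounts)) && !is.null(names(inputCounts))) {
        stopifnot(setequal(names(rnaCounts), names(inputCounts)))
        inputCounts <- inputCounts[names(rnaCounts)]
    }
    if (sum(rnaCounts) == 0 || sum(inputCounts) == 0)
        stop("zero library size")
    log2((rnaCounts + pseudocount) / sum(rnaCounts)) -
        log2((inputCounts + pseudocount) / sum(inputCounts))
}
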