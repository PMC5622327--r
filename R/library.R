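## MPRA oligonucleotide pool construction: endogenous p53-bound variable
## regions, motif-scrambled partners, random GC-matched controls, and unique
## barcode tags assembled into full-length oligos.

## Tag generator: random DNA tags with no homopolymer run >= 5, no forbidden
## substring (restriction sites), and pairwise Hamming distance >= 2 across
## the whole pool. The Hamming constraint is enforced with masked keys: two
## tags at Hamming distance <= 1 share a key in which one position is
## wildcarded, so a hash of masked keys detects near-duplicates in O(tagLen)
## per tag.
.generateTags <- function(n, tagLength, forbidden = character(),
                          maxAttempts = 200L * n) {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    homopolymer <- paste(sprintf("%s{5,}", DNA_BASES), collapse = "|")
    tags <- character(n)
    got <- 0L
    attempts <- 0L
    while (got < n) {
        attempts <- attempts + 1L
        if (attempts > maxAttempts)
            stop("tag space exhausted after ", maxAttempts, " attempts; ",
                 "requested ", n, " tags of length ", tagLength)
        tag <- paste(sample(DNA_BASES, tagLength, replace = TRUE),
                     collapse = "")
        if (grepl(homopolymer, tag)) next
        if (length(forbidden) &&
            any(vapply(forbidden, grepl, logical(1L), x = tag, fixed = TRUE)))
            next
        keys <- vapply(seq_len(tagLength), function(i) {
            k <- tag
            substr(k, i, i) <- "."
            paste0(i, k)
        }, character(1L))
        if (any(vapply(keys, exists, logical(1L), envir = seen,
                       inherits = FALSE)))
            next
        for (k in keys) assign(k, TRUE, envir = seen)
        got <- got + 1L
        tags[got] <- tag
    }
    tags
}

## Random motif-free control regions, GC-matched to a target within a band.
.randomControls <- function(n, len, gcTarget, gcTol, model,
                            maxAttempts = 500L) {
    out <- character(n)
    for (i in seq_len(n)) {
        ok <- FALSE
        for (a in seq_len(maxAttempts)) {
            s <- randomDna(1L, len, gcTarget)
            if (abs(.gcContent(s) - gcTarget) > gcTol) next
            if (length(scanP53Motif(s, model)) > 0L) next
            out[i] <- s; ok <- TRUE; break
        }
        if (!ok)
            stop("failed to generate a GC-matched motif-free control region")
    }
    out
}

#' Build an MPRA oligonucleotide pool
#'
#' Constructs the full library from a set of endogenous p53-bound variable
#' regions: every endogenous region receives a motif-scrambled partner (via
#' \code{\link{scrambleMotif}}), \code{nRandom} random motif-free control
#' regions GC-matched to the endogenous mean are added, and each variable
#' region is assigned \code{tagsPerRegion} unique barcode tags. Each tagged
#' region is assembled into a full-length oligo according to \code{layout}.
#' The pool therefore contains
#' \code{(2 * n_endogenous + nRandom) * tagsPerRegion} oligos.
#'
#' Tags are random DNA with no homopolymer run of 5 or more, pairwise Hamming
#' distance at least 2, and no restriction-site substring.
#'
#' @param endogenous endogenous variable regions: a named character vector or
#'   a data.frame with columns \code{region_id} and \code{sequence}. Every
#'   sequence must contain a p53 motif (required for scrambling).
#' @param nRandom number of random control regions.
#' @param tagsPerRegion barcode tags per variable region (default 10).
#' @param layout an \linkS4class{OligoLayout}.
#' @param seed integer seed; the build is deterministic given the seed.
#' @param model \linkS4class{P53MotifModel} used for scanning and scramble
#'   verification.
#' @param gcTol admissible deviation of control-region GC from the endogenous
#'   mean.
#' @return An \linkS4class{MpraLibrary}.
#' @examples
#' regs <- genEndogenousRegions(simConfig(seed = 1), n = 3)
#' lib <- buildLibrary(regs, nRandom = 1, tagsPerRegion = 2, seed = 1)
#' lib
#' @export
buildLibrary <- function(endogenous, nRandom, tagsPerRegion = 10L,
                         layout = oligoLayout(), seed = 1L,
                         model = p53MotifModel(), gcTol = 0.05) {
    if (is.character(endogenous)) {
        ids <- names(endogenous)
        if (is.null(ids)) ids <- sprintf("region_%04d", seq_along(endogenous))
        endogenous <- data.frame(region_id = ids, sequence = unname(endogenous))
    }
    stopifnot(is.data.frame(endogenous) || is(endogenous, "DataFrame"))
    endogenous <- as.data.frame(endogenous)
    if (nrow(endogenous) == 0L) stop("need at least one endogenous region")
    stopifnot(tagsPerRegion >= 1L, nRandom >= 0L)
    .assertDna(endogenous$sequence, "endogenous region")
    if (any(nchar(endogenous$sequence) != layout@variableLength))
        stop("endogenous regions must be ", layout@variableLength, " nt")

    withSeed(seed, {
        ## endogenous: locate motifs
        spans <- lapply(endogenous$sequence, scanP53Motif, model = model)
        noMotif <- lengths(spans) == 0L
        if (any(noMotif))
            stop("no p53 motif found in endogenous region(s): ",
                 paste(utils::head(endogenous$region_id[noMotif], 5L),
                       collapse = ", "))
        ms <- vapply(spans, function(s) start(s)[1L], integer(1L))
        me <- vapply(spans, function(s) end(s)[1L], integer(1L))

        ## scrambled partners
        scrSeq <- vapply(seq_len(nrow(endogenous)), function(i) {
            scrambleMotif(endogenous$sequence[i], c(ms[i], me[i]),
                          seed = sample.int(.Machine$integer.max, 1L),
                          model = model)
        }, character(1L))

        ## random controls, GC-matched to the endogenous mean
        gcTarget <- mean(.gcContent(endogenous$sequence))
        rndSeq <- if (nRandom > 0L)
            .randomControls(nRandom, layout@variableLength, gcTarget, gcTol,
                            model)
        else character(0L)

        regions <- DataFrame(
            region_id = c(endogenous$region_id,
                          paste0(endogenous$region_id, "_scr"),
                          sprintf("random_%04d", seq_len(nRandom))),
            category = rep(c("endogenous", "scrambled", "random"),
                           c(nrow(endogenous), nrow(endogenous), nRandom)),
            sequence = c(endogenous$sequence, scrSeq, rndSeq),
            motif_start = c(ms, ms, rep(NA_integer_, nRandom)),
            motif_end = c(me, me, rep(NA_integer_, nRandom)),
            partner_id = c(rep(NA_character_, nrow(endogenous)),
                           endogenous$region_id,
                           rep(NA_character_, nRandom)))

        ## unique tags across the whole pool
        nOligos <- nrow(regions) * tagsPerRegion
        tags <- .generateTags(nOligos, layout@tagLength,
                              forbidden = layout@spacer)
        regionOfOligo <- rep(regions$region_id, each = tagsPerRegion)
        seqOfOligo <- rep(regions$sequence, each = tagsPerRegion)
        oligos <- DataFrame(
            oligo_id = paste0(regionOfOligo, "|", tags),
            region_id = regionOfOligo,
            tag = tags,
            full_sequence = paste0(layout@primer5, seqOfOligo, layout@spacer,
                                   tags, layout@primer3))
        new("MpraLibrary", regions = regions, oligos = oligos, layout = layout)
    })
}

#' Write library oligos as FASTA
#'
#' One record per oligo; record ids are \code{region_id|tag}.
#'
#' @param library an \linkS4class{MpraLibrary}.
#' @param file output FASTA path.
#' @return \code{file}, invisibly.
#' @export
writeLibraryFasta <- function(library, file) {
    o <- libOligos(library)
    x <- DNAStringSet(o$full_sequence)
    names(x) <- o$oligo_id
    writeXStringSet(x, file)
    invisible(file)
}

#' Write or read the library manifest
#'
#' The manifest is a TSV with one row per oligo: \code{region_id},
#' \code{category}, \code{tag}, \code{sequence} (variable region),
#' \code{motif_start}, \code{motif_end}.
#'
#' @param library an \linkS4class{MpraLibrary}.
#' @param file TSV path.
#' @return \code{writeLibraryManifest}: \code{file}, invisibly.
#'   \code{readLibraryManifest}: the manifest as a data.frame.
#' @export
writeLibraryManifest <- function(library, file) {
    o <- as.data.frame(libOligos(library))
    r <- as.data.frame(libRegions(library))
    m <- merge(o[, c("region_id", "tag")],
               r[, c("region_id", "category", "sequence", "motif_start",
                     "motif_end")],
               by = "region_id", sort = FALSE)
    m <- m[order(m$region_id, m$tag),
           c("region_id", "category", "tag", "sequence", "motif_start",
             "motif_end")]
    utils::write.table(m, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' @rdname writeLibraryManifest
#' @export
readLibraryManifest <- function(file) {
    utils::read.delim(file, colClasses = c(
        region_id = "character", category = "character", tag = "character",
        sequence = "character"))
}
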