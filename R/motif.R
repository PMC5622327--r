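## p53 response element scanning and motif scrambling.

## Logical vector over start positions: does the degenerate pattern match at
## each start? Vectorised over positions; O(pattern length x sequence length).
.patternHits <- function(chars, pattern) {
    L <- length(chars)
    P <- nchar(pattern)
    n <- L - P + 1L
    if (n < 1L) return(logical(0L))
    pat <- strsplit(pattern, "", fixed = TRUE)[[1L]]
    ok <- rep(TRUE, n)
    for (j in seq_len(P)) {
        ok <- ok & chars[j:(j + n - 1L)] %in% IUPAC_SETS[[pat[j]]]
    }
    ok
}

#' Scan a sequence for p53 response elements
#'
#' Finds occurrences of two degenerate half sites separated by a spacer
#' within the model's admissible range. All (position, spacer) candidates are
#' enumerated; overlapping candidates are resolved greedily to the leftmost
#' start and, at equal start, the shortest spacer, so the returned spans are
#' non-overlapping and sorted by start.
#'
#' @param sequence a single DNA string over A/C/G/T.
#' @param model a \linkS4class{P53MotifModel}.
#' @return An \code{\link[IRanges]{IRanges}} of motif spans (1-based,
#'   inclusive) with a metadata column \code{spacer}.
#' @examples
#' scanP53Motif("GGGCATGCCCGGGCATGCCC")
#' @export
scanP53Motif <- function(sequence, model = p53MotifModel()) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    .assertDna(sequence)
    chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    hits <- which(.patternHits(chars, model@halfSite))
    P <- nchar(model@halfSite)
    empty <- IRanges()
    mcols(empty)$spacer <- integer(0L)
    if (length(hits) < 2L) return(empty)
    inHits <- logical(length(chars))
    inHits[hits] <- TRUE
    cand <- do.call(rbind, lapply(model@spacerMin:model@spacerMax, function(d) {
        second <- hits + P + d
        keep <- second <= length(chars) - P + 1L & inHits[pmin(second,
            length(inHits))]
        if (!any(keep)) return(NULL)
        cbind(start = hits[keep], spacer = d)
    }))
    if (is.null(cand)) return(empty)
    cand <- cand[order(cand[, "start"], cand[, "spacer"]), , drop = FALSE]
    starts <- integer(0L); ends <- integer(0L); spacers <- integer(0L)
    lastEnd <- 0L
    for (k in seq_len(nrow(cand))) {
        s <- cand[k, "start"]
        e <- s + 2L * P + cand[k, "spacer"] - 1L
        if (s > lastEnd) {
            starts <- c(starts, s); ends <- c(ends, e)
            spacers <- c(spacers, cand[k, "spacer"])
            lastEnd <- e
        }
    }
    out <- IRanges(start = unname(starts), end = unname(ends))
    mcols(out)$spacer <- unname(spacers)
    out
}

.overlapsSpan <- function(spans, from, to) {
    if (length(spans) == 0L) return(FALSE)
    any(start(spans) <= to & end(spans) >= from)
}

#' Randomly scramble the p53 motif within a variable region
#'
#' Permutes the bases inside the motif span uniformly at random, leaving the
#' flanking sequence untouched, and resamples until the permuted span (a)
#' differs from the original and (b) no longer contains a p53 motif
#' overlapping the span. Deterministic for a given seed.
#'
#' @param sequence variable-region DNA string.
#' @param span motif span as a length-2 integer vector (start, end; 1-based
#'   inclusive) or an \code{IRanges} of length 1.
#' @param seed integer seed controlling the permutation draws.
#' @param model the \linkS4class{P53MotifModel} used for rescanning.
#' @param maxAttempts resampling bound; exceeding it is an error.
#' @return The scrambled sequence (single DNA string).
#' @examples
#' r <- "AAAAAGGGCATGCCCGGGCATGCCCAAAAA"
#' sp <- scanP53Motif(r)[1]
#' scrambleMotif(r, sp, seed = 1)
#' @export
scrambleMotif <- function(sequence, span, seed, model = p53MotifModel(),
                          maxAttempts = 1000L) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    .assertDna(sequence)
    if (is(span, "IRanges")) {
        stopifnot(length(span) == 1L)
        from <- start(span); to <- end(span)
    } else {
        from <- as.integer(span[1L]); to <- as.integer(span[2L])
    }
    if (is.na(from) || is.na(to) || from < 1L || to > nchar(sequence) ||
        to - from + 1L < 2L)
        stop("motif span must lie within the sequence and cover >= 2 bases")
    chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    inner <- chars[from:to]
    if (length(unique(inner)) == 1L)
        stop("motif span bases are all identical; no non-trivial permutation")
    withSeed(seed, {
        for (i in seq_len(maxAttempts)) {
            perm <- sample(inner)
            if (identical(perm, inner)) next
            cand <- chars
            cand[from:to] <- perm
            candSeq <- paste(cand, collapse = "")
            if (!.overlapsSpan(scanP53Motif(candSeq, model), from, to))
                return(candSeq)
        }
        stop("no motif-free permutation found within ", maxAttempts,
             " attempts")
    })
}
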