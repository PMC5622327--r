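suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
    library(IRanges)
})

## Shared fixtures, built once per test run and cached.
.fix <- new.env(parent = emptyenv())

fixLibrary <- function() {
    if (is.null(.fix$lib)) {
        regs <- genEndogenousRegions(simConfig(seed = 101L), n = 8)
        .fix$lib <- buildLibrary(regs, nRandom = 4, tagsPerRegion = 3,
                                 seed = 101L)
    }
    .fix$lib
}

fixMpraSim <- function() {
    if (is.null(.fix$mpra)) {
        cfg <- simConfig(seed = 202L, mpraDepth = 60)
        .fix$mpra <- genMpraDataset(cfg, fixLibrary(), dir = tempfile())
    }
    .fix$mpra
}

fixAtacConfig <- function(seed = 303L)
    simConfig(seed = seed, nSites = 40L, genomeLength = 2e6,
              siteWidth = 10000L, totalReads = 2e5)

fixAtac <- function() {
    if (is.null(.fix$atac)) .fix$atac <- genAtacDataset(fixAtacConfig())
    .fix$atac
}

## Independent brute-force IUPAC matcher used as the motif-scan oracle.
## Deliberately naive: per-position nested loops over character sets.
oracleIupac <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"))

oracleHalfSiteMatch <- function(chars, at, pattern) {
    for (j in seq_len(nchar(pattern))) {
        allowed <- oracleIupac[[substr(pattern, j, j)]]
        if (!(chars[at + j - 1L] %in% allowed)) return(FALSE)
    }
    TRUE
}

## Enumerates every (position, spacer) candidate by brute force, then
## applies the stated resolution rule (leftmost start, shortest spacer,
## non-overlapping, sorted).
oracleScan <- function(sequence, halfSite = "RRRCWWGYYY",
                       spacerRange = c(0L, 13L)) {
    chars <- strsplit(sequence, "")[[1L]]
    L <- length(chars)
    P <- nchar(halfSite)
    cand <- list()
    for (i in seq_len(max(0L, L - 2L * P + 1L))) {
        for (d in spacerRange[1L]:spacerRange[2L]) {
            j <- i + P + d
            if (j + P - 1L > L) next
            if (oracleHalfSiteMatch(chars, i, halfSite) &&
                oracleHalfSiteMatch(chars, j, halfSite))
                cand[[length(cand) + 1L]] <-
                    c(start = i, end = i + 2L * P + d - 1L, spacer = d)
        }
    }
    if (!length(cand))
        return(data.frame(start = integer(0L), end = integer(0L),
                          spacer = integer(0L)))
    m <- as.data.frame(do.call(rbind, cand))
    m <- m[order(m$start, m$spacer), ]
    keep <- list()
    lastEnd <- 0L
    for (k in seq_len(nrow(m))) {
        if (m$start[k] > lastEnd) {
            keep[[length(keep) + 1L]] <- m[k, ]
            lastEnd <- m$end[k]
        }
    }
    out <- do.call(rbind, keep)
    rownames(out) <- NULL
    out
}

randomSeq <- function(n, len, seed) {
    withr_seed <- seed
    set.seed(withr_seed)
    vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = ""), character(1L))
}
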