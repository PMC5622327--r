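## Transcription factor enrichment within pioneering sites — the
## (s/S)/(g/G) statistic with a label-shuffling permutation null — and
## pairwise co-occurrence significance via the upper-tail hypergeometric
## distribution, both Bonferroni-corrected.

#' Normalise per-factor peak sets
#'
#' Sorts and merges (reduces) overlapping peaks within each factor, the
#' standard treatment for ChIP-seq cluster files which contain overlapping
#' entries.
#'
#' @param x a named \code{GRangesList} or named list of \code{GRanges}, one
#'   element per factor.
#' @return A named \code{GRangesList} of sorted, disjoint peaks.
#' @export
peakSets <- function(x) {
    if (is.list(x)) x <- GRangesList(x)
    stopifnot(is(x, "GRangesList"))
    if (is.null(names(x)) || anyDuplicated(names(x)))
        stop("peak sets must carry unique factor names")
    GRangesList(lapply(x, function(gr) sort(reduce(gr,
        ignore.strand = TRUE))))
}

.enrichOne <- function(pk, pio, genomeNt, pioNt) {
    g <- length(pk)
    peakNt <- sum(width(pk))
    s <- sum(countOverlaps(pk, pio, ignore.strand = TRUE) > 0L)
    S <- pioNt / peakNt
    G <- genomeNt / peakNt
    c(s = s, g = g, peak_nt = peakNt, S = S, G = G,
      enrichment = (s / S) / (g / G))
}

#' TF binding enrichment within pioneering sites
#'
#' For each factor, enrichment = (s/S)/(g/G), where s is the number of the
#' factor's peaks overlapping (by at least one base) a pioneering site, g
#' the number of its peaks in the genome, S the nucleotides covered by
#' pioneering sites divided by the nucleotides covered by the factor's
#' peaks, and G the genome size divided by the nucleotides covered by the
#' factor's peaks. Algebraically this equals (s/g) x (genome_nt /
#' pioneering_nt); the peak coverage cancels.
#'
#' @param peaks named \code{GRangesList} of per-factor peaks (merged on
#'   load via \code{\link{peakSets}}).
#' @param pioneering \code{GRanges} of pioneering sites (merged internally).
#' @param genomeNt genome size in bases.
#' @return A \code{DataFrame} with one row per factor: \code{factor},
#'   \code{s}, \code{g}, \code{peak_nt}, \code{pioneering_nt},
#'   \code{genome_nt}, \code{S}, \code{G}, \code{enrichment}. Factors with
#'   zero peak coverage are skipped with a warning.
#' @export
tfEnrichment <- function(peaks, pioneering, genomeNt) {
    peaks <- peakSets(peaks)
    stopifnot(is(pioneering, "GRanges"), genomeNt > 0)
    pio <- reduce(pioneering, ignore.strand = TRUE)
    if (length(pio) == 0L) stop("empty pioneering set")
    pioNt <- sum(width(pio))
    empty <- vapply(peaks, function(pk) sum(width(pk)) == 0,
                    logical(1L))
    if (any(empty)) {
        warning("skipping factor(s) with zero peak coverage: ",
                paste(names(peaks)[empty], collapse = ", "))
        peaks <- peaks[!empty]
    }
    rows <- t(vapply(peaks, .enrichOne, numeric(6L), pio = pio,
                     genomeNt = genomeNt, pioNt = pioNt))
    DataFrame(factor = names(peaks),
              s = as.integer(rows[, "s"]), g = as.integer(rows[, "g"]),
              peak_nt = rows[, "peak_nt"],
              pioneering_nt = pioNt, genome_nt = genomeNt,
              S = rows[, "S"], G = rows[, "G"],
              enrichment = rows[, "enrichment"])
}

#' Permutation significance of TF enrichment
#'
#' Pools all factors' peaks and repeatedly reassigns factor labels at random
#' across the pooled collection (preserving each factor's peak count),
#' recomputing every factor's enrichment per shuffle. The permutation
#' p-value uses the add-one estimator p = (1 + #\{shuffles with enrichment
#' >= observed\}) / (nShuffles + 1), so p is bounded below by
#' 1/(nShuffles + 1) and never exactly 0; Bonferroni multiplies by the
#' number of factors. Deterministic given the seed.
#'
#' @param peaks named \code{GRangesList} of per-factor peaks (at least two
#'   factors).
#' @param pioneering \code{GRanges} of pioneering sites.
#' @param genomeNt genome size in bases.
#' @param nShuffles number of label shuffles (default 100, as in the
#'   enrichment analysis this implements).
#' @param seed integer seed.
#' @return The \code{\link{tfEnrichment}} table with added columns
#'   \code{perm_p} and \code{adjusted_p}.
#' @export
permutationSignificance <- function(peaks, pioneering, genomeNt,
                                    nShuffles = 100L, seed = 1L) {
    stopifnot(nShuffles >= 1L)
    peaks <- peakSets(peaks)
    if (length(peaks) < 2L)
        stop("permutation null is degenerate with a single factor; ",
             "need at least two peak sets")
    obs <- tfEnrichment(peaks, pioneering, genomeNt)
    peaks <- peaks[obs$factor]
    pio <- reduce(pioneering, ignore.strand = TRUE)
    pooled <- unlist(GRangesList(unname(peaks)), use.names = FALSE)
    labels <- factor(rep(names(peaks), lengths(peaks)),
                     levels = names(peaks))
    hit <- countOverlaps(pooled, pio, ignore.strand = TRUE) > 0L
    ## enrichment = (s/g) * (genomeNt/pioNt); g and the constants are fixed
    ## under label reassignment, so shuffles compare on s alone.
    sObs <- obs$s
    exceed <- integer(length(peaks))
    withSeed(seed, {
        for (i in seq_len(nShuffles)) {
            sPerm <- tabulate(labels[sample.int(length(labels))][hit],
                              nbins = length(peaks))
            exceed <- exceed + (sPerm >= sObs)
        }
    })
    obs$perm_p <- (1 + exceed) / (nShuffles + 1)
    obs$adjusted_p <- pmin(1, obs$perm_p * length(peaks))
    obs
}

#' Pioneering sites overlapped by each factor
#'
#' Helper mapping each factor to the indices of the pioneering sites its
#' peaks overlap (by at least one base), the input expected by
#' \code{\link{cooccurrenceSignificance}}.
#'
#' @param peaks named \code{GRangesList} of per-factor peaks.
#' @param pioneering \code{GRanges} of pioneering sites.
#' @return Named list of integer site-index vectors.
#' @export
pioneeringOverlapSets <- function(peaks, pioneering) {
    peaks <- peakSets(peaks)
    stopifnot(is(pioneering, "GRanges"))
    lapply(as.list(peaks), function(pk)
        which(countOverlaps(pioneering, pk, ignore.strand = TRUE) > 0L))
}

#' Hypergeometric co-occurrence of TF binding within pioneering sites
#'
#' For every unordered factor pair, tests whether the number of pioneering
#' sites overlapped by both factors is larger than expected when drawing
#' without replacement: with k_a and k_b sites overlapped by each factor out
#' of n_total pioneering sites, the upper-tail p-value is
#' P(X >= k_both) for X ~ Hypergeometric(n_total, k_a, k_b). P-values are
#' Bonferroni-corrected over all pairs. A factor overlapping zero sites
#' gives p = 1 for its pairs.
#'
#' @param overlapSets named list mapping factor to the ids of the pioneering
#'   sites it overlaps (see \code{\link{pioneeringOverlapSets}}).
#' @param nTotal total number of pioneering sites.
#' @return A \code{DataFrame}: \code{factor_a}, \code{factor_b},
#'   \code{n_total}, \code{k_a}, \code{k_b}, \code{k_both}, \code{hyper_p},
#'   \code{adjusted_p}.
#' @examples
#' cooccurrenceSignificance(list(a = 1:5, b = c(1:3, 6)), nTotal = 10)
#' @export
cooccurrenceSignificance <- function(overlapSets, nTotal) {
    stopifnot(is.list(overlapSets), length(overlapSets) >= 2L,
              !is.null(names(overlapSets)), nTotal >= 1L)
    overlapSets <- lapply(overlapSets, unique)
    if (any(lengths(overlapSets) > nTotal))
        stop("a factor overlaps more sites than nTotal")
    cmb <- utils::combn(names(overlapSets), 2L)
    n <- ncol(cmb)
    kA <- lengths(overlapSets)[cmb[1L, ]]
    kB <- lengths(overlapSets)[cmb[2L, ]]
    kBoth <- vapply(seq_len(n), function(j)
        length(intersect(overlapSets[[cmb[1L, j]]],
                         overlapSets[[cmb[2L, j]]])), integer(1L))
    p <- stats::phyper(kBoth - 1L, kA, nTotal - kA, kB, lower.tail = FALSE)
    DataFrame(factor_a = cmb[1L, ], factor_b = cmb[2L, ],
              n_total = as.integer(nTotal),
              k_a = as.integer(kA), k_b = as.integer(kB), k_both = kBoth,
              hyper_p = p, adjusted_p = pmin(1, p * n))
}
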