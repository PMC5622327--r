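## Per-position, per-base sequence activity contribution over the variable
## region: the summed activity (absolute fold-change) of all elements
## carrying base N at position i, normalised by the frequency of base N at
## position i, rescaled to a maximum of 1.

#' Sequence activity contribution matrix
#'
#' For every base \code{N} in A/C/G/T and position \code{i} along the
#' variable region, the activities (absolute, unsigned fold-changes) of all
#' elements whose sequence carries \code{N} at \code{i} are summed and
#' normalised by the frequency at which \code{N} appears at \code{i}; the
#' matrix is then rescaled so its maximum entry equals 1. Frequency is
#' implemented as the element count; using the proportion instead differs by
#' a global constant that cancels in the rescaling. Cells never covered by
#' any element are reported as 0 and flagged undefined.
#'
#' @param sequences character vector of equal-length element sequences.
#' @param activity numeric vector of non-negative activities, parallel to
#'   \code{sequences} (pass \code{2^abs(log2FoldChange)} or any unsigned
#'   fold-change convention explicitly).
#' @param rescale divide by the maximum defined entry (default TRUE).
#' @return An \linkS4class{ActivityMatrix}.
#' @examples
#' m <- activityContribution(c("A", "C"), c(4, 1))
#' activityValues(m)[, 1]
#' @export
activityContribution <- function(sequences, activity, rescale = TRUE) {
    .assertDna(sequences, "element sequence")
    stopifnot(length(sequences) == length(activity), is.numeric(activity))
    if (any(is.na(activity)) || any(activity < 0))
        stop("activities must be non-negative and non-missing")
    if (all(activity == 0))
        stop("all activities are zero; the rescaling maximum is undefined")
    M <- .seqMatrix(sequences)
    L <- ncol(M)
    values <- matrix(0, nrow = 4L, ncol = L,
                     dimnames = list(DNA_BASES, seq_len(L)))
    coverage <- matrix(0L, nrow = 4L, ncol = L,
                       dimnames = list(DNA_BASES, seq_len(L)))
    for (b in DNA_BASES) {
        ind <- M == b
        coverage[b, ] <- colSums(ind)
        values[b, ] <- colSums(ind * activity)
    }
    def <- coverage > 0L
    values[def] <- values[def] / coverage[def]
    if (rescale) values <- values / max(values[def])
    new("ActivityMatrix", values = values, coverage = coverage)
}

#' Position-wise activity contribution profile
#'
#' Collapses the 4 x L matrix to a length-L profile by taking, at each
#' position, the maximum contribution over the covered bases — the
#' position-wise summary displayed in sequence-activity-contribution plots,
#' which peaks over the bases of the motif driving activity. Positions with
#' no coverage give 0.
#'
#' @param x an \linkS4class{ActivityMatrix}.
#' @return Numeric vector of length L.
#' @export
positionProfile <- function(x) {
    stopifnot(is(x, "ActivityMatrix"))
    v <- x@values
    v[x@coverage == 0L] <- -Inf
    out <- apply(v, 2L, max)
    out[!is.finite(out)] <- 0
    out
}
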