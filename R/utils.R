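#' Evaluate an expression under a fixed RNG seed
#'
#' Runs \code{expr} with the global RNG seeded at \code{seed} and restores the
#' caller's RNG state afterwards, so that seeded operations are reproducible
#' without disturbing the session stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

DNA_BASES <- c("A", "C", "G", "T")

## IUPAC degenerate nucleotide codes, used by the motif scanner.
IUPAC_SETS <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

.assertDna <- function(x, what = "sequence") {
    if (!is.character(x) || any(is.na(x)))
        stop(what, " must be a character vector without NAs")
    bad <- grepl("[^ACGT]", x)
    if (any(bad))
        stop(what, " contains non-ACGT characters (first offender: '",
             x[which(bad)[1L]], "')")
    invisible(x)
}

#' Random DNA strings with a target GC fraction
#'
#' @param n number of sequences.
#' @param len length of each sequence.
#' @param gc expected GC fraction in [0, 1].
#' @return Character vector of length \code{n}.
#' @keywords internal
randomDna <- function(n, len, gc = 0.5) {
    stopifnot(gc >= 0, gc <= 1, len >= 1)
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    m <- matrix(sample(DNA_BASES, n * len, replace = TRUE, prob = p),
                nrow = len)
    apply(m, 2L, paste, collapse = "")
}

.gcContent <- function(x) {
    vapply(gregexpr("[GC]", x), function(m) {
        if (m[1L] == -1L) 0L else length(m)
    }, integer(1L)) / nchar(x)
}

## Split equal-length sequences into an n x L character matrix.
.seqMatrix <- function(x) {
    L <- unique(nchar(x))
    if (length(L) != 1L)
        stop("all sequences must have equal length")
    matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
           ncol = L, byrow = TRUE)
}
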