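## Interval and table IO. BED files are 0-based half-open; GRanges are
## 1-based inclusive — rtracklayer performs the conversion.

#' Write and read genomic intervals as BED
#'
#' @param gr a \code{GRanges} (names become the BED name field).
#' @param file BED path.
#' @return \code{writeIntervalsBed}: \code{file}, invisibly;
#'   \code{readIntervalsBed}: a \code{GRanges}.
#' @export
writeIntervalsBed <- function(gr, file) {
    stopifnot(is(gr, "GRanges"))
    rtracklayer::export(gr, file, format = "BED")
    invisible(file)
}

#' @rdname writeIntervalsBed
#' @export
readIntervalsBed <- function(file) {
    rtracklayer::import(file, format = "BED")
}

#' Write a differential-activity or accessibility table as TSV
#'
#' @param x a \code{DataFrame} or data.frame.
#' @param file TSV path.
#' @return \code{file}, invisibly.
#' @export
writeResultsTsv <- function(x, file) {
    utils::write.table(as.data.frame(x), file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}
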