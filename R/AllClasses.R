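#' @import methods
#' @importFrom S4Vectors DataFrame metadata mcols mcols<- splitAsList
#' @importFrom BiocGenerics sort start end width strand
#' @importFrom IRanges IRanges CharacterList findOverlaps countOverlaps
#'   reduce gaps
#' @importFrom GenomicRanges GRanges GRangesList seqnames
#' @importFrom Biostrings DNAStringSet BStringSet readDNAStringSet
#'   writeXStringSet
NULL

## ---------------------------------------------------------------------------
## p53 response element model
## ---------------------------------------------------------------------------

#' P53MotifModel: degenerate consensus for the p53 response element
#'
#' The canonical p53 response element consists of two copies of the degenerate
#' decamer half site \code{RRRCWWGYYY} separated by a spacer of 0-13 bases.
#' Both the half-site pattern and the admissible spacer range are configurable.
#'
#' @slot halfSite degenerate IUPAC decamer matched by each half site.
#' @slot spacerMin,spacerMax admissible spacer lengths (bases) between the two
#'   half sites.
#' @exportClass P53MotifModel
setClass("P53MotifModel",
    representation(halfSite = "character",
                   spacerMin = "integer",
                   spacerMax = "integer"))

setValidity("P53MotifModel", function(object) {
    msg <- character()
    if (length(object@halfSite) != 1L || nchar(object@halfSite) != 10L)
        msg <- c(msg, "halfSite must be a single 10-base pattern")
    else if (!all(strsplit(object@halfSite, "")[[1L]] %in% names(IUPAC_SETS)))
        msg <- c(msg, "halfSite contains non-IUPAC characters")
    if (object@spacerMin < 0L || object@spacerMax < object@spacerMin)
        msg <- c(msg, "spacer bounds must satisfy 0 <= min <= max")
    if (length(msg)) msg else TRUE
})

#' Construct a p53 response element model
#'
#' @param halfSite degenerate decamer half-site pattern (IUPAC codes).
#' @param spacer length-2 integer vector, minimum and maximum spacer (bases)
#'   between the two half sites.
#' @return A \linkS4class{P53MotifModel}.
#' @examples
#' p53MotifModel()
#' @export
p53MotifModel <- function(halfSite = "RRRCWWGYYY", spacer = c(0L, 13L)) {
    new("P53MotifModel", halfSite = toupper(halfSite),
        spacerMin = as.integer(spacer[1L]), spacerMax = as.integer(spacer[2L]))
}

setMethod("show", "P53MotifModel", function(object) {
    cat("P53MotifModel: ", object@halfSite, " {",
        object@spacerMin, "-", object@spacerMax, " nt spacer} ",
        object@halfSite, "\n", sep = "")
})

## ---------------------------------------------------------------------------
## Oligo layout
## ---------------------------------------------------------------------------

#' OligoLayout: fixed architecture of a 150-mer MPRA oligonucleotide
#'
#' Layout of the synthesised oligo:
#' \code{[5' primer][variable region][restriction spacer][tag][3' primer]}.
#' The variable region sits upstream of the tag, separated by a restriction
#' spacer into which the reporter cassette is cloned. Segment lengths must sum
#' to \code{oligoLength}.
#'
#' @slot primer5,spacer,primer3 fixed DNA segments.
#' @slot variableLength,tagLength lengths (nt) of the variable region and tag.
#' @slot oligoLength total oligo length (nt).
#' @exportClass OligoLayout
setClass("OligoLayout",
    representation(primer5 = "character", spacer = "character",
                   primer3 = "character", variableLength = "integer",
                   tagLength = "integer", oligoLength = "integer"))

setValidity("OligoLayout", function(object) {
    .assertDna(c(object@primer5, object@spacer, object@primer3),
               "layout segment")
    tot <- nchar(object@primer5) + object@variableLength +
        nchar(object@spacer) + object@tagLength + nchar(object@primer3)
    if (tot != object@oligoLength)
        return(sprintf("layout lengths sum to %d, not %d",
                       tot, object@oligoLength))
    TRUE
})

#' Construct an oligo layout
#'
#' Defaults give the 150-mer architecture
#' 15 nt 5' primer + 95 nt variable region + 10 nt restriction spacer
#' (KpnI site) + 10 nt tag + 20 nt 3' primer. The fixed sequences are
#' configurable stand-ins; the study does not print its primer or restriction
#' sequences.
#'
#' @param primer5,spacer,primer3 fixed DNA segments.
#' @param variableLength,tagLength,oligoLength segment lengths (nt).
#' @return An \linkS4class{OligoLayout}.
#' @examples
#' oligoLayout()
#' @export
oligoLayout <- function(primer5 = "ACTGGCCGCTTCACT",
                        spacer = "AGGTACCGAT",
                        primer3 = "AGATCGGAAGAGCGTCGTGT",
                        variableLength = 95L, tagLength = 10L,
                        oligoLength = 150L) {
    new("OligoLayout", primer5 = primer5, spacer = spacer, primer3 = primer3,
        variableLength = as.integer(variableLength),
        tagLength = as.integer(tagLength),
        oligoLength = as.integer(oligoLength))
}

setMethod("show", "OligoLayout", function(object) {
    cat(sprintf(
        "OligoLayout (%d nt): [%d nt primer][%d nt variable][%d nt spacer][%d nt tag][%d nt primer]\n",
        object@oligoLength, nchar(object@primer5), object@variableLength,
        nchar(object@spacer), object@tagLength, nchar(object@primer3)))
})

## ---------------------------------------------------------------------------
## MPRA library
## ---------------------------------------------------------------------------

#' MpraLibrary: a designed MPRA oligonucleotide pool
#'
#' Holds the variable regions (endogenous p53-bound sequences, their
#' motif-scrambled partners, and random controls) and the tagged 150-mer
#' oligos assembled from them. Each variable region carries
#' \code{tagsPerRegion} unique barcode tags.
#'
#' @slot regions \code{DataFrame} with columns \code{region_id},
#'   \code{category} (endogenous/scrambled/random), \code{sequence},
#'   \code{motif_start}, \code{motif_end} (1-based inclusive, NA when no
#'   motif), \code{partner_id} (scrambled regions point to their endogenous
#'   partner).
#' @slot oligos \code{DataFrame} with columns \code{oligo_id},
#'   \code{region_id}, \code{tag}, \code{full_sequence}.
#' @slot layout the \linkS4class{OligoLayout} used for assembly.
#' @seealso \code{\link{buildLibrary}}
#' @exportClass MpraLibrary
setClass("MpraLibrary",
    representation(regions = "DataFrame", oligos = "DataFrame",
                   layout = "OligoLayout"))

setValidity("MpraLibrary", function(object) {
    r <- object@regions; o <- object@oligos; lay <- object@layout
    msg <- character()
    need <- c("region_id", "category", "sequence", "motif_start",
              "motif_end", "partner_id")
    if (!all(need %in% colnames(r)))
        msg <- c(msg, "regions is missing required columns")
    else {
        if (any(nchar(r$sequence) != lay@variableLength))
            msg <- c(msg, sprintf("all variable regions must be %d nt",
                                  lay@variableLength))
        if (!all(r$category %in% c("endogenous", "scrambled", "random")))
            msg <- c(msg, "unknown region category")
        if (anyDuplicated(r$region_id))
            msg <- c(msg, "region_id values must be unique")
    }
    if (!all(c("oligo_id", "region_id", "tag", "full_sequence") %in%
             colnames(o)))
        msg <- c(msg, "oligos is missing required columns")
    else {
        if (anyDuplicated(o$tag))
            msg <- c(msg, "tags must be unique across the pool")
        if (any(nchar(o$tag) != lay@tagLength))
            msg <- c(msg, sprintf("all tags must be %d nt", lay@tagLength))
        if (any(nchar(o$full_sequence) != lay@oligoLength))
            msg <- c(msg, sprintf("all oligos must be %d nt", lay@oligoLength))
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "MpraLibrary", function(object) {
    tab <- table(object@regions$category)
    cat("MpraLibrary with", nrow(object@oligos), "oligos over",
        nrow(object@regions), "variable regions\n")
    cat("  regions:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                            collapse = ", "), "\n")
    cat(sprintf("  oligo length %d nt, variable region %d nt, tag %d nt\n",
                object@layout@oligoLength, object@layout@variableLength,
                object@layout@tagLength))
})

#' @describeIn MpraLibrary variable-region table.
#' @param x an \code{MpraLibrary}.
#' @export
libRegions <- function(x) x@regions

#' @describeIn MpraLibrary oligo table (one row per tagged 150-mer).
#' @export
libOligos <- function(x) x@oligos

#' @describeIn MpraLibrary the oligo layout.
#' @export
libLayout <- function(x) x@layout

## ---------------------------------------------------------------------------
## Tag index
## ---------------------------------------------------------------------------

#' TagIndex: barcode-to-region lookup for read counting
#'
#' Maps each 10-base tag to its variable region and records the 26-base
#' reporter constant expected immediately downstream of the tag in every
#' targeted RNA-seq read.
#'
#' @slot tag2region named character vector; names are tags, values region ids.
#' @slot reporter the reporter constant sequence.
#' @exportClass TagIndex
setClass("TagIndex",
    representation(tag2region = "character", reporter = "character"))

setValidity("TagIndex", function(object) {
    t <- names(object@tag2region)
    msg <- character()
    if (length(t) == 0L) msg <- c(msg, "index must contain at least one tag")
    if (anyDuplicated(t)) msg <- c(msg, "tags must be unique")
    if (length(unique(nchar(t))) > 1L)
        msg <- c(msg, "all tags must have the same length")
    if (length(object@reporter) != 1L || nchar(object@reporter) < 1L)
        msg <- c(msg, "reporter must be a single non-empty sequence")
    if (length(msg)) msg else TRUE
})

setMethod("show", "TagIndex", function(object) {
    cat("TagIndex:", length(object@tag2region), "tags (",
        nchar(names(object@tag2region)[1L]), "nt ) over",
        length(unique(object@tag2region)), "regions;",
        nchar(object@reporter), "nt reporter constant\n")
})

## ---------------------------------------------------------------------------
## Activity contribution matrix
## ---------------------------------------------------------------------------

#' ActivityMatrix: per-position, per-base sequence activity contribution
#'
#' A 4 x L matrix (rows A, C, G, T) of activity contributions over the
#' variable region, rescaled so that the maximum entry equals 1, together
#' with the 4 x L coverage (number of elements carrying base N at position
#' i). Cells with zero coverage are reported as 0 and flagged undefined.
#'
#' @slot values rescaled contribution matrix.
#' @slot coverage integer coverage matrix.
#' @seealso \code{\link{activityContribution}}
#' @exportClass ActivityMatrix
setClass("ActivityMatrix",
    representation(values = "matrix", coverage = "matrix"))

setValidity("ActivityMatrix", function(object) {
    msg <- character()
    if (!identical(dim(object@values), dim(object@coverage)))
        msg <- c(msg, "values and coverage must have identical dimensions")
    if (!identical(rownames(object@values), DNA_BASES))
        msg <- c(msg, "rows must be A, C, G, T")
    if (any(object@values < 0)) msg <- c(msg, "contributions must be >= 0")
    def <- object@coverage > 0L
    if (any(def) && abs(max(object@values[def]) - 1) > 1e-12)
        msg <- c(msg, "maximum defined contribution must equal 1")
    if (any(object@values[!def] != 0))
        msg <- c(msg, "undefined cells (zero coverage) must be 0")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ActivityMatrix", function(object) {
    L <- ncol(object@values)
    cat("ActivityMatrix: 4 x", L, "(max contribution rescaled to 1;",
        sum(object@coverage == 0L), "undefined cells)\n")
})

#' @describeIn ActivityMatrix rescaled 4 x L contribution values.
#' @param x an \code{ActivityMatrix}.
#' @export
activityValues <- function(x) x@values

#' @describeIn ActivityMatrix 4 x L coverage counts.
#' @export
activityCoverage <- function(x) x@coverage

#' @describeIn ActivityMatrix logical 4 x L matrix flagging zero-coverage
#'   (undefined) cells.
#' @export
undefinedCells <- function(x) x@coverage == 0L
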