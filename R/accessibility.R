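## Chromatin accessibility at p53 binding sites: region FPKM from aligned
## fragment intervals, four-way accessibility classification, fold-change
## sub-classification of accessible sites, TSS proximity, and induction of
## nearby genes by class.

ACCESSIBILITY_CLASSES <- c("constitutively_accessible",
                           "constitutively_inaccessible",
                           "pioneering", "intermediate")

#' Region FPKM from fragment intervals
#'
#' FPKM = fragments overlapping the region / (region length in kb x total
#' mapped fragments in millions). A fragment overlaps a region if they share
#' at least one base; a fragment overlapping two regions counts in both.
#' Replicates are pooled by summing fragments before normalisation
#' (default), or averaged per replicate with \code{pooling = "mean"}.
#'
#' @param reads a \code{GRanges} of fragment intervals, or a
#'   \code{GRangesList}/list of them (one per replicate).
#' @param regions \code{GRanges} of regions to quantify.
#' @param pooling \code{"sum"} (pool fragments, then normalise) or
#'   \code{"mean"} (per-replicate FPKM, then average).
#' @return Numeric vector of FPKM values, named by region names when
#'   present.
#' @examples
#' rg <- GRanges("chr1", IRanges(1, 1000))
#' rd <- GRanges("chr1", IRanges(rep(1, 10), width = 50))
#' regionFpkm(rd, rg) # 10 fragments, 1 kb, 10 total => 1e6 FPKM scale
#' @export
regionFpkm <- function(reads, regions, pooling = c("sum", "mean")) {
    pooling <- match.arg(pooling)
    if (is(reads, "GRanges")) reads <- GRangesList(rep1 = reads)
    if (is.list(reads)) reads <- GRangesList(reads)
    stopifnot(is(reads, "GRangesList"), is(regions, "GRanges"))
    one <- function(gr) {
        total <- length(gr)
        if (total == 0L) stop("zero total fragments")
        countOverlaps(regions, gr, ignore.strand = TRUE) /
            (width(regions) / 1000 * total / 1e6)
    }
    fpkm <- if (pooling == "sum") {
        one(unlist(reads, use.names = FALSE))
    } else {
        perRep <- vapply(seq_along(reads), function(i) one(reads[[i]]),
                         numeric(length(regions)))
        rowMeans(matrix(perRep, nrow = length(regions)))
    }
    names(fpkm) <- names(regions)
    fpkm
}

#' Classify binding-site accessibility from untreated/treated FPKM
#'
#' Rules, with strict inequalities: FPKM < 1 untreated and > 2 treated is
#' \code{pioneering}; < 1 untreated and < 1.5 treated is
#' \code{constitutively_inaccessible}; > 1 in both conditions is
#' \code{constitutively_accessible}; every remaining region (including all
#' boundary values and the 1.5-2 treated band) is \code{intermediate}, the
#' catch-all. The result is a total partition: each region receives exactly
#' one class.
#'
#' @param fpkmUntreated,fpkmTreated non-negative FPKM vectors.
#' @return Factor with levels
#'   \code{constitutively_accessible, constitutively_inaccessible,
#'   pioneering, intermediate}.
#' @examples
#' classifyAccessibility(c(0.5, 0.5, 0.5, 1.5), c(3, 0.8, 1.7, 2.5))
#' @export
classifyAccessibility <- function(fpkmUntreated, fpkmTreated) {
    stopifnot(length(fpkmUntreated) == length(fpkmTreated))
    if (any(fpkmUntreated < 0) || any(fpkmTreated < 0))
        stop("FPKM values must be non-negative")
    cls <- rep("intermediate", length(fpkmUntreated))
    cls[fpkmUntreated < 1 & fpkmTreated > 2] <- "pioneering"
    cls[fpkmUntreated < 1 & fpkmTreated < 1.5] <- "constitutively_inaccessible"
    cls[fpkmUntreated > 1 & fpkmTreated > 1] <- "constitutively_accessible"
    out <- factor(cls, levels = ACCESSIBILITY_CLASSES)
    names(out) <- names(fpkmUntreated)
    out
}

#' Sub-classify constitutively accessible sites by accessibility fold-change
#'
#' Among constitutively accessible sites: treated/untreated FPKM ratio > 2
#' is \code{increased}, untreated/treated > 2 is \code{decreased}, otherwise
#' \code{unchanged} (strict inequalities).
#'
#' @param fpkmUntreated,fpkmTreated FPKM vectors of sites already classified
#'   constitutively accessible (untreated FPKM > 1 by the class rule).
#' @return Factor with levels \code{increased, unchanged, decreased}.
#' @examples
#' subclassifyAccessible(c(1.5, 2, 4), c(4, 3, 1.5))
#' @export
subclassifyAccessible <- function(fpkmUntreated, fpkmTreated) {
    stopifnot(length(fpkmUntreated) == length(fpkmTreated))
    if (any(fpkmUntreated <= 0) || any(fpkmTreated < 0))
        stop("accessible sites must have positive untreated FPKM")
    cls <- rep("unchanged", length(fpkmUntreated))
    cls[fpkmTreated / fpkmUntreated > 2] <- "increased"
    cls[fpkmUntreated / fpkmTreated > 2] <- "decreased"
    out <- factor(cls, levels = c("increased", "unchanged", "decreased"))
    names(out) <- names(fpkmUntreated)
    out
}

#' Genes with a TSS near each binding site
#'
#' A gene is assigned to a site iff the distance (in bases, by coordinate
#' difference) from its TSS to the nearest edge of the site interval is at
#' most \code{window}; a TSS inside the site has distance 0. A gene may map
#' to multiple sites.
#'
#' @param sites \code{GRanges} of binding sites (named).
#' @param tss \code{GRanges} of width-1 TSS positions, named by gene.
#' @param window maximum distance in bases (default 2000).
#' @return A \code{CharacterList}, one element per site, of nearby gene
#'   names (possibly empty).
#' @export
genesNearSites <- function(sites, tss, window = 2000L) {
    stopifnot(is(sites, "GRanges"), is(tss, "GRanges"), window >= 0)
    siteNames <- names(sites)
    if (is.null(siteNames)) siteNames <- sprintf("site_%05d",
                                                 seq_along(sites))
    geneNames <- names(tss)
    if (is.null(geneNames)) stop("tss must be named by gene")
    if (length(sites) == 0L || length(tss) == 0L) {
        out <- CharacterList(lapply(siteNames, function(i) character(0L)))
        names(out) <- siteNames
        return(out)
    }
    ## superset via maxgap, then filter on the exact edge distance
    h <- findOverlaps(tss, sites, maxgap = as.integer(window) + 1L,
                      ignore.strand = TRUE)
    pos <- start(tss)[S4Vectors::queryHits(h)]
    s <- start(sites)[S4Vectors::subjectHits(h)]
    e <- end(sites)[S4Vectors::subjectHits(h)]
    d <- pmax(s - pos, pos - e, 0L)
    keep <- d <= window
    out <- splitAsList(geneNames[S4Vectors::queryHits(h)][keep],
                       factor(siteNames[S4Vectors::subjectHits(h)][keep],
                              levels = siteNames))
    CharacterList(out)
}

#' Compare induction of nearby genes across accessibility classes
#'
#' Pools, per accessibility class, the expression log2 fold-changes of genes
#' near sites of that class and tests every class pair with a two-sided
#' Wilcoxon rank-sum test, Bonferroni-corrected over the pairs tested. A
#' class with fewer than 2 genes yields an undefined (NA) p-value for its
#' pairs, not an error.
#'
#' @param siteClasses named factor/character mapping site to accessibility
#'   class.
#' @param siteGenes mapping site to nearby genes, as returned by
#'   \code{\link{genesNearSites}}.
#' @param geneLog2fc named numeric vector of per-gene log2 fold-changes (or
#'   a data.frame with columns \code{gene}, \code{log2fc}); every referenced
#'   gene must be present.
#' @return A list with \code{summary} (per-class n, mean and median log2FC),
#'   \code{pairs} (per-pair Wilcoxon p and Bonferroni-adjusted p), and
#'   \code{values} (per-class numeric vectors).
#' @export
compareInductionByClass <- function(siteClasses, siteGenes, geneLog2fc) {
    if (is.data.frame(geneLog2fc))
        geneLog2fc <- structure(geneLog2fc$log2fc, names = geneLog2fc$gene)
    siteClasses <- structure(as.character(siteClasses),
                             names = names(siteClasses))
    stopifnot(!is.null(names(siteClasses)), !is.null(names(geneLog2fc)))
    classes <- intersect(ACCESSIBILITY_CLASSES, unique(siteClasses))
    values <- lapply(classes, function(cl) {
        genes <- unique(unlist(siteGenes[names(siteClasses)[
            siteClasses == cl]], use.names = FALSE))
        missing <- setdiff(genes, names(geneLog2fc))
        if (length(missing))
            stop("gene(s) absent from the log2FC table: ",
                 paste(utils::head(missing, 3L), collapse = ", "))
        unname(geneLog2fc[genes])
    })
    names(values) <- classes
    summary <- DataFrame(
        class = classes,
        n_genes = lengths(values),
        mean_log2fc = vapply(values, function(v)
            if (length(v)) mean(v) else NA_real_, numeric(1L)),
        median_log2fc = vapply(values, function(v)
            if (length(v)) stats::median(v) else NA_real_, numeric(1L)))
    if (length(classes) >= 2L) {
        cmb <- utils::combn(classes, 2L)
        p <- vapply(seq_len(ncol(cmb)), function(j) {
            a <- values[[cmb[1L, j]]]; b <- values[[cmb[2L, j]]]
            if (length(a) < 2L || length(b) < 2L) return(NA_real_)
            stats::wilcox.test(a, b, alternative = "two.sided",
                               exact = FALSE)$p.value
        }, numeric(1L))
        pairs <- DataFrame(class_a = cmb[1L, ], class_b = cmb[2L, ],
                           n_a = lengths(values)[cmb[1L, ]],
                           n_b = lengths(values)[cmb[2L, ]],
                           pvalue = p,
                           padj_bonferroni = pmin(1, p * sum(!is.na(p))))
    } else {
        pairs <- DataFrame(class_a = character(0L), class_b = character(0L),
                           n_a = integer(0L), n_b = integer(0L),
                           pvalue = numeric(0L),
                           padj_bonferroni = numeric(0L))
    }
    list(summary = summary, pairs = pairs, values = values)
}
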