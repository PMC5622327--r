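## Synthetic-data generators with known ground truth: toy genome and binding
## sites, MPRA reads with injected fold-changes, ATAC-like fragment
## intervals hitting class-specific FPKM targets, TF peak sets with
## controlled enrichment, and gene induction that depends on accessibility
## class. Every generator is deterministic for a given SimConfig.

#' SimConfig: parameters for the synthetic-data generators
#'
#' Houses every tunable of the simulation. Class proportions default to the
#' observed distribution of p53 binding sites across accessibility classes
#' (21.4/61.8/10.4/6.4 percent); MPRA counts are negative-binomial with
#' variance mu + dispersion * mu^2; ATAC FPKM targets default to values at
#' least 20 percent away from every classification threshold.
#'
#' @slot seed master integer seed; identical configs give identical output.
#' @slot genomeLength toy genome size (bases).
#' @slot gcFraction GC content of generated sequence, in [0, 1].
#' @slot nSites number of binding sites.
#' @slot siteWidth binding-site/accessibility-region width (bases).
#' @slot classMix named proportions over the four accessibility classes,
#'   summing to 1.
#' @slot mpraDepth expected reads per tag.
#' @slot nbDispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @slot injectedLog2fc named per-region log2 fold-changes; empty means the
#'   category defaults (endogenous 2, scrambled and random 0).
#' @slot fpkmTargets 4 x 2 matrix (class x untreated/treated) of FPKM
#'   targets.
#' @slot totalReads ATAC fragments per condition (summed over replicates).
#' @slot readWidth ATAC fragment width (bases).
#' @slot nReplicatesAtac ATAC replicates per condition.
#' @slot peakEnrichment named target enrichment ratio per TF.
#' @slot peaksPerFactor,peakWidth TF peak count per factor and width.
#' @slot classLog2fc named mean expression log2FC of genes near sites of
#'   each class.
#' @slot exprNoiseSd Gaussian noise sd on gene log2FC.
#' @slot tssWindow TSS proximity window (bases).
#' @slot mpraReadLength simulated MPRA read length (bases).
#' @exportClass SimConfig
setClass("SimConfig",
    representation(seed = "integer", genomeLength = "numeric",
                   gcFraction = "numeric", nSites = "integer",
                   siteWidth = "integer", classMix = "numeric",
                   mpraDepth = "numeric", nbDispersion = "numeric",
                   injectedLog2fc = "numeric", fpkmTargets = "matrix",
                   totalReads = "numeric", readWidth = "integer",
                   nReplicatesAtac = "integer", peakEnrichment = "numeric",
                   peaksPerFactor = "integer", peakWidth = "integer",
                   classLog2fc = "numeric", exprNoiseSd = "numeric",
                   tssWindow = "integer", mpraReadLength = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (abs(sum(object@classMix) - 1) > 1e-9)
        msg <- c(msg, "classMix must sum to 1 (within 1e-9)")
    if (!setequal(names(object@classMix), ACCESSIBILITY_CLASSES))
        msg <- c(msg, "classMix must be named by the four classes")
    if (any(object@classMix < 0)) msg <- c(msg, "classMix must be >= 0")
    if (object@gcFraction < 0 || object@gcFraction > 1)
        msg <- c(msg, "gcFraction must be in [0, 1]")
    pos <- c(genomeLength = object@genomeLength, nSites = object@nSites,
             siteWidth = object@siteWidth, mpraDepth = object@mpraDepth,
             totalReads = object@totalReads, readWidth = object@readWidth,
             nReplicatesAtac = object@nReplicatesAtac,
             peaksPerFactor = object@peaksPerFactor,
             peakWidth = object@peakWidth,
             mpraReadLength = object@mpraReadLength)
    if (any(pos <= 0))
        msg <- c(msg, paste("must be positive:",
                            paste(names(pos)[pos <= 0], collapse = ", ")))
    if (object@nbDispersion < 0) msg <- c(msg, "nbDispersion must be >= 0")
    ft <- object@fpkmTargets
    if (!all(ACCESSIBILITY_CLASSES %in% rownames(ft)) ||
        !identical(colnames(ft), c("untreated", "treated")))
        msg <- c(msg, paste("fpkmTargets must have the four classes as rows",
                            "and untreated/treated columns"))
    else if (any(ft < 0)) msg <- c(msg, "fpkmTargets must be >= 0")
    if (object@exprNoiseSd < 0) msg <- c(msg, "exprNoiseSd must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' @param seed master seed.
#' @param genomeLength,gcFraction,nSites,siteWidth toy-genome geometry.
#' @param classMix named accessibility-class proportions (sum 1).
#' @param mpraDepth,nbDispersion,injectedLog2fc,mpraReadLength MPRA
#'   simulation parameters.
#' @param fpkmTargets,totalReads,readWidth,nReplicatesAtac ATAC simulation
#'   parameters.
#' @param peakEnrichment,peaksPerFactor,peakWidth TF peak simulation
#'   parameters.
#' @param classLog2fc,exprNoiseSd,tssWindow expression-table parameters.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' simConfig(seed = 7, nSites = 40)
#' @export
simConfig <- function(seed = 1L,
                      genomeLength = 1e7, gcFraction = 0.41,
                      nSites = 200L, siteWidth = 10000L,
                      classMix = c(constitutively_accessible = 0.214,
                                   constitutively_inaccessible = 0.618,
                                   pioneering = 0.104,
                                   intermediate = 0.064),
                      mpraDepth = 1000, nbDispersion = 0.05,
                      injectedLog2fc = numeric(0L),
                      fpkmTargets = rbind(
                          constitutively_accessible = c(3, 4),
                          constitutively_inaccessible = c(0.4, 0.5),
                          pioneering = c(0.4, 3),
                          intermediate = c(0.5, 1.75)),
                      totalReads = 1e6, readWidth = 50L,
                      nReplicatesAtac = 3L,
                      peakEnrichment = c(TP53 = 5, SUZ12 = 4, CTBP2 = 4,
                                         ATF3 = 2, PRDM1 = 2, CTCF = 1,
                                         MAX = 1, REST = 1),
                      peaksPerFactor = 200L, peakWidth = 300L,
                      classLog2fc = c(constitutively_accessible = 1,
                                      constitutively_inaccessible = 0.2,
                                      pioneering = 2,
                                      intermediate = 0.8),
                      exprNoiseSd = 0.5, tssWindow = 2000L,
                      mpraReadLength = 50L) {
    if (is.null(colnames(fpkmTargets)))
        colnames(fpkmTargets) <- c("untreated", "treated")
    new("SimConfig", seed = as.integer(seed),
        genomeLength = genomeLength, gcFraction = gcFraction,
        nSites = as.integer(nSites), siteWidth = as.integer(siteWidth),
        classMix = classMix, mpraDepth = mpraDepth,
        nbDispersion = nbDispersion, injectedLog2fc = injectedLog2fc,
        fpkmTargets = fpkmTargets, totalReads = totalReads,
        readWidth = as.integer(readWidth),
        nReplicatesAtac = as.integer(nReplicatesAtac),
        peakEnrichment = peakEnrichment,
        peaksPerFactor = as.integer(peaksPerFactor),
        peakWidth = as.integer(peakWidth), classLog2fc = classLog2fc,
        exprNoiseSd = exprNoiseSd, tssWindow = as.integer(tssWindow),
        mpraReadLength = as.integer(mpraReadLength))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig (seed ", object@seed, "): genome ", object@genomeLength,
        " nt, ", object@nSites, " sites x ", object@siteWidth, " nt, ",
        "MPRA depth ", object@mpraDepth, ", NB dispersion ",
        object@nbDispersion, ", ATAC ", object@totalReads,
        " fragments/condition x ", object@nReplicatesAtac,
        " replicates\n", sep = "")
})

## Sub-seeds: each generator draws from its own deterministic stream so the
## generators are independently reproducible. Kept below 2^31.
.subSeed <- function(config, offset)
    (config@seed * 97L + offset) %% .Machine$integer.max

## ---------------------------------------------------------------------------
## Endogenous regions (toy p53-bound 95-mers)
## ---------------------------------------------------------------------------

#' Generate endogenous variable regions with embedded p53 motifs
#'
#' Random sequences at the configured GC fraction, each with a realised
#' (non-degenerate) p53 response element — two half sites drawn from the
#' model's degenerate decamer, spacer 0-3 — embedded at a random position.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param n number of regions.
#' @param length region length (default 95).
#' @param model the \linkS4class{P53MotifModel} realised.
#' @return data.frame with columns \code{region_id}, \code{sequence}.
#' @export
genEndogenousRegions <- function(config, n, length = 95L,
                                 model = p53MotifModel()) {
    stopifnot(is(config, "SimConfig"), n >= 1L)
    pat <- strsplit(model@halfSite, "")[[1L]]
    withSeed(.subSeed(config, 11L), {
        seqs <- vapply(seq_len(n), function(i) {
            half <- function() paste(vapply(pat, function(ch)
                sample(IUPAC_SETS[[ch]], 1L), character(1L)),
                collapse = "")
            spacer <- sample(0:3, 1L)
            motif <- paste0(half(),
                            if (spacer > 0L) randomDna(1L, spacer,
                                config@gcFraction) else "",
                            half())
            backbone <- randomDna(1L, length, config@gcFraction)
            at <- sample.int(length - nchar(motif) + 1L, 1L)
            paste0(substr(backbone, 1L, at - 1L), motif,
                   substr(backbone, at + nchar(motif), length))
        }, character(1L))
        data.frame(region_id = sprintf("site_%04d", seq_len(n)),
                   sequence = seqs)
    })
}

## ---------------------------------------------------------------------------
## MPRA reads
## ---------------------------------------------------------------------------

.injectedLfc <- function(config, regions) {
    lfc <- structure(rep(0, nrow(regions)), names = regions$region_id)
    if (length(config@injectedLog2fc)) {
        unknown <- setdiff(names(config@injectedLog2fc), names(lfc))
        if (length(unknown))
            stop("injectedLog2fc names not in library: ",
                 paste(utils::head(unknown, 3L), collapse = ", "))
        lfc[names(config@injectedLog2fc)] <- config@injectedLog2fc
    } else {
        lfc[regions$category == "endogenous"] <- 2
    }
    lfc
}

MPRA_SAMPLES <- c("input", "untreated_rep1", "untreated_rep2",
                  "treated_rep1", "treated_rep2")

#' Simulate per-tag MPRA counts
#'
#' Negative-binomial per-tag counts (variance mu + dispersion * mu^2) for
#' one plasmid-input sample and two RNA replicates per condition. The
#' expected count is \code{mpraDepth} for input and untreated samples and
#' \code{mpraDepth * 2^log2FC(region)} for treated samples, with log2FC
#' taken from \code{injectedLog2fc} (default: endogenous regions 2, all
#' others 0).
#'
#' @param config a \linkS4class{SimConfig}.
#' @param library an \linkS4class{MpraLibrary}.
#' @return List with \code{tagCounts} (integer matrix tags x samples),
#'   \code{truth} (data.frame \code{region_id}, \code{true_log2fc}) and
#'   \code{tag2region}.
#' @export
genMpraCounts <- function(config, library) {
    stopifnot(is(config, "SimConfig"), is(library, "MpraLibrary"))
    o <- libOligos(library)
    if (nrow(o) == 0L) stop("empty library")
    if (config@mpraDepth <= 0) stop("mpraDepth must be positive")
    regions <- as.data.frame(libRegions(library))
    lfc <- .injectedLfc(config, regions)
    muBase <- rep(config@mpraDepth, nrow(o))
    muTreat <- config@mpraDepth * 2^lfc[o$region_id]
    alpha <- config@nbDispersion
    draw <- function(mu) {
        if (alpha > 0) stats::rnbinom(length(mu), mu = mu, size = 1 / alpha)
        else stats::rpois(length(mu), mu)
    }
    withSeed(.subSeed(config, 23L), {
        m <- cbind(input = draw(muBase),
                   untreated_rep1 = draw(muBase),
                   untreated_rep2 = draw(muBase),
                   treated_rep1 = draw(muTreat),
                   treated_rep2 = draw(muTreat))
        rownames(m) <- o$tag
        storage.mode(m) <- "integer"
        list(tagCounts = m,
             truth = data.frame(region_id = regions$region_id,
                                true_log2fc = unname(lfc)),
             tag2region = structure(o$region_id, names = o$tag))
    })
}

#' Simulate targeted MPRA sequencing reads
#'
#' Draws per-tag counts with \code{\link{genMpraCounts}} and emits, for each
#' sample, reads of the form tag + reporter constant + random filler,
#' shuffled, as FASTQ when \code{dir} is given (files
#' \code{<sample>.fastq}) and always as in-memory \code{DNAStringSet}s.
#' Parsing the reads with \code{\link{countReads}} recovers the generator's
#' internal draws exactly.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param library an \linkS4class{MpraLibrary}.
#' @param reporter reporter constant placed after the tag.
#' @param dir optional output directory for FASTQ files.
#' @return List with \code{reads} (named list of \code{DNAStringSet}),
#'   \code{files} (FASTQ paths or NULL), \code{tagCounts}, \code{truth},
#'   \code{reporter}.
#' @export
genMpraDataset <- function(config, library, reporter = defaultReporter(),
                           dir = NULL) {
    sim <- genMpraCounts(config, library)
    tags <- rownames(sim$tagCounts)
    fillerLen <- max(0L, config@mpraReadLength - nchar(tags[1L]) -
                     nchar(reporter))
    reads <- withSeed(.subSeed(config, 29L), {
        lapply(stats::setNames(nm = colnames(sim$tagCounts)), function(smp) {
            n <- sim$tagCounts[, smp]
            x <- rep(paste0(tags, reporter), n)
            if (fillerLen > 0L)
                x <- paste0(x, randomDna(length(x), fillerLen,
                                         config@gcFraction))
            x <- x[sample.int(length(x))]
            out <- DNAStringSet(x)
            names(out) <- sprintf("%s_read_%06d", smp, seq_along(x))
            out
        })
    })
    files <- NULL
    if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        files <- vapply(names(reads), function(smp) {
            f <- file.path(dir, paste0(smp, ".fastq"))
            writeXStringSet(reads[[smp]], f, format = "fastq",
                            qualities = BStringSet(strrep("I",
                                width(reads[[smp]]))))
            f
        }, character(1L))
    }
    list(reads = reads, files = files, tagCounts = sim$tagCounts,
         truth = sim$truth, reporter = reporter)
}

## ---------------------------------------------------------------------------
## Toy binding sites and ATAC fragments
## ---------------------------------------------------------------------------

#' Generate non-overlapping binding sites with truth accessibility classes
#'
#' Places \code{nSites} sites of width \code{siteWidth} on the toy
#' chromosome (one site per equal-width bin, jittered within the bin, so
#' sites never overlap) and assigns accessibility classes in the configured
#' proportions.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return \code{GRanges} named \code{site_0001 ...} with metadata column
#'   \code{class}.
#' @export
genSites <- function(config) {
    stopifnot(is(config, "SimConfig"))
    n <- config@nSites; w <- config@siteWidth
    bin <- floor(config@genomeLength / n)
    if (bin < w) stop("genome too small for the requested sites")
    withSeed(.subSeed(config, 37L), {
        offs <- sample.int(bin - w + 1L, n, replace = TRUE) - 1L
        starts <- (seq_len(n) - 1L) * bin + offs + 1L
        ## class allocation: largest-remainder counts, shuffled assignment
        target <- config@classMix * n
        cnt <- floor(target)
        rem <- n - sum(cnt)
        if (rem > 0L) {
            extra <- order(target - cnt, decreasing = TRUE)[seq_len(rem)]
            cnt[extra] <- cnt[extra] + 1L
        }
        cls <- sample(rep(names(config@classMix), cnt))
        gr <- GRanges("chrT", IRanges(start = starts, width = w),
                      class = cls)
        names(gr) <- sprintf("site_%04d", seq_len(n))
        gr
    })
}

## sample n interval starts uniformly over a set of allowed gaps, fully
## inside a gap
.sampleStarts <- function(n, gapStart, gapEnd, readWidth) {
    room <- gapEnd - gapStart + 1L - readWidth + 1L
    ok <- room > 0L
    gapStart <- gapStart[ok]; room <- room[ok]
    if (!length(room)) stop("no room to place fragments")
    g <- sample.int(length(room), n, replace = TRUE, prob = room)
    gapStart[g] + floor(stats::runif(n) * room[g])
}

#' Simulate ATAC-like fragment intervals over the toy genome
#'
#' For every site, the pooled per-condition fragment count is fixed at
#' round(FPKM target x site length in kb x total fragments in millions), so
#' the realised pooled FPKM hits the class target up to rounding; fragment
#' positions are uniform within the site and fragments are assigned to
#' replicates at random. Background fragments fill the remainder of the
#' genome (entirely outside sites) so each condition totals
#' \code{totalReads} fragments.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param sites \code{GRanges} of non-overlapping sites; a \code{class}
#'   metadata column is used as truth (generated via \code{\link{genSites}}
#'   when absent).
#' @return List with \code{reads} (\code{GRangesList} named
#'   \code{<condition>_rep<i>}), \code{conditions} (named vector mapping
#'   replicate to condition), \code{sites}, and \code{classes} (named truth
#'   vector).
#' @export
genAtacDataset <- function(config, sites = genSites(config)) {
    stopifnot(is(config, "SimConfig"), is(sites, "GRanges"))
    if (is.null(mcols(sites)$class))
        stop("sites must carry a 'class' metadata column")
    cls <- as.character(mcols(sites)$class)
    miss <- setdiff(unique(cls), rownames(config@fpkmTargets))
    if (length(miss))
        stop("fpkmTargets missing class(es): ", paste(miss, collapse = ", "))
    if (any(start(sites) < 1L) || any(end(sites) > config@genomeLength))
        stop("sites must lie within the genome")
    red <- reduce(sites, ignore.strand = TRUE)
    if (length(red) != length(sites)) stop("sites must be non-overlapping")
    w <- config@readWidth
    nRep <- config@nReplicatesAtac
    ## background gaps (complement of sites)
    ord <- order(start(sites))
    gapStart <- c(1L, end(sites)[ord] + 1L)
    gapEnd <- c(start(sites)[ord] - 1L, as.integer(config@genomeLength))
    keep <- gapEnd - gapStart + 1L >= w
    withSeed(.subSeed(config, 41L), {
        reads <- list()
        conditions <- character(0L)
        for (cond in c("untreated", "treated")) {
            e <- config@fpkmTargets[cls, cond] * (width(sites) / 1000) *
                (config@totalReads / 1e6)
            nSite <- as.integer(round(e))
            nBg <- config@totalReads - sum(nSite)
            if (nBg < 0) stop("totalReads too small for the FPKM targets")
            siteStarts <- unlist(lapply(which(nSite > 0L), function(i) {
                start(sites)[i] +
                    floor(stats::runif(nSite[i]) *
                          (width(sites)[i] - w + 1L))
            }), use.names = FALSE)
            bgStarts <- .sampleStarts(nBg, gapStart[keep], gapEnd[keep], w)
            starts <- c(siteStarts, bgStarts)
            rep <- sample.int(nRep, length(starts), replace = TRUE)
            gr <- GRanges("chrT", IRanges(start = starts, width = w))
            for (r in seq_len(nRep)) {
                nm <- sprintf("%s_rep%d", cond, r)
                reads[[nm]] <- gr[rep == r]
                conditions[nm] <- cond
            }
        }
        list(reads = GRangesList(reads), conditions = conditions,
             sites = sites,
             classes = structure(cls, names = names(sites)))
    })
}

## ---------------------------------------------------------------------------
## TF peak sets
## ---------------------------------------------------------------------------

#' Simulate TF peak sets with controlled enrichment in pioneering intervals
#'
#' For each factor with target enrichment E, s = round(g x E x
#' pioneering_nt / genome_nt) of its g peaks are placed uniformly inside
#' pioneering intervals and the rest uniformly in the complement, so the
#' realised (s/S)/(g/G) statistic approximates E (exactly, up to rounding
#' and merge collisions). Requesting an enrichment that would need s > g is
#' an error.
#'
#' @param config a \linkS4class{SimConfig}; factors and targets come from
#'   \code{peakEnrichment}.
#' @param pioneering \code{GRanges} of pioneering intervals within the
#'   genome.
#' @return Named \code{GRangesList}, one sorted peak set per factor.
#' @export
genTfPeakDataset <- function(config, pioneering) {
    stopifnot(is(config, "SimConfig"), is(pioneering, "GRanges"),
              length(pioneering) > 0L)
    if (any(start(pioneering) < 1L) ||
        any(end(pioneering) > config@genomeLength))
        stop("pioneering intervals must lie within the genome")
    pio <- reduce(pioneering, ignore.strand = TRUE)
    pioNt <- sum(width(pio))
    g <- config@peaksPerFactor
    w <- config@peakWidth
    ord <- order(start(pio))
    gapStart <- c(1L, end(pio)[ord] + 1L)
    gapEnd <- c(start(pio)[ord] - 1L, as.integer(config@genomeLength))
    keepGap <- gapEnd - gapStart + 1L >= w
    withSeed(.subSeed(config, 53L), {
        out <- lapply(stats::setNames(nm = names(config@peakEnrichment)),
                      function(f) {
            E <- config@peakEnrichment[[f]]
            s <- as.integer(round(g * E * pioNt / config@genomeLength))
            if (s > g)
                stop("factor ", f, ": requested enrichment ", E,
                     " exceeds the maximum achievable with ", g, " peaks")
            inStarts <- if (s > 0L)
                .sampleStarts(s, start(pio), end(pio), w)
            else integer(0L)
            outStarts <- if (g - s > 0L)
                .sampleStarts(g - s, gapStart[keepGap], gapEnd[keepGap], w)
            else integer(0L)
            sort(GRanges("chrT", IRanges(start = c(inStarts, outStarts),
                                         width = w)))
        })
        GRangesList(out)
    })
}

## ---------------------------------------------------------------------------
## Gene expression
## ---------------------------------------------------------------------------

#' Generate TSS annotations around sites plus background genes
#'
#' One gene TSS inside each site (distance 0 to the site) and
#' \code{nBackground} background TSS placed in the complement at more than
#' \code{tssWindow} bases from every site.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param sites \code{GRanges} of binding sites.
#' @param nBackground number of background genes.
#' @return Width-1 \code{GRanges} named by gene.
#' @export
genTssAnnotation <- function(config, sites, nBackground = 100L) {
    stopifnot(is(config, "SimConfig"), is(sites, "GRanges"))
    wnd <- config@tssWindow
    ord <- order(start(sites))
    gapStart <- c(1L, end(sites)[ord] + 1L + wnd)
    gapEnd <- c(start(sites)[ord] - 1L - wnd,
                as.integer(config@genomeLength))
    keep <- gapEnd >= gapStart
    withSeed(.subSeed(config, 71L), {
        sitePos <- start(sites) +
            floor(stats::runif(length(sites)) * width(sites))
        bgPos <- if (nBackground > 0L)
            .sampleStarts(nBackground, gapStart[keep], gapEnd[keep], 1L)
        else integer(0L)
        gr <- GRanges("chrT", IRanges(start = c(sitePos, bgPos), width = 1L))
        names(gr) <- c(paste0("gene_", names(sites)),
                       sprintf("bg_gene_%04d", seq_len(nBackground)))
        gr
    })
}

#' Simulate a gene expression log2 fold-change table
#'
#' Genes whose TSS lies within \code{tssWindow} of a site receive that
#' site's class mean log2FC (\code{classLog2fc}) plus Gaussian noise
#' (\code{exprNoiseSd}); all other genes are centred at 0 with the same
#' noise. When a gene is near several sites the first such site (in site
#' order) supplies the class; with the default site spacing this is
#' effectively unique.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param sites \code{GRanges} of sites carrying a \code{class} metadata
#'   column.
#' @param tss width-1 \code{GRanges} named by gene.
#' @return data.frame with columns \code{gene}, \code{log2fc},
#'   \code{site_class} (NA for background genes).
#' @export
genExpressionTable <- function(config, sites, tss) {
    stopifnot(is(config, "SimConfig"), is(sites, "GRanges"),
              is(tss, "GRanges"), !is.null(names(tss)))
    if (is.null(mcols(sites)$class))
        stop("sites must carry a 'class' metadata column")
    near <- genesNearSites(sites, tss, window = config@tssWindow)
    geneClass <- structure(rep(NA_character_, length(tss)),
                           names = names(tss))
    siteNames <- names(sites)
    if (is.null(siteNames)) siteNames <- sprintf("site_%05d",
                                                 seq_along(sites))
    for (i in seq_along(near)) {
        cl <- as.character(mcols(sites)$class[i])
        for (gene in near[[i]]) {
            if (is.na(geneClass[gene])) geneClass[gene] <- cl
        }
    }
    withSeed(.subSeed(config, 83L), {
        mu <- ifelse(is.na(geneClass), 0,
                     config@classLog2fc[geneClass])
        lfc <- mu + stats::rnorm(length(mu), sd = config@exprNoiseSd)
        data.frame(gene = names(tss), log2fc = unname(lfc),
                   site_class = unname(geneClass))
    })
}
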