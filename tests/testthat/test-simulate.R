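test_that("config invariants are enforced", {
    expect_error(simConfig(classMix = c(constitutively_accessible = 0.5,
                                        constitutively_inaccessible = 0.4,
                                        pioneering = 0.2,
                                        intermediate = 0.1)),
                 "sum to 1")
    expect_error(simConfig(nbDispersion = -1), "nbDispersion")
    expect_error(simConfig(totalReads = 0), "positive")
    expect_error(simConfig(gcFraction = 1.2), "gcFraction")
})

test_that("identical configs reproduce byte-identical outputs", {
    lib <- fixLibrary()
    mk <- function() {
        cfg <- simConfig(seed = 55L, mpraDepth = 30)
        d <- tempfile()
        sim <- genMpraDataset(cfg, lib, dir = d)
        atacCfg <- fixAtacConfig(seed = 55L)
        atac <- genAtacDataset(atacCfg)
        pk <- genTfPeakDataset(atacCfg,
                               atac$sites[atac$classes == "pioneering"])
        list(fastq = lapply(sim$files, readLines),
             counts = sim$tagCounts, atac = atac$reads, peaks = pk)
    }
    a <- mk(); b <- mk()
    expect_identical(a$fastq, b$fastq)
    expect_identical(a$counts, b$counts)
    expect_identical(a$atac, b$atac)
    expect_identical(a$peaks, b$peaks)
})

test_that("simulated counts match NB moments within 5% at 1e5 draws", {
    regs <- genEndogenousRegions(simConfig(seed = 56), n = 2)
    lib <- buildLibrary(regs, nRandom = 0, tagsPerRegion = 250, seed = 56)
    ## pool the null samples (input + untreated) across repeated draws
    draws <- unlist(lapply(1:34, function(i) {
        genMpraCounts(simConfig(seed = i, mpraDepth = 500,
                                nbDispersion = 0.1),
                      lib)$tagCounts[, c("input", "untreated_rep1",
                                         "untreated_rep2")]
    }))
    expect_gte(length(draws), 1e5)
    mu <- 500; alpha <- 0.1
    expect_lt(abs(mean(draws) - mu) / mu, 0.05)
    expect_lt(abs(var(draws) - (mu + alpha * mu^2)) / (mu + alpha * mu^2),
              0.05)
})

test_that("null injection gives balanced conditions; log2FC 2 scales counts", {
    lib <- fixLibrary()
    ids <- libRegions(lib)$region_id
    nullCfg <- simConfig(seed = 58, mpraDepth = 1000,
                         injectedLog2fc = structure(rep(0, length(ids)),
                                                    names = ids))
    sim <- genMpraCounts(nullCfg, lib)
    u <- rowSums(sim$tagCounts[, c("untreated_rep1", "untreated_rep2")])
    t <- rowSums(sim$tagCounts[, c("treated_rep1", "treated_rep2")])
    expect_lt(abs(mean(log(t / u))), 0.05)

    hotCfg <- simConfig(seed = 59, mpraDepth = 1000,
                        injectedLog2fc = structure(
                            rep(2, length(ids)), names = ids))
    sim2 <- genMpraCounts(hotCfg, lib)
    ratio <- mean(rowMeans(sim2$tagCounts[, c("treated_rep1",
                                              "treated_rep2")])) /
        mean(rowMeans(sim2$tagCounts[, c("untreated_rep1",
                                         "untreated_rep2")]))
    expect_gt(ratio, 3.2)
    expect_lt(ratio, 5.0)
})

test_that("generator rejects empty libraries and bad depths", {
    lib <- fixLibrary()
    expect_error(genMpraCounts(simConfig(mpraDepth = -5), lib), "positive")
    expect_error(simConfig(injectedLog2fc = c(nope = 1)) |>
                     genMpraCounts(lib), "not in library")
})

test_that("ATAC reads stay in bounds and hit the FPKM targets", {
    cfg <- simConfig(seed = 60, nSites = 30, genomeLength = 2e6,
                     siteWidth = 10000, totalReads = 1e6)
    atac <- genAtacDataset(cfg)
    all <- unlist(atac$reads)
    expect_true(all(start(all) >= 1))
    expect_true(all(end(all) <= 2e6))
    expect_equal(sum(atac$conditions == "untreated"), 3L)
    perCond <- tapply(lengths(atac$reads), atac$conditions, sum)
    expect_equal(as.numeric(perCond), c(1e6, 1e6))

    ## pioneering targets (0.4, 3.0) realised within 25%
    u <- regionFpkm(atac$reads[atac$conditions == "untreated"], atac$sites)
    t <- regionFpkm(atac$reads[atac$conditions == "treated"], atac$sites)
    pio <- atac$classes == "pioneering"
    expect_true(all(abs(u[pio] - 0.4) / 0.4 <= 0.25))
    expect_true(all(abs(t[pio] - 3.0) / 3.0 <= 0.25))
})

test_that("ATAC generation fails cleanly on missing classes", {
    cfg <- fixAtacConfig()
    sites <- genSites(cfg)
    mcols(sites)$class[1] <- "mystery"
    expect_error(genAtacDataset(cfg, sites), "missing class")
})

test_that("downstream classification recovers the truth classes exactly", {
    atac <- fixAtac()
    u <- regionFpkm(atac$reads[atac$conditions == "untreated"], atac$sites)
    t <- regionFpkm(atac$reads[atac$conditions == "treated"], atac$sites)
    cls <- classifyAccessibility(u, t)
    expect_equal(as.character(cls), unname(atac$classes))
})

test_that("TF peak placement approximates the requested enrichment", {
    cfg <- simConfig(seed = 61, nSites = 50, genomeLength = 5e6,
                     siteWidth = 10000,
                     peakEnrichment = c(null = 1, strong = 5),
                     peaksPerFactor = 200)
    sites <- genSites(cfg)
    pio <- sites[mcols(sites)$class == "pioneering"]
    pk <- genTfPeakDataset(cfg, pio)
    res <- tfEnrichment(pk, pio, cfg@genomeLength)
    eNull <- res$enrichment[res$factor == "null"]
    eStrong <- res$enrichment[res$factor == "strong"]
    expect_gte(eNull, 0.7); expect_lte(eNull, 1.4)
    expect_lt(abs(eStrong - 5) / 5, 0.3)
    ## unreachable enrichment errors
    cfgBad <- simConfig(seed = 61, nSites = 50, genomeLength = 5e6,
                        siteWidth = 10000,
                        peakEnrichment = c(big = 500),
                        peaksPerFactor = 200)
    expect_error(genTfPeakDataset(cfgBad, pio), "exceeds")
})

test_that("peak sets are valid sorted half-open BED intervals", {
    cfg <- fixAtacConfig()
    atac <- fixAtac()
    pk <- genTfPeakDataset(cfg, atac$sites[atac$classes == "pioneering"])
    f <- tempfile(fileext = ".bed")
    writeIntervalsBed(pk[["TP53"]], f)
    raw <- read.table(f, sep = "\t")
    expect_true(all(raw$V2 < raw$V3))         # half-open, start < end
    expect_true(all(raw$V2 >= 0))
    expect_false(is.unsorted(raw$V2))
    back <- readIntervalsBed(f)
    expect_equal(start(back), start(pk[["TP53"]]))
    expect_equal(width(back), width(pk[["TP53"]]))
})

test_that("zero-noise expression tables are exactly the class means", {
    cfg <- simConfig(seed = 62, nSites = 40, genomeLength = 2e6,
                     siteWidth = 10000, exprNoiseSd = 0)
    sites <- genSites(cfg)
    tss <- genTssAnnotation(cfg, sites, nBackground = 10)
    expr <- genExpressionTable(cfg, sites, tss)
    nearPio <- expr$site_class %in% "pioneering"
    expect_true(all(expr$log2fc[nearPio] == 2))
    bg <- is.na(expr$site_class)
    expect_true(all(expr$log2fc[bg] == 0))
    ## determinism
    expr2 <- genExpressionTable(cfg, sites, tss)
    expect_identical(expr, expr2)
})
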