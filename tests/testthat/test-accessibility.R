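test_that("FPKM matches its unit definition and handles empty overlap", {
    region <- GRanges("chr1", IRanges(1001, 2000))  # 1 kb
    reads <- c(GRanges("chr1", IRanges(1500, 1549)),
               GRanges("chr1", IRanges(rep(5000, 999999),
                                       width = 50)))
    expect_equal(unname(regionFpkm(reads, region)), 1.0)
    far <- GRanges("chr1", IRanges(rep(5000, 100), width = 50))
    expect_equal(unname(regionFpkm(far, region)), 0)
    expect_error(regionFpkm(GRanges(), region), "zero total")
})

test_that("FPKM agrees with a brute-force per-fragment overlap oracle", {
    set.seed(31)
    regions <- GRanges("chr1", IRanges(start = c(100, 900, 5000),
                                       width = c(500, 300, 1000)))
    starts <- sample.int(8000, 2000, replace = TRUE)
    reads <- GRanges("chr1", IRanges(starts, width = 50))
    got <- regionFpkm(reads, regions)
    ## oracle: count overlaps fragment by fragment
    cnt <- sapply(seq_along(regions), function(i) {
        s <- start(regions)[i]; e <- end(regions)[i]
        sum(starts <= e & (starts + 49) >= s)
    })
    expect_equal(unname(got),
                 cnt / (width(regions) / 1000 * length(reads) / 1e6))
})

test_that("FPKM is linear in fragments and inverse in library size", {
    region <- GRanges("chr1", IRanges(1, 1000))
    inside <- GRanges("chr1", IRanges(rep(10, 20), width = 50))
    outside <- GRanges("chr1", IRanges(rep(9000, 980), width = 50))
    f1 <- regionFpkm(c(inside, outside), region)
    f2 <- regionFpkm(c(inside, inside, outside), region)  # double hits
    expect_equal(unname(f2 / f1), 2 * 1000 / 1020, tolerance = 1e-12)
    f3 <- regionFpkm(c(inside, outside, outside), region)
    expect_equal(unname(f3 / f1), 1000 / 1980, tolerance = 1e-12)
})

test_that("replicate pooling sums reads before normalisation", {
    region <- GRanges("chr1", IRanges(1, 1000))
    repA <- GRanges("chr1", IRanges(rep(10, 4), width = 50))
    repB <- GRanges("chr1", IRanges(rep(2000, 96), width = 50))
    pooled <- regionFpkm(GRangesList(a = repA, b = repB), region)
    expect_equal(unname(pooled), 4 / (1 * 100 / 1e6))
    perRep <- regionFpkm(GRangesList(a = repA, b = repB), region,
                         pooling = "mean")
    expect_equal(unname(perRep), mean(c(4 / (4 / 1e6), 0)))
})

test_that("the printed threshold rules classify the worked examples", {
    u <- c(0.5, 0.5, 0.5, 1.5)
    t <- c(3.0, 0.8, 1.7, 2.5)
    expect_equal(as.character(classifyAccessibility(u, t)),
                 c("pioneering", "constitutively_inaccessible",
                   "intermediate", "constitutively_accessible"))
    ## boundary values fail every strict rule and fall to the catch-all
    expect_equal(as.character(classifyAccessibility(1.0, 1.0)),
                 "intermediate")
    expect_equal(as.character(classifyAccessibility(1.0, 3.0)),
                 "intermediate")
    expect_equal(as.character(classifyAccessibility(0.5, 2.0)),
                 "intermediate")
    expect_error(classifyAccessibility(-1, 2), "non-negative")
})

test_that("classification is a total partition on fuzzed inputs", {
    set.seed(32)
    u <- c(runif(500, 0, 4), 0, 1, 1.5, 2)
    t <- c(runif(504, 0, 4))
    cls <- classifyAccessibility(u, t)
    expect_false(any(is.na(cls)))
    expect_equal(sum(table(cls)), length(u))
})

test_that("raising treated FPKM moves low-untreated regions forward only", {
    grid <- seq(0, 4, by = 0.01)
    cls <- as.character(classifyAccessibility(rep(0.5, length(grid)), grid))
    rank <- c(constitutively_inaccessible = 1L, intermediate = 2L,
              pioneering = 3L)
    expect_true(all(diff(rank[cls]) >= 0L))
})

test_that("accessible sites subclassify by the 2-fold rule", {
    expect_equal(as.character(subclassifyAccessible(
        c(1.5, 2.0, 4.0), c(4.0, 3.0, 1.5))),
        c("increased", "unchanged", "decreased"))
    ## exactly 2-fold is not > 2-fold
    expect_equal(as.character(subclassifyAccessible(1.5, 3.0)), "unchanged")
    expect_error(subclassifyAccessible(0, 3), "positive")
})

test_that("TSS proximity respects the 2 kb window boundary exactly", {
    site <- GRanges("chr1", IRanges(10000, 11000))
    names(site) <- "s1"
    tss <- GRanges("chr1", IRanges(c(11000 + 1999, 11000 + 2000,
                                     11000 + 2001, 10500,
                                     10000 - 2000, 10000 - 2001),
                                   width = 1))
    names(tss) <- paste0("g", 1:6)
    got <- genesNearSites(site, tss, window = 2000)
    expect_setequal(got[["s1"]], c("g1", "g2", "g4", "g5"))
    ## containment at window 0
    expect_equal(genesNearSites(site, tss, window = 0)[["s1"]], "g4")
})

test_that("TSS proximity agrees with an all-pairs distance oracle", {
    set.seed(33)
    sites <- GRanges("chr1", IRanges(sort(sample.int(900000, 30)) * 10,
                                     width = 800))
    names(sites) <- sprintf("s%02d", 1:30)
    tss <- GRanges("chr1", IRanges(sample.int(9.2e6, 400), width = 1))
    names(tss) <- sprintf("g%03d", 1:400)
    got <- genesNearSites(sites, tss, window = 2000)
    for (i in seq_along(sites)) {
        d <- pmax(start(sites)[i] - start(tss),
                  start(tss) - end(sites)[i], 0L)
        expect_setequal(got[[i]], names(tss)[d <= 2000])
    }
    ## a gene may map to multiple sites
    expect_gte(max(table(unlist(got))), 1L)
})

test_that("induction comparison detects a configured class effect", {
    cfg <- fixAtacConfig()
    atac <- fixAtac()
    tss <- genTssAnnotation(cfg, atac$sites, nBackground = 50)
    expr <- genExpressionTable(cfg, atac$sites, tss)
    near <- genesNearSites(atac$sites, tss, window = 2000)
    cmp <- compareInductionByClass(atac$classes, near, expr)
    s <- as.data.frame(cmp$summary)
    expect_setequal(s$class, unique(atac$classes))
    pioAcc <- as.data.frame(cmp$pairs)
    row <- pioAcc[(pioAcc$class_a == "pioneering" &
                   pioAcc$class_b == "constitutively_accessible") |
                  (pioAcc$class_b == "pioneering" &
                   pioAcc$class_a == "constitutively_accessible"), ]
    expect_equal(nrow(row), 1L)
    ## configured means: pioneering 2.0 vs accessible 1.0, sd 0.5
    expect_gt(s$mean_log2fc[s$class == "pioneering"],
              s$mean_log2fc[s$class == "constitutively_accessible"])
})

test_that("null induction comparison shows no systematic significance", {
    set.seed(34)
    classes <- structure(rep(c("pioneering", "constitutively_accessible",
                               "constitutively_inaccessible"), each = 10),
                         names = sprintf("s%02d", 1:30))
    genes <- split(sprintf("g%03d", 1:300),
                   rep(sprintf("s%02d", 1:30), each = 10))
    lfc <- structure(rnorm(300), names = sprintf("g%03d", 1:300))
    cmp <- compareInductionByClass(classes, genes, lfc)
    expect_true(all(as.data.frame(cmp$pairs)$padj_bonferroni > 0.05))
})

test_that("a single-gene class yields an undefined p, not an error", {
    classes <- c(s1 = "pioneering", s2 = "constitutively_accessible")
    genes <- list(s1 = "g1", s2 = c("g2", "g3", "g4"))
    lfc <- c(g1 = 2, g2 = 0.1, g3 = 0.2, g4 = 0.3)
    cmp <- compareInductionByClass(classes, genes, lfc)
    expect_true(is.na(as.data.frame(cmp$pairs)$pvalue))
    expect_error(compareInductionByClass(classes, genes, lfc[-1]),
                 "absent")
})
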