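toyEnrichment <- function() {
    ## genome 10 kb; pioneering covers 1 kb; 10 peaks of 50 nt (500 nt
    ## total coverage), 5 overlapping the pioneering interval
    pio <- GRanges("chr1", IRanges(1, 1000))
    inside <- GRanges("chr1", IRanges(seq(1, 801, by = 200), width = 50))
    outside <- GRanges("chr1", IRanges(seq(2000, 9200, by = 1800),
                                       width = 50))
    list(peaks = GRangesList(tf = c(inside, outside)), pio = pio,
         genomeNt = 10000)
}

test_that("the enrichment statistic reproduces the hand-computed toy", {
    toy <- toyEnrichment()
    res <- tfEnrichment(toy$peaks, toy$pio, toy$genomeNt)
    expect_equal(res$s, 5L)
    expect_equal(res$g, 10L)
    expect_equal(res$peak_nt, 500)
    expect_equal(res$S, 2)    # 1000 / 500
    expect_equal(res$G, 20)   # 10000 / 500
    expect_equal(res$enrichment, 5.0)  # (5/2)/(10/20)
})

test_that("zero overlap gives zero enrichment; proportional overlap gives 1", {
    pio <- GRanges("chr1", IRanges(1, 1000))
    far <- GRangesList(tf = GRanges("chr1", IRanges(seq(3000, 9000, 1000),
                                                    width = 50)))
    expect_equal(tfEnrichment(far, pio, 1e4)$enrichment, 0)
    ## s/g = pioneering_nt/genome_nt => enrichment exactly 1
    mix <- GRangesList(tf = GRanges("chr1",
        IRanges(c(100, seq(2000, 9800, length.out = 9)), width = 20)))
    expect_equal(tfEnrichment(mix, pio, 1e4)$enrichment, 1.0)
    expect_error(tfEnrichment(far, GRanges(), 1e4), "empty pioneering")
})

test_that("the cancellation identity holds to 1e-12 on random instances", {
    set.seed(41)
    for (i in 1:1000) {
        genomeNt <- sample(5e4:2e5, 1)
        pio <- reduce(GRanges("chr1",
            IRanges(sample.int(genomeNt - 500, sample(2:8, 1)),
                    width = sample(100:400, 1))))
        pk <- GRanges("chr1", IRanges(sample.int(genomeNt - 100,
                                                 sample(5:40, 1)),
                                      width = sample(20:80, 1)))
        res <- tfEnrichment(GRangesList(tf = pk), pio, genomeNt)
        lhs <- res$enrichment
        rhs <- (res$s / res$g) * (genomeNt / res$pioneering_nt)
        expect_lt(abs(lhs - rhs), 1e-12 * max(1, abs(rhs)))
    }
})

test_that("permutation p-values respect the add-one estimator bounds", {
    cfg <- fixAtacConfig()
    atac <- fixAtac()
    pio <- atac$sites[atac$classes == "pioneering"]
    pk <- genTfPeakDataset(cfg, pio)
    res <- permutationSignificance(pk, pio, cfg@genomeLength,
                                   nShuffles = 100, seed = 5)
    expect_true(all(res$perm_p >= 1 / 101 & res$perm_p <= 1))
    expect_true(all(res$adjusted_p >= res$perm_p))
    ## the factor placed at enrichment 5 beats all shuffles
    expect_equal(res$perm_p[res$factor == "TP53"], 1 / 101)
    ## determinism
    res2 <- permutationSignificance(pk, pio, cfg@genomeLength,
                                    nShuffles = 100, seed = 5)
    expect_identical(res$perm_p, res2$perm_p)
    expect_error(permutationSignificance(pk[1], pio, cfg@genomeLength),
                 "single factor")
})

test_that("permutation p-values are near-uniform under a pooled null", {
    ## 50 factors drawn from one pool per run: no factor is genuinely
    ## enriched. 500 peaks/factor keeps the overlap counts off the
    ## heavily tied small-count regime; p-values are pooled over three
    ## independent runs before the KS comparison.
    genomeNt <- 1e6
    pio <- GRanges("chr1", IRanges(seq(1, 9e5, length.out = 20),
                                   width = 5000))
    nullRun <- function(seed) {
        set.seed(seed)
        pool <- lapply(1:50, function(i)
            GRanges("chr1", IRanges(sample.int(genomeNt - 200, 500),
                                    width = 150)))
        names(pool) <- sprintf("f%02d", 1:50)
        permutationSignificance(GRangesList(pool), pio, genomeNt,
                                nShuffles = 100, seed = seed + 1)$perm_p
    }
    p <- c(nullRun(6), nullRun(7), nullRun(8))
    ks <- suppressWarnings(ks.test(p, "punif"))$statistic
    expect_lt(unname(ks), 0.15)
})

test_that("hypergeometric co-occurrence matches the enumerated example", {
    res <- cooccurrenceSignificance(list(a = 1:5, b = c(1, 2, 3, 4)),
                                    nTotal = 10)
    expect_equal(res$k_both, 4L)
    expect_equal(res$hyper_p, 5 / 210)  # C(5,4) C(5,0) / C(10,4)
    ## k_both = 0 gives the full tail: P(X >= 0) = 1
    res0 <- cooccurrenceSignificance(list(a = 1:3, b = 4:6), nTotal = 20)
    expect_equal(res0$hyper_p, 1)
    resEmpty <- cooccurrenceSignificance(list(a = integer(0), b = 1:4),
                                         nTotal = 10)
    expect_equal(resEmpty$hyper_p, 1)
})

test_that("co-occurrence matches a brute-force subset-enumeration oracle", {
    ## P(X >= k_both) by enumerating all placements of factor b's sites
    ## given factor a's, for n_total <= 12
    oracle <- function(nTotal, kA, kB, kBoth) {
        sets <- combn(nTotal, kB)
        mean(apply(sets, 2, function(s) sum(s <= kA) >= kBoth))
    }
    set.seed(43)
    for (i in 1:25) {
        nTotal <- sample(4:12, 1)
        kA <- sample(0:nTotal, 1)
        kB <- sample(1:nTotal, 1)
        a <- seq_len(kA)
        b <- sample.int(nTotal, kB)
        res <- cooccurrenceSignificance(list(a = a, b = b), nTotal)
        expect_equal(res$hyper_p,
                     oracle(nTotal, kA, kB, res$k_both),
                     tolerance = 1e-12)
    }
})

test_that("co-occurrence p is symmetric in the pair and Bonferroni-bounded", {
    sets <- list(a = 1:6, b = c(2, 3, 9, 10), c = c(1, 2, 3))
    res <- cooccurrenceSignificance(sets, nTotal = 12)
    swapped <- cooccurrenceSignificance(rev(sets), nTotal = 12)
    key <- function(d) {
        k <- apply(cbind(d$factor_a, d$factor_b), 1,
                   function(r) paste(sort(r), collapse = "-"))
        structure(d$hyper_p, names = k)
    }
    a <- key(as.data.frame(res)); b <- key(as.data.frame(swapped))
    expect_equal(a[sort(names(a))], b[sort(names(b))])
    expect_true(all(res$adjusted_p >= res$hyper_p))
    expect_true(all(res$adjusted_p <= 1))
})
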