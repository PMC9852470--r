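test_that("binomial tail matches independent enumeration and edge cases", {
    expect_identical(binomialPValue(50L, 0L, 0.05), 1)
    expect_identical(binomialPValue(50L, 5L, 0), 0)
    expect_equal(binomialPValue(20L, 10L, 0.05),
                 oracleBinomTail(20, 10, 0.05), tolerance = 1e-12)
    for (p0 in c(0.001, 0.05, 0.5)) {
        for (N in c(1L, 7L, 50L)) {
            for (Nmm in unique(c(0L, 1L, N %/% 2L, N))) {
                expect_equal(binomialPValue(N, Nmm, p0),
                             oracleBinomTail(N, Nmm, p0),
                             tolerance = 1e-12)
            }
        }
    }
    expect_error(binomialPValue(10L, 11L, 0.1), "Nmm")
    expect_error(binomialPValue(10L, 2L, 1.2), "p0")
})

test_that("binomial tail is monotone in Nmm and p0 and stable at depth 1e6", {
    N <- 100L
    p <- binomialPValue(rep(N, N + 1L), 0:N, 0.05)
    expect_true(all(diff(p) <= 0))
    grid <- c(0.001, 0.01, 0.05, 0.1, 0.5)
    p <- binomialPValue(rep(N, 5L), rep(20L, 5L), grid)
    expect_true(all(diff(p) >= 0))
    big <- binomialPValue(1e6L, 30000L, 0.0264)
    expect_true(is.finite(big) && big >= 0 && big <= 1)
})

test_that("consensus requires the quorum of replicates at p <= 0.01", {
    # 3 replicates, counts chosen so the per-replicate p-values straddle
    # the cutoffs; p0 = 0.0264 throughout
    p0 <- 0.0264
    d <- matrix(50L, 1L, 3L)
    # two replicates clearly significant, one null
    nC <- matrix(c(8L, 8L, 1L), 1L)
    ps <- binomialPValue(d[1, ], nC[1, ], p0)
    expect_true(ps[1] <= 0.01 && ps[3] > 0.01)
    r <- callSites(d, nC, p0)
    expect_true(r$consensus)
    # only one replicate significant: no consensus
    r <- callSites(d, matrix(c(12L, 1L, 1L), 1L), p0)
    expect_false(r$consensus)
    expect_equal(r$tier, "not_significant")
    # all replicates extreme: highly significant
    r <- callSites(d, matrix(c(15L, 15L, 15L), 1L), p0)
    expect_equal(r$tier, "highly_significant")
    # two replicates in (0.001, 0.01], third null: significant tier only
    nC <- matrix(c(6L, 6L, 1L), 1L)
    ps <- binomialPValue(50L, 6L, p0)
    expect_true(ps > 0.001 && ps <= 0.01)
    r <- callSites(d, nC, p0)
    expect_equal(r$tier, "significant")
})

test_that("coverage threshold and SNP flags gate eligibility", {
    p0 <- 0.0264
    # replicate depths (7, 7, 6): ineligible
    r <- callSites(matrix(c(7L, 7L, 6L), 1L), matrix(c(7L, 7L, 6L), 1L),
                   p0)
    expect_false(r$consensus)
    expect_equal(r$reason, "low_coverage")
    # exactly 7 in every replicate is eligible
    r <- callSites(matrix(7L, 1L, 3L), matrix(7L, 1L, 3L), p0)
    expect_true(r$consensus)
    # SNP-flagged sites are never consensus
    r <- callSites(matrix(50L, 1L, 3L), matrix(25L, 1L, 3L), p0,
                   snp = TRUE)
    expect_false(r$consensus)
    expect_equal(r$reason, "snp")
})

test_that("quorum scales with the replicate count", {
    p0 <- 0.0264
    sig <- 12L; null <- 1L
    # R = 2 -> 2-of-2
    expect_false(callSites(matrix(50L, 1, 2),
                           matrix(c(sig, null), 1), p0)$consensus)
    expect_true(callSites(matrix(50L, 1, 2),
                          matrix(c(sig, sig), 1), p0)$consensus)
    # R = 1 -> 1-of-1
    expect_true(callSites(matrix(50L, 1, 1),
                          matrix(sig, 1), p0)$consensus)
    # calling is invariant to replicate order
    a <- callSites(matrix(50L, 1, 3), matrix(c(12L, 8L, 1L), 1), p0)
    b <- callSites(matrix(50L, 1, 3), matrix(c(1L, 12L, 8L), 1), p0)
    expect_equal(a$consensus, b$consensus)
    expect_equal(a$tier, b$tier)
    expect_equal(sort(a$pvalues[1, ]), sort(b$pvalues[1, ]))
})

test_that("transcriptome-wide detection finds planted sites and writes
           consistent outputs", {
    cfg <- simulationConfig(seed = 21, nTranscripts = 4, coverage = 40,
        truthSites = data.frame(transcript = c(1, 2), txpos = c(150, 200),
                                occupancy = 1, efficiency = 0.7))
    sim <- simulateExperiment(cfg)
    direct <- lapply(1:3, function(r)
        buildCountTable(sim$directSams[r], sim$fasta, label = "direct",
                        replicate = paste0("rep", r)))
    ivt <- lapply(1:2, function(r)
        buildCountTable(sim$ivtSams[r], sim$fasta, label = "ivt",
                        replicate = paste0("rep", r)))
    res <- detectModifications(direct, ivt, sim$fasta)
    cl <- modCalls(res)
    key <- paste(cl$contig, cl$pos, cl$strand)
    tkey <- paste(sim$truth$contig, sim$truth$pos, sim$truth$strand)
    hit <- key %in% tkey
    expect_equal(sum(hit), 2L)
    expect_true(all(cl$tier[hit] == "highly_significant"))
    # planted occupancy 1, efficiency 0.7: mismatch near 0.71
    expect_true(all(abs(cl$merged_mismatch[hit] - 0.71) < 0.15))
    # raising the coverage threshold never adds a called site
    res60 <- detectModifications(direct, ivt, sim$fasta, minDepth = 60L)
    expect_true(all(modCalls(res60)$consensus <= cl$consensus[
        match(paste(modCalls(res60)$contig, modCalls(res60)$pos,
                    modCalls(res60)$strand), key)]))
    # manifest records the tested universe
    expect_equal(manifest(res)$n_tested_sites, nrow(cl))
    # output files round-trip
    pre <- file.path(tempfile("out_"))
    dir.create(dirname(pre), showWarnings = FALSE, recursive = TRUE)
    files <- writeModCalls(res, pre)
    tsv <- read.delim(paste0(pre, "_calls.tsv"))
    expect_equal(nrow(tsv), nrow(cl))
    expect_true(all(c("p_rep1", "p_rep2", "p_rep3", "tier", "p0")
                    %in% colnames(tsv)))
    bed <- read.delim(paste0(pre, ".bed"), header = FALSE)
    expect_equal(nrow(bed), sum(cl$consensus))
    expect_true(all(bed$V3 == bed$V2 + 1L))
})

test_that("empty direct/IVT overlap yields an empty call set", {
    fx <- writeFixture(c(c1 = "CCATTGACCCATTGACC"), character(0))
    d <- makeCountTable("c1", 4L, "+", 30L, 2L)
    i <- makeCountTable("c1", 12L, "+", 30L, 1L, label = "ivt")
    res <- detectModifications(list(d), list(i), fx$fasta)
    cl <- modCalls(res)
    # the direct site is tested but ineligible (no IVT coverage there)
    expect_false(any(cl$consensus))
    expect_true(all(cl$reason == "low_coverage"))
})
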