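# chrP: T at 1-based 6 and 24; chrM: single A (minus-strand U) at 6
chrP <- "AAAAATAAAAACAAAAAGAAAAATAAAAAA"
chrM <- "CCCCCACCCCCC"

test_that("read-level filter keeps only primary alignments with MAPQ >= 20", {
    expect_false(filterAlignment(0L, 19L))
    expect_false(filterAlignment(256L, 60L))   # secondary
    expect_false(filterAlignment(2048L, 60L))  # supplementary
    expect_false(filterAlignment(4L, 60L))     # unmapped
    expect_true(filterAlignment(0L, 60L))
    expect_true(filterAlignment(16L, 20L))     # boundary is inclusive
    expect_equal(filterAlignment(c(0L, 256L, 0L), c(60L, 60L, 19L)),
                 c(TRUE, FALSE, FALSE))
})

test_that("clip-adjacent mask covers the first/last aligned bases", {
    pos <- 101:150
    expect_equal(maskClipAdjacent(pos, 5L, 0L), c(101L, 102L, 103L))
    expect_equal(maskClipAdjacent(pos, 0L, 2L), c(148L, 149L, 150L))
    expect_length(maskClipAdjacent(pos, 0L, 0L), 0L)
    # degenerate short read: mask truncates at the read length
    expect_equal(sort(maskClipAdjacent(c(7L, 8L), 2L, 0L, 3L)), c(7L, 8L))
})

test_that("plus-strand tally: 4 C calls among 10 reads gives 0.4", {
    seqs <- rep(chrP, 10)
    substr(seqs[1:4], 6, 6) <- "C"
    recs <- vapply(1:10, function(i)
        samRecord(paste0("r", i), 0L, "chrP", 1L, 60L, "30M", seqs[i]),
        character(1))
    fx <- writeFixture(c(chrP = chrP), recs)
    ct <- buildCountTable(fx$sam, fx$fasta, label = "direct")
    s <- as.data.frame(siteCounts(ct))
    site <- s[s$pos == 5L, ]
    expect_equal(site$depth, 10L)
    expect_equal(site$nC, 4L)
    expect_equal(site$nU, 6L)
    expect_equal(site$mismatch_frac, 0.4)
    # the all-U site
    expect_equal(s[s$pos == 23L, ]$nU, 10L)
    # only plus-strand sites: no read on the minus strand
    expect_true(all(s$strand == "+"))
})

test_that("minus-strand tally records counts in transcript space", {
    seqs <- rep(chrM, 8)
    substr(seqs[1:2], 6, 6) <- "G"   # read-space C on a minus read
    recs <- vapply(1:8, function(i)
        samRecord(paste0("m", i), 16L, "chrM", 1L, 60L, "12M", seqs[i]),
        character(1))
    fx <- writeFixture(c(chrM = chrM), recs)
    s <- as.data.frame(siteCounts(
        buildCountTable(fx$sam, fx$fasta, label = "direct")))
    expect_equal(nrow(s), 1L)
    expect_equal(s$strand, "-")
    expect_equal(s$pos, 5L)
    expect_equal(s$depth, 8L)
    expect_equal(s$nC, 2L)
    expect_equal(s$mismatch_frac, 0.25)
})

test_that("MAPQ boundary, secondary alignments, deletions and clips", {
    delSeq <- paste0(substr(chrP, 1, 5), substr(chrP, 8, 30))
    recs <- c(
        samRecord("q19", 0L, "chrP", 1L, 19L, "30M", chrP),
        samRecord("q20", 0L, "chrP", 1L, 20L, "30M", chrP),
        samRecord("sec", 256L, "chrP", 1L, 60L, "30M", chrP),
        samRecord("del", 0L, "chrP", 1L, 60L, "5M2D23M", delSeq),
        samRecord("scl", 0L, "chrP", 4L, 60L, "3S25M",
                  paste0("GGG", substr(chrP, 4, 28))),
        samRecord("scr", 0L, "chrP", 4L, 60L, "25M2S",
                  paste0(substr(chrP, 4, 28), "GG")))
    fx <- writeFixture(c(chrP = chrP), recs)
    s <- as.data.frame(siteCounts(
        buildCountTable(fx$sam, fx$fasta, label = "direct")))
    site6 <- s[s$pos == 5L, ]
    # q20 + del + scr contribute (q19/secondary filtered, scl masked)
    expect_equal(site6$depth, 3L)
    expect_equal(site6$nDel, 1L)
    expect_equal(site6$nU, 2L)
    site24 <- s[s$pos == 23L, ]
    # q20, del, scl, scr all cover position 24 unmasked
    expect_equal(site24$depth, 4L)
    expect_equal(site24$nU, 4L)
})

test_that("count table matches the brute-force per-read oracle on a
           simulated library with clips, introns and both strands", {
    cfg <- simulationConfig(seed = 11, nTranscripts = 3, coverage = 8,
        minusStrandFrac = 0.5, softclipProb = 0.4,
        truthSites = data.frame(transcript = 1, txpos = 100,
                                occupancy = 1, efficiency = 0.6))
    sim <- simulateExperiment(cfg)
    for (sam in c(sim$directSams[1], sim$ivtSams[1])) {
        got <- as.data.frame(siteCounts(
            buildCountTable(sam, sim$fasta, label = "direct")))
        want <- oracleCountTable(sam, sim$fasta)
        expect_equal(got[, colnames(want)], want)
        expect_true(all(got$nU + got$nC + got$nA + got$nG + got$nDel ==
                        got$depth))
    }
})

test_that("raising filter stringency never increases site depth", {
    cfg <- simulationConfig(seed = 12, nTranscripts = 2, coverage = 10,
                            softclipProb = 0.5, lowMapqFrac = 0.3)
    sim <- simulateExperiment(cfg)
    loose <- as.data.frame(siteCounts(buildCountTable(
        sim$directSams[1], sim$fasta, minMapq = 0L, clipMask = 0L,
        label = "direct")))
    strict <- as.data.frame(siteCounts(buildCountTable(
        sim$directSams[1], sim$fasta, minMapq = 20L, clipMask = 5L,
        label = "direct")))
    i <- match(paste(strict$contig, strict$pos, strict$strand),
               paste(loose$contig, loose$pos, loose$strand))
    expect_false(anyNA(i))
    expect_true(all(strict$depth <= loose$depth[i]))
})

test_that("merging replicates pools counts, not fractions", {
    t1 <- makeCountTable("c", 5L, "+", nU = 6L, nC = 4L)   # 0.4 of 10
    t2 <- makeCountTable("c", 5L, "+", nU = 27L, nC = 3L)  # 0.1 of 30
    m <- mergeReplicates(list(t1, t2))
    s <- as.data.frame(siteCounts(m))
    expect_equal(s$depth, 40L)
    expect_equal(s$nC, 7L)
    expect_equal(s$mismatch_frac, 0.175)
    # identity on a single table
    expect_identical(mergeReplicates(list(t1)), t1)
    # mixed labels refuse to merge
    t3 <- makeCountTable("c", 5L, "+", nU = 1L, nC = 0L, label = "ivt")
    expect_error(mergeReplicates(list(t1, t3)), "mixed")
})

test_that("pooled mismatch lies within the replicate range", {
    cfg <- simulationConfig(seed = 13, nTranscripts = 2, coverage = 12)
    sim <- simulateExperiment(cfg)
    tabs <- lapply(seq_len(3), function(r)
        buildCountTable(sim$directSams[r], sim$fasta, label = "direct",
                        replicate = paste0("rep", r)))
    m <- as.data.frame(siteCounts(mergeReplicates(tabs)))
    reps <- lapply(tabs, function(t) as.data.frame(siteCounts(t)))
    key <- function(d) paste(d$contig, d$pos, d$strand)
    fr <- sapply(reps, function(r) {
        i <- match(key(m), key(r))
        ifelse(is.na(i), NA, r$mismatch_frac[pmax(i, 1)])
    })
    lo <- apply(fr, 1, min, na.rm = TRUE)
    hi <- apply(fr, 1, max, na.rm = TRUE)
    expect_true(all(m$mismatch_frac >= lo - 1e-12 &
                    m$mismatch_frac <= hi + 1e-12))
})

test_that("alignments against unknown contigs are rejected with the name", {
    recs <- samRecord("r1", 0L, "chrP", 1L, 60L, "30M", chrP)
    fx <- writeFixture(c(chrP = chrP), recs)
    other <- tempfile(fileext = ".fa")
    dna <- Biostrings::DNAStringSet(c(elsewhere = "ACGTACGTACGT"))
    Biostrings::writeXStringSet(dna, other)
    expect_error(buildCountTable(fx$sam, other, label = "direct"), "chrP")
})
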