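toyModel <- transcriptModel("tx1", "g1", "chr1", "+",
                            c(100, 300), c(200, 400), 150, 350)

test_that("region assignment and splice distance on the toy transcript", {
    r <- assignRegion(160, toyModel)
    expect_equal(r$region, "CDS")
    expect_equal(r$splice_distance, 40)
    expect_equal(assignRegion(120, toyModel)$region, "5UTR")
    r <- assignRegion(390, toyModel)
    expect_equal(r$region, "3UTR")
    expect_equal(r$splice_distance, 90)
    # single-exon transcripts have no junction
    single <- transcriptModel("tx2", "g2", "chr1", "+", 100, 400, 150, 350)
    expect_true(is.na(assignRegion(160, single)$splice_distance))
    # intronic sites indicate a model mismatch
    expect_error(assignRegion(250, toyModel), "intronic")
    # non-coding transcripts report region noncoding
    nc <- transcriptModel("tx3", "g3", "chr1", "+", c(100, 300),
                          c(200, 400))
    expect_equal(assignRegion(160, nc)$region, "noncoding")
})

test_that("region assignment mirrors correctly on the minus strand", {
    # same exons, minus strand: 5'UTR is now at high genomic coordinates
    m <- transcriptModel("tx1", "g1", "chr1", "-",
                         c(100, 300), c(200, 400), 150, 350)
    expect_equal(assignRegion(390, m)$region, "5UTR")
    expect_equal(assignRegion(120, m)$region, "3UTR")
    r <- assignRegion(160, m)
    expect_equal(r$region, "CDS")
    # txpos of 160 on minus: exon2 (100 nt) + (200-1-160) = 139; |139-100|
    expect_equal(r$splice_distance, 39)
})

test_that("synthase motifs are tagged from the 5-mer", {
    expect_equal(motifTag("UGUAG"), "PUS7")
    expect_equal(motifTag(c("GUUCA", "GUUCU", "GUUCC", "GUUCG")),
                 rep("TRUB1", 4))
    expect_equal(motifTag("AAUCU"), "other")
    expect_error(motifTag("AACCU"), "center")
})

test_that("type I requires mismatch strictly above the cutoff", {
    expect_true(classifyType1(0.45))
    expect_false(classifyType1(0.40))
    expect_false(classifyType1(0.30))
    # monotone in the mismatch
    x <- seq(0, 1, by = 0.05)
    expect_true(all(diff(classifyType1(x)) >= 0))
})

test_that("type II counts unique highly significant positions", {
    tx <- c("a", "a", "b", "b", "c", "c", "c", "c", "c", "c", "c")
    pos <- c(10, 20, 10, 30, 1:7 * 10)
    tier <- c("highly_significant", "highly_significant",
              "highly_significant", "significant",
              rep("highly_significant", 7))
    out <- classifyType2(tx, pos, tier)
    expect_true(out$type2[out$transcript_id == "a"])
    expect_equal(out$n_high_sites[out$transcript_id == "a"], 2L)
    # a merely significant second site does not make a transcript type II
    expect_false(out$type2[out$transcript_id == "b"])
    # the 7-position transcript lands in the 7 histogram bin
    h <- attr(out, "histogram")
    expect_equal(h$n_transcripts[h$n_sites == 7L], 1L)
    # duplicated positions count once
    out2 <- classifyType2(c("d", "d"), c(5, 5),
                          rep("highly_significant", 2))
    expect_false(out2$type2)
})

test_that("kmer frequencies sort and normalise", {
    t <- kmerFrequency(c("UGUAG", "UGUAG", "GUUCA"))
    expect_equal(t$kmer[1], "UGUAG")
    expect_equal(t$fraction, c(2, 1) / 3)
    expect_equal(sum(t$fraction), 1)
    expect_equal(nrow(kmerFrequency(character(0))), 0L)
})

test_that("position frequency matrix is all-U at the center with equal
           column sums", {
    ctx <- "AGGTCATCGATAG"   # 13-mer with T at position 7
    contig <- paste0(strrep("C", 20), ctx, strrep("C", 20))
    fx <- writeFixture(c(c1 = contig), character(0))
    pfm <- positionFrequencyMatrix(fx$fasta, c("c1", "c1"),
                                   c(26L, 26L), c("+", "+"))
    expect_equal(dim(pfm), c(4L, 13L))
    expect_equal(pfm["U", "0"], 2L)
    expect_equal(sum(pfm[, "0"]), 2L)
    expect_true(all(colSums(pfm) == 2L))
    # identical contexts: one nonzero count per column
    expect_true(all(apply(pfm, 2, function(x) sum(x > 0)) == 1L))
})

test_that("dominant isoform follows read support, then length, then id", {
    short <- transcriptModel("short", "g", "chr1", "+", 100, 300)
    long <- transcriptModel("long", "g", "chr1", "+", 100, 400)
    # no reads: longest transcript wins
    m <- dominantIsoform(NULL, list(short, long), "chr1", 150, "+")
    expect_equal(m@transcript_id, "long")
    # equal support and length: lexicographic id
    a <- transcriptModel("a", "g", "chr1", "+", 100, 300)
    b <- transcriptModel("b", "g", "chr1", "+", 100, 300)
    expect_equal(dominantIsoform(NULL, list(b, a), "chr1", 150,
                                 "+")@transcript_id, "a")
    # no overlapping candidate
    expect_null(dominantIsoform(NULL, list(short), "chr1", 350, "+"))
})

test_that("read support discriminates spliced isoforms", {
    # genomic: exon1 0-50, intron 50-100, exon2 100-150 (spliced iso);
    # unspliced iso covers 0-150 contiguously
    contig <- strrep("ACGT", 50)
    spliced <- transcriptModel("spliced", "g", "c1", "+",
                               c(0, 100), c(50, 150))
    unspliced <- transcriptModel("unspliced", "g", "c1", "+", 0, 150)
    sp <- function(i) samRecord(paste0("s", i), 0L, "c1", 1L, 60L,
                                "50M50N50M", substr(paste0(
                                    substr(contig, 1, 50),
                                    substr(contig, 101, 150)), 1, 100))
    reads <- vapply(1:30, sp, character(1))
    fx <- writeFixture(c(c1 = contig), reads)
    m <- dominantIsoform(fx$sam, list(spliced, unspliced), "c1", 20, "+")
    expect_equal(m@transcript_id, "spliced")
})

test_that("annotated simulator calls recover planted type II transcripts
           and region fractions sum to one", {
    cfg <- simulationConfig(seed = 31, nTranscripts = 5, coverage = 40,
        cdsFrac = 1, truthSites = data.frame(
            transcript = c(1, 1, 2), txpos = c(150, 300, 200),
            occupancy = 1, efficiency = 0.7))
    r <- endToEndRecovery(cfg)
    ann <- r$annotated
    expect_true(all(!is.na(ann$transcript_id)))
    hit <- paste(ann$contig, ann$pos) %in%
        paste(r$sim$truth$contig, r$sim$truth$pos)
    expect_true(all(hit))
    frac <- table(ann$region[ann$region %in% c("5UTR", "CDS", "3UTR")])
    expect_equal(sum(frac / sum(frac)), 1)
    t2 <- r$type2
    expect_true(t2$type2[t2$transcript_id == "tx001"])
    expect_false(any(t2$type2[t2$transcript_id != "tx001"]))
})

test_that("GTF round-trip reproduces the simulated transcript models", {
    cfg <- simulationConfig(seed = 32, nTranscripts = 3, coverage = 5)
    sim <- simulateExperiment(cfg)
    models <- loadTranscriptModels(sim$gtf)
    expect_setequal(names(models),
                    vapply(sim$models, function(m) m@transcript_id,
                           character(1)))
    for (nm in names(models)) {
        expect_equal(models[[nm]]@exons, sim$models[[nm]]@exons,
                     ignore_attr = TRUE)
        expect_equal(models[[nm]]@strand, sim$models[[nm]]@strand)
        expect_equal(models[[nm]]@cdsStart, sim$models[[nm]]@cdsStart)
        expect_equal(models[[nm]]@cdsEnd, sim$models[[nm]]@cdsEnd)
    }
})
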