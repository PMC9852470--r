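#' Configuration for the synthetic direct/IVT experiment generator
#'
#' The generator emulates a paired direct / IVT nanopore experiment at
#' the basecall level: transcripts embedded in synthetic contigs with
#' 1--5 exons, 3'-anchored reads with optional 5' truncation (so coverage
#' decays toward the 5' end), per-5-mer background U-to-C error, per-site
#' modification occupancy with basecaller under-calling efficiency, and
#' soft-clipped read ends.  IVT libraries force occupancy 0 everywhere.
#'
#' @param seed integer seed; every downstream draw derives from it.
#' @param nTranscripts number of transcripts (one gene per contig).
#' @param medianLength,sdlogLength log-normal transcript-length model
#'   (median 670 nt, sdlog 0.45 giving an N50 near 850 nt).
#' @param coverage reads simulated per transcript per replicate.
#' @param nDirectReps,nIvtReps replicate structure (defaults 3 and 2).
#' @param backgroundError background U-to-C miscall rate applied to every
#'   5-mer without an override (default 0.0264).
#' @param kmerOverrides named numeric vector of per-5-mer background
#'   rates (default \code{c(CUUUG = 0.10, AAUCU = 0.004)}).
#' @param nonUError miscall rate at non-U bases (to a random other base).
#' @param truncFrac fraction of reads 5'-truncated at a uniform point.
#' @param minReadLen minimum simulated read length (nt).
#' @param softclipProb per read-end probability of a soft clip.
#' @param maxSoftclip maximum soft-clip length (nt).
#' @param lowMapqFrac fraction of reads emitted with MAPQ 10 (filtered
#'   out by the default caller settings).
#' @param minusStrandFrac fraction of genes placed on the minus strand.
#' @param nExonsRange inclusive range of exon counts per transcript.
#' @param intronRange inclusive range of intron lengths (nt).
#' @param cdsFrac fraction of transcripts annotated with a CDS.
#' @param truthSites \code{data.frame} with columns \code{transcript}
#'   (1-based index), \code{txpos} (0-based transcript coordinate),
#'   \code{occupancy}, \code{efficiency}; the reference is forced to U
#'   at these positions.
#' @param plantContexts optional \code{data.frame(transcript, txpos,
#'   kmer)} forcing a 5-mer sequence context centered at a transcript
#'   position (used to place specific background k-mers).
#' @return a list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1L, nTranscripts = 20L,
                             medianLength = 670, sdlogLength = 0.45,
                             coverage = 50L, nDirectReps = 3L,
                             nIvtReps = 2L, backgroundError = 0.0264,
                             kmerOverrides = c(CUUUG = 0.10,
                                               AAUCU = 0.004),
                             nonUError = 0.002, truncFrac = 0.3,
                             minReadLen = 50L, softclipProb = 0.2,
                             maxSoftclip = 5L, lowMapqFrac = 0.02,
                             minusStrandFrac = 0.3,
                             nExonsRange = c(1L, 5L),
                             intronRange = c(50L, 200L), cdsFrac = 0.8,
                             truthSites = NULL, plantContexts = NULL) {
    cfg <- as.list(environment())
    rates <- c(backgroundError, kmerOverrides, nonUError)
    if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
    if (!is.null(truthSites) &&
        any(truthSites$occupancy < 0 | truthSites$occupancy > 1 |
            truthSites$efficiency < 0 | truthSites$efficiency > 1))
        stop("occupancy and efficiency must lie in [0, 1]")
    class(cfg) <- "SimulationConfig"
    cfg
}

# background U-to-C rate for a vector of 5-mers
.bgRate <- function(kmer, config) {
    r <- rep(config$backgroundError, length(kmer))
    i <- match(kmer, names(config$kmerOverrides))
    r[!is.na(i)] <- config$kmerOverrides[i[!is.na(i)]]
    r
}

.randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# map 0-based transcript coords to 0-based genomic coords via a layout
.txToGenomic <- function(layout, p) {
    ex <- layout$exons
    out <- rep(NA_real_, length(p))
    for (k in seq_len(nrow(ex))) {
        inEx <- p >= ex$txStart[k] & p < ex$txEnd[k]
        off <- p[inEx] - ex$txStart[k]
        out[inEx] <- if (layout$strand == "+") ex$gStart[k] + off
                     else ex$gEnd[k] - 1 - off
    }
    out
}

#' Build the synthetic reference genome, annotation and truth table
#'
#' Deterministic given the config seed.  Each transcript lives on its own
#' contig with 100-nt pads, 1--5 exons separated by introns, a CDS for
#' the configured fraction of transcripts, and the requested truth-site
#' and planted-context sequence constraints.
#'
#' @param config a [simulationConfig()].
#' @param outDir directory for \code{reference.fa} (+ .fai) and
#'   \code{annotation.gtf}.
#' @return a simulation descriptor list: file paths, per-transcript
#'   layouts, transcript sequences, [TranscriptModel-class] list, and the
#'   truth \code{data.frame} (with genomic coordinates, k-mer and
#'   expected mismatch per site).
#' @export
makeReference <- function(config, outDir = tempfile("psinano_sim_")) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    set.seed(config$seed)
    n <- config$nTranscripts
    lens <- if (n > 0L) pmax(config$minReadLen * 4L, pmin(6000L, round(
        stats::rlnorm(n, meanlog = log(config$medianLength),
                      sdlog = config$sdlogLength)))) else integer(0)
    # transcripts must hold their truth sites / planted contexts
    needs <- function(t) {
        m <- 0L
        if (!is.null(config$truthSites)) {
            p <- config$truthSites$txpos[config$truthSites$transcript == t]
            if (length(p)) m <- max(m, max(p) + 3L)
        }
        if (!is.null(config$plantContexts)) {
            p <- config$plantContexts$txpos[
                config$plantContexts$transcript == t]
            if (length(p)) m <- max(m, max(p) + 3L)
        }
        m
    }
    txSeqs <- character(n); layouts <- vector("list", n)
    models <- vector("list", n)
    contigSeqs <- character(n)
    gtf <- character(0)
    names(layouts) <- names(models) <- sprintf("tx%03d", seq_len(n))
    truth <- NULL
    for (t in seq_len(n)) {
        txid <- sprintf("tx%03d", t); gid <- sprintf("g%03d", t)
        contig <- sprintf("ctg%03d", t)
        L <- max(lens[t], needs(t) + 10L)
        S <- .randSeq(L)
        if (!is.null(config$plantContexts)) {
            pc <- config$plantContexts[config$plantContexts$transcript == t, ,
                                       drop = FALSE]
            for (r in seq_len(nrow(pc))) {
                km <- chartr("U", "T", pc$kmer[r])
                substr(S, pc$txpos[r] - 1L, pc$txpos[r] + 3L) <- km
            }
        }
        tsT <- if (is.null(config$truthSites)) NULL else
            config$truthSites[config$truthSites$transcript == t, ,
                              drop = FALSE]
        if (!is.null(tsT) && nrow(tsT)) {
            for (r in seq_len(nrow(tsT))) {
                p1 <- tsT$txpos[r] + 1L
                if (substr(S, p1, p1) != "T")
                    substr(S, p1, p1) <- "T"
            }
        }
        # exon structure (plus-strand build, flipped afterwards if minus)
        maxEx <- max(1L, min(config$nExonsRange[2], L %/% 60L))
        nEx <- sample(seq.int(min(config$nExonsRange[1], maxEx), maxEx), 1L)
        cuts <- if (nEx > 1L)
            sort(sample(seq.int(30L, L - 30L), nEx - 1L)) else integer(0)
        exTxStart <- c(0L, cuts); exTxEnd <- c(cuts, L)
        intr <- if (nEx > 1L)
            sample(seq.int(config$intronRange[1], config$intronRange[2]),
                   nEx - 1L, replace = TRUE) else integer(0)
        pad <- 100L
        gStart <- numeric(nEx); gEnd <- numeric(nEx)
        cursor <- pad
        genomic <- .randSeq(pad)
        for (k in seq_len(nEx)) {
            w <- exTxEnd[k] - exTxStart[k]
            gStart[k] <- cursor; gEnd[k] <- cursor + w
            genomic <- paste0(genomic,
                              substr(S, exTxStart[k] + 1L, exTxEnd[k]))
            cursor <- cursor + w
            if (k < nEx) {
                genomic <- paste0(genomic, .randSeq(intr[k]))
                cursor <- cursor + intr[k]
            }
        }
        genomic <- paste0(genomic, .randSeq(pad))
        Lc <- nchar(genomic)
        strand <- if (stats::runif(1) < config$minusStrandFrac) "-" else "+"
        if (strand == "-") {
            genomic <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(genomic)))
            ngS <- Lc - gEnd; ngE <- Lc - gStart
            gStart <- ngS; gEnd <- ngE    # tx order now genomic-descending
        }
        layouts[[t]] <- list(contig = contig, strand = strand, L = L,
                             exons = data.frame(txStart = exTxStart,
                                                txEnd = exTxEnd,
                                                gStart = gStart,
                                                gEnd = gEnd))
        txSeqs[t] <- S
        contigSeqs[t] <- genomic
        # CDS in transcript coordinates, mapped to genomic bounds
        hasCDS <- stats::runif(1) < config$cdsFrac && L >= 150L
        csG <- ceG <- NA_real_
        if (hasCDS) {
            csTx <- floor(0.2 * L); ceTx <- floor(0.8 * L)
            gpos <- .txToGenomic(layouts[[t]], c(csTx, ceTx - 1L))
            csG <- min(gpos); ceG <- max(gpos) + 1
        }
        eo <- order(gStart)
        models[[t]] <- transcriptModel(txid, gid, contig, strand,
                                       gStart[eo], gEnd[eo], csG, ceG)
        for (k in eo)
            gtf <- c(gtf, paste(contig, "psiNano", "exon", gStart[k] + 1L,
                gEnd[k], ".", strand, ".",
                sprintf('gene_id "%s"; transcript_id "%s";', gid, txid),
                sep = "\t"))
        if (hasCDS) {
            ex <- layouts[[t]]$exons
            for (k in seq_len(nrow(ex))) {
                cs <- max(ex$gStart[k], csG); ce <- min(ex$gEnd[k], ceG)
                if (ce > cs)
                    gtf <- c(gtf, paste(contig, "psiNano", "CDS", cs + 1L,
                        ce, ".", strand, ".",
                        sprintf('gene_id "%s"; transcript_id "%s";',
                                gid, txid), sep = "\t"))
            }
        }
        if (!is.null(tsT) && nrow(tsT)) {
            gpos <- .txToGenomic(layouts[[t]], tsT$txpos)
            km <- vapply(tsT$txpos, function(p)
                .toRNA(substr(S, p - 1L, p + 3L)), character(1))
            occEff <- tsT$occupancy * tsT$efficiency
            bg <- .bgRate(km, config)
            truth <- rbind(truth, data.frame(
                transcript_id = txid, contig = contig, pos = gpos,
                strand = strand, txpos = tsT$txpos, kmer = km,
                occupancy = tsT$occupancy, efficiency = tsT$efficiency,
                expected_mismatch = occEff + (1 - occEff) * bg))
        }
    }
    fasta <- file.path(outDir, "reference.fa")
    dna <- Biostrings::DNAStringSet(contigSeqs)
    names(dna) <- sprintf("ctg%03d", seq_len(n))
    Biostrings::writeXStringSet(dna, fasta, width = 70L)
    if (file.exists(paste0(fasta, ".fai")))
        unlink(paste0(fasta, ".fai"))
    if (n > 0L) Rsamtools::indexFa(fasta)
    gtfPath <- file.path(outDir, "annotation.gtf")
    writeLines(gtf, gtfPath)
    if (!is.null(truth)) {
        bad <- vapply(seq_len(nrow(truth)), function(i) {
            p <- truth$txpos[i]
            substr(txSeqs[truth$transcript_id[i] == names(layouts)][1],
                   p + 1L, p + 1L) != "T"
        }, logical(1))
        if (any(bad)) stop("truth site requested on a non-U base")
    }
    list(config = config, dir = outDir, fasta = fasta, gtf = gtfPath,
         layouts = layouts, txSeqs = stats::setNames(txSeqs,
                                                     names(layouts)),
         models = models, truth = truth)
}

# simulate one read set for one transcript; returns SAM record strings
.simulateTranscriptReads <- function(sim, t, config, label, prefix) {
    lay <- sim$layouts[[t]]
    S <- sim$txSeqs[[t]]
    L <- lay$L
    chars <- strsplit(S, "")[[1]]
    uPos <- which(chars == "T")            # 0-based: uPos - 1
    km <- vapply(uPos, function(p1) {
        if (p1 < 3L || p1 > L - 2L) NA_character_
        else .toRNA(substr(S, p1 - 2L, p1 + 2L))
    }, character(1))
    uRate <- .bgRate(km, config)
    uRate[is.na(km)] <- config$backgroundError
    txid <- names(sim$layouts)[t]
    ts <- sim$truth
    tsT <- if (is.null(ts) || label == "ivt") NULL else
        ts[ts$transcript_id == txid, , drop = FALSE]

    recs <- character(config$coverage)
    for (i in seq_len(config$coverage)) {
        s0 <- 0L
        if (L > config$minReadLen &&
            stats::runif(1) < config$truncFrac)
            s0 <- sample.int(L - config$minReadLen, 1L)
        rchars <- chars[(s0 + 1L):L]
        inWin <- uPos > s0
        up <- uPos[inWin]; rate <- uRate[inWin]
        call_c <- stats::runif(length(up)) < rate
        if (!is.null(tsT) && nrow(tsT)) {
            for (r in seq_len(nrow(tsT))) {
                p1 <- tsT$txpos[r] + 1L
                j <- match(p1, up)
                if (is.na(j)) next
                if (stats::runif(1) < tsT$occupancy[r]) {
                    # modified molecule: miscalled C per efficiency
                    call_c[j] <- stats::runif(1) < tsT$efficiency[r]
                }
            }
        }
        rchars[up[call_c] - s0] <- "C"
        nonU <- setdiff(seq_along(rchars), up - s0)
        err <- nonU[stats::runif(length(nonU)) < config$nonUError]
        if (length(err)) {
            for (e in err) {
                alt <- setdiff(c("A", "C", "G", "T"), rchars[e])
                rchars[e] <- alt[sample.int(3L, 1L)]
            }
        }
        readSeq <- paste(rchars, collapse = "")

        # genomic placement and CIGAR
        ex <- lay$exons
        cov <- ex[ex$txEnd > s0, , drop = FALSE]
        covS <- pmax(cov$txStart, s0)
        if (lay$strand == "+") {
            gS <- cov$gStart + (covS - cov$txStart)
            gE <- cov$gEnd
            widths <- gE - gS
            pos1 <- gS[1] + 1
            cigar <- paste0(widths[1], "M")
            if (length(widths) > 1L) for (k in 2:length(widths))
                cigar <- paste0(cigar, gS[k] - gE[k - 1L], "N",
                                widths[k], "M")
            seqOut <- readSeq
        } else {
            gE <- cov$gEnd - (covS - cov$txStart)
            gS <- cov$gStart
            widths <- gE - gS
            o <- order(gS)            # ascending genomic for the CIGAR
            gS <- gS[o]; gE <- gE[o]; widths <- widths[o]
            pos1 <- gS[1] + 1
            cigar <- paste0(widths[1], "M")
            if (length(widths) > 1L) for (k in 2:length(widths))
                cigar <- paste0(cigar, gS[k] - gE[k - 1L], "N",
                                widths[k], "M")
            seqOut <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(readSeq)))
        }
        if (stats::runif(1) < config$softclipProb) {
            cl <- sample.int(config$maxSoftclip, 1L)
            seqOut <- paste0(.randSeq(cl), seqOut)
            cigar <- paste0(cl, "S", cigar)
        }
        if (stats::runif(1) < config$softclipProb) {
            cl <- sample.int(config$maxSoftclip, 1L)
            seqOut <- paste0(seqOut, .randSeq(cl))
            cigar <- paste0(cigar, cl, "S")
        }
        mapq <- if (stats::runif(1) < config$lowMapqFrac) 10L else 60L
        flag <- if (lay$strand == "-") 16L else 0L
        recs[i] <- paste(sprintf("%s_%s_r%04d", prefix, txid, i), flag,
                         lay$contig, pos1, mapq, cigar, "*", 0L, 0L,
                         seqOut, "*", sep = "\t")
    }
    recs
}

#' Simulate one direct or IVT replicate as a SAM file
#'
#' Reads are 3'-anchored with optional 5' truncation; at every uridine a
#' read miscalls C with the 5-mer background rate, and at truth sites of
#' a direct library the molecule is modified with probability
#' \code{occupancy} and a modified base is called C with probability
#' \code{efficiency}.  IVT libraries ignore the truth sites (occupancy 0
#' everywhere, the modification-free control).
#'
#' @param sim a simulation descriptor from [makeReference()].
#' @param label \code{"direct"} or \code{"ivt"}.
#' @param replicate replicate number (drives the random substream).
#' @param outSam output SAM path (default inside the simulation dir).
#' @return the SAM path, invisibly.
#' @export
simulateLibrary <- function(sim, label = c("direct", "ivt"),
                            replicate = 1L, outSam = NULL) {
    label <- match.arg(label)
    config <- sim$config
    if (is.null(outSam))
        outSam <- file.path(sim$dir,
                            sprintf("%s_rep%d.sam", label, replicate))
    # per-component substream: replicate and library never share draws
    set.seed(config$seed + 7919L * as.integer(replicate) +
             if (label == "ivt") 104729L else 0L)
    hdr <- "@HD\tVN:1.6\tSO:unknown"
    if (length(sim$layouts) > 0L) {
        fai <- Rsamtools::seqinfo(openReference(sim$fasta))
        ctgs <- as.character(GenomeInfoDb::seqnames(fai))
        hdr <- c(hdr, sprintf("@SQ\tSN:%s\tLN:%d", ctgs,
                              GenomeInfoDb::seqlengths(fai)[ctgs]))
    }
    prefix <- sprintf("%s%d", label, replicate)
    recs <- unlist(lapply(seq_along(sim$layouts), function(t)
        .simulateTranscriptReads(sim, t, config, label, prefix)))
    writeLines(c(hdr, recs), outSam)
    invisible(outSam)
}

#' Simulate the full paired experiment
#'
#' Builds the reference and annotation, writes every direct and IVT
#' replicate as SAM, and the truth table as TSV.
#'
#' @param config a [simulationConfig()].
#' @param outDir output directory.
#' @return simulation descriptor with elements \code{directSams},
#'   \code{ivtSams} and \code{truthTsv} added.
#' @export
simulateExperiment <- function(config,
                               outDir = tempfile("psinano_sim_")) {
    sim <- makeReference(config, outDir)
    sim$directSams <- vapply(seq_len(config$nDirectReps), function(r)
        simulateLibrary(sim, "direct", r), character(1))
    sim$ivtSams <- vapply(seq_len(config$nIvtReps), function(r)
        simulateLibrary(sim, "ivt", r), character(1))
    sim$truthTsv <- file.path(outDir, "truth.tsv")
    .writeTSV(if (is.null(sim$truth)) data.frame() else sim$truth,
              sim$truthTsv)
    jsonlite::write_json(sim$config[!vapply(sim$config, is.data.frame,
                                            logical(1))],
                         file.path(outDir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    sim
}

#' Run the whole pipeline on a simulated experiment and score it
#'
#' Counts every replicate, runs detection, annotation and type I/II
#' classification, and compares the calls against the planted truth.
#'
#' @param config a [simulationConfig()].
#' @param outDir working directory for the simulated files.
#' @return list with the call set, annotated calls, and a report:
#'   sensitivity and specificity against truth, tier recall,
#'   background-recovery error, and the type I/II confusion counts.
#' @export
endToEndRecovery <- function(config,
                             outDir = tempfile("psinano_e2e_")) {
    sim <- simulateExperiment(config, outDir)
    direct <- lapply(seq_along(sim$directSams), function(r)
        buildCountTable(sim$directSams[r], sim$fasta, label = "direct",
                        replicate = paste0("rep", r)))
    ivt <- lapply(seq_along(sim$ivtSams), function(r)
        buildCountTable(sim$ivtSams[r], sim$fasta, label = "ivt",
                        replicate = paste0("rep", r)))
    calls <- detectModifications(direct, ivt, sim$fasta)
    cl <- modCalls(calls)
    key <- .siteKey(cl$contig, cl$pos, cl$strand)
    truthKey <- if (is.null(sim$truth)) character(0) else
        .siteKey(sim$truth$contig, sim$truth$pos, sim$truth$strand)
    isTruth <- key %in% truthKey
    eligible <- cl$reason != "low_coverage"
    report <- list(
        n_tested = nrow(cl),
        n_truth = length(truthKey),
        n_truth_tested = sum(isTruth),
        sensitivity = if (any(isTruth & eligible))
            mean(cl$consensus[isTruth & eligible]) else NA_real_,
        high_tier_recall = if (any(isTruth & eligible))
            mean(cl$tier[isTruth & eligible] == "highly_significant")
            else NA_real_,
        specificity = if (any(!isTruth & eligible))
            mean(!cl$consensus[!isTruth & eligible]) else NA_real_)
    ann <- annotateCalls(calls, sim$models, bam = sim$directSams[1])
    t2 <- classifyType2(ann$transcript_id, ann$pos, ann$tier)
    list(sim = sim, calls = calls, annotated = ann, type2 = t2,
         report = report)
}
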