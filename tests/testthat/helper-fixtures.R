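# Build small SAM + FASTA fixtures in code, and an independent
# brute-force tally oracle that shares no code with buildCountTable.

writeFixture <- function(contigs, records, dir = tempfile("fix_")) {
    dir.create(dir, showWarnings = FALSE)
    fasta <- file.path(dir, "ref.fa")
    dna <- Biostrings::DNAStringSet(contigs)
    names(dna) <- names(contigs)
    Biostrings::writeXStringSet(dna, fasta, width = 70L)
    Rsamtools::indexFa(fasta)
    sam <- file.path(dir, "reads.sam")
    hdr <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", names(contigs),
                     nchar(contigs)))
    writeLines(c(hdr, records), sam)
    list(fasta = fasta, sam = sam, dir = dir)
}

samRecord <- function(qname, flag, rname, pos, mapq, cigar, seq) {
    paste(qname, flag, rname, pos, mapq, cigar, "*", 0, 0, seq, "*",
          sep = "\t")
}

# brute-force per-read walk over a SAM text file: plain string parsing,
# no Rsamtools / GenomicAlignments involved
oracleCountTable <- function(samPath, fastaPath, minMapq = 20,
                             clipMask = 3) {
    lines <- readLines(samPath)
    lines <- lines[!startsWith(lines, "@")]
    ref <- Biostrings::readDNAStringSet(fastaPath)
    names(ref) <- sub("\\s.*", "", names(ref))
    tally <- new.env()
    bump <- function(key, slot) {
        cur <- tally[[key]]
        if (is.null(cur))
            cur <- c(U = 0, C = 0, A = 0, G = 0, del = 0)
        cur[slot] <- cur[slot] + 1
        tally[[key]] <- cur
    }
    for (ln in lines) {
        f <- strsplit(ln, "\t")[[1]]
        flag <- as.integer(f[2]); mapq <- as.integer(f[5])
        if (bitwAnd(flag, 0x4) > 0 || bitwAnd(flag, 0x100) > 0 ||
            bitwAnd(flag, 0x800) > 0 || mapq < minMapq) next
        rname <- f[3]; pos <- as.integer(f[4]); cigar <- f[6]
        seq <- f[10]
        strand <- if (bitwAnd(flag, 0x10) > 0) "-" else "+"
        ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
        lens <- as.integer(sub("[A-Z=]", "", ops))
        chs <- sub("[0-9]+", "", ops)
        refp <- pos; readp <- 1L
        aligned <- list(); dels <- integer(0)
        for (k in seq_along(chs)) {
            ch <- chs[k]; w <- lens[k]
            if (ch %in% c("M", "=", "X")) {
                for (u in seq_len(w))
                    aligned[[length(aligned) + 1L]] <-
                        c(refp + u - 1L, readp + u - 1L)
                refp <- refp + w; readp <- readp + w
            } else if (ch == "D") {
                dels <- c(dels, refp:(refp + w - 1L))
                refp <- refp + w
            } else if (ch == "N") {
                refp <- refp + w
            } else if (ch %in% c("I", "S")) {
                readp <- readp + w
            }
        }
        leftClip <- if (chs[1] %in% c("S", "H")) lens[1] else 0L
        nops <- length(chs)
        rightClip <- if (chs[nops] %in% c("S", "H")) lens[nops] else 0L
        refPositions <- vapply(aligned, `[`, integer(1), 1L)
        masked <- integer(0)
        n <- length(refPositions)
        if (leftClip > 0 && clipMask > 0)
            masked <- c(masked, refPositions[seq_len(min(clipMask, n))])
        if (rightClip > 0 && clipMask > 0)
            masked <- c(masked,
                        refPositions[seq.int(max(1, n - clipMask + 1), n)])
        for (a in aligned) {
            rp <- a[1]
            if (rp %in% masked) next
            refbase <- toupper(substr(as.character(ref[[rname]]), rp, rp))
            siteU <- (strand == "+" && refbase == "T") ||
                     (strand == "-" && refbase == "A")
            if (!siteU) next
            b <- toupper(substr(seq, a[2], a[2]))
            if (strand == "-") b <- chartr("ACGTN", "TGCAN", b)
            if (b == "N") next
            if (b == "T") b <- "U"
            if (!b %in% c("U", "C", "A", "G")) next
            bump(paste(rname, rp - 1L, strand, sep = ":"), b)
        }
        for (rp in dels) {
            if (rp %in% masked) next
            refbase <- toupper(substr(as.character(ref[[rname]]), rp, rp))
            siteU <- (strand == "+" && refbase == "T") ||
                     (strand == "-" && refbase == "A")
            if (siteU)
                bump(paste(rname, rp - 1L, strand, sep = ":"), "del")
        }
    }
    keys <- ls(tally)
    if (length(keys) == 0L)
        return(data.frame(contig = character(0), pos = integer(0),
                          strand = character(0), depth = integer(0),
                          nU = integer(0), nC = integer(0),
                          nA = integer(0), nG = integer(0),
                          nDel = integer(0)))
    parts <- strsplit(keys, ":")
    df <- data.frame(
        contig = vapply(parts, `[`, character(1), 1L),
        pos = as.integer(vapply(parts, `[`, character(1), 2L)),
        strand = vapply(parts, `[`, character(1), 3L))
    m <- t(vapply(keys, function(k) tally[[k]], numeric(5)))
    df$nU <- as.integer(m[, "U"]); df$nC <- as.integer(m[, "C"])
    df$nA <- as.integer(m[, "A"]); df$nG <- as.integer(m[, "G"])
    df$nDel <- as.integer(m[, "del"])
    df$depth <- df$nU + df$nC + df$nA + df$nG + df$nDel
    df <- df[order(df$contig, df$pos, df$strand), ]
    rownames(df) <- NULL
    df[, c("contig", "pos", "strand", "depth", "nU", "nC", "nA", "nG",
           "nDel")]
}

# independent log-space term-by-term binomial upper tail
oracleBinomTail <- function(N, Nmm, p0) {
    if (Nmm == 0) return(1)
    if (p0 == 0) return(0)
    if (p0 == 1) return(1)
    k <- Nmm:N
    sum(exp(lchoose(N, k) + k * log(p0) + (N - k) * log1p(-p0)))
}

# CountTable construction straight from count vectors (test scaffolding)
makeCountTable <- function(contig, pos, strand, nU, nC, nA = 0L, nG = 0L,
                           nDel = 0L, label = "direct", rep = "rep1") {
    n <- length(pos)
    nA <- rep_len(nA, n); nG <- rep_len(nG, n); nDel <- rep_len(nDel, n)
    depth <- nU + nC + nA + nG + nDel
    new("CountTable",
        sites = S4Vectors::DataFrame(
            contig = rep_len(contig, n), pos = as.integer(pos),
            strand = rep_len(strand, n), depth = as.integer(depth),
            nU = as.integer(nU), nC = as.integer(nC),
            nA = as.integer(nA), nG = as.integer(nG),
            nDel = as.integer(nDel), mismatch_frac = nC / depth),
        label = label, replicate = rep, params = list())
}
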