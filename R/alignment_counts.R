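#' Read-level alignment filter
#'
#' Keeps only primary alignments with sufficient mapping quality, the two
#' read-level filters applied before any site is counted.  Unmapped,
#' secondary and supplementary alignments are always rejected.
#'
#' @param flag integer vector of SAM FLAG values.
#' @param mapq integer vector of mapping qualities (same length).
#' @param minMapq minimum mapping quality to keep a read (default 20,
#'   i.e. >= 99\% probability of correct placement).
#' @return logical vector, \code{TRUE} for reads that pass.
#' @examples
#' filterAlignment(c(0L, 256L, 0L), c(60L, 60L, 19L))  # TRUE FALSE FALSE
#' @export
filterAlignment <- function(flag, mapq, minMapq = 20L) {
    if (length(flag) != length(mapq))
        stop("flag and mapq must have the same length")
    if (anyNA(flag))
        stop("malformed record: missing FLAG")
    unmapped <- bitwAnd(flag, 0x4L) > 0L
    secondary <- bitwAnd(flag, 0x100L) > 0L
    supplementary <- bitwAnd(flag, 0x800L) > 0L
    mapq[is.na(mapq)] <- 0L
    !unmapped & !secondary & !supplementary & mapq >= minMapq
}

#' Reference positions masked next to a clipped read end
#'
#' Bases adjacent to a soft-clipped (or hard-clipped) read end have
#' degraded quality, so the first \code{nMask} aligned bases after a left
#' clip and the last \code{nMask} before a right clip are excluded from
#' counting.  An end without a clip contributes no masked positions; the
#' mask truncates at the read length.
#'
#' @param alignedPositions increasing integer vector of reference
#'   positions carrying an aligned base for this read.
#' @param leftClip,rightClip clipped lengths (nt) at each read end.
#' @param nMask bases to mask next to each clipped end (default 3).
#' @return integer vector of masked reference positions (possibly empty).
#' @export
maskClipAdjacent <- function(alignedPositions, leftClip, rightClip,
                             nMask = 3L) {
    if (nMask < 0L) stop("nMask must be >= 0")
    n <- length(alignedPositions)
    idx <- integer(0)
    if (leftClip > 0L && nMask > 0L)
        idx <- c(idx, seq_len(min(nMask, n)))
    if (rightClip > 0L && nMask > 0L)
        idx <- c(idx, seq.int(max(1L, n - nMask + 1L), length.out = min(nMask, n)))
    alignedPositions[unique(idx)]
}

# leading / trailing S+H clip lengths for a cigar vector
.clipLengths <- function(cigar) {
    ops <- GenomicAlignments::explodeCigarOps(cigar)
    lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
    left <- mapply(function(o, l) {
        i <- 1L; tot <- 0L
        while (i <= length(o) && o[i] %in% c("S", "H")) {
            tot <- tot + l[i]; i <- i + 1L
        }
        tot
    }, ops, lens, USE.NAMES = FALSE)
    right <- mapply(function(o, l) {
        i <- length(o); tot <- 0L
        while (i >= 1L && o[i] %in% c("S", "H")) {
            tot <- tot + l[i]; i <- i - 1L
        }
        tot
    }, ops, lens, USE.NAMES = FALSE)
    list(left = as.integer(left), right = as.integer(right))
}

#' Build the per-uridine-site base-call count table for one replicate
#'
#' Walks every primary, MAPQ-filtered alignment, masks clip-adjacent
#' bases, and tallies transcript-space base calls at every reference
#' position whose transcript-space base is U (plus-strand T, minus-strand
#' A).  Reads contribute only to sites on their own alignment strand --
#' for direct RNA sequencing the alignment strand is the transcribed
#' strand.  Deletions at a site increment \code{nDel} (and depth);
#' insertions and read-space N calls are ignored.
#'
#' @param file path to a coordinate-sorted BAM (or SAM, converted on the
#'   fly) aligned against \code{reference}.
#' @param reference path to the reference FASTA (indexed, or indexable).
#' @param minMapq minimum mapping quality (default 20).
#' @param clipMask bases masked next to each clipped read end (default 3).
#' @param label \code{"direct"} or \code{"ivt"}.
#' @param replicate replicate identifier, e.g. \code{"rep1"}.
#' @return a [CountTable-class] with one row per covered U site.
#' @export
buildCountTable <- function(file, reference, minMapq = 20L, clipMask = 3L,
                            label = c("direct", "ivt"), replicate = "rep1") {
    label <- match.arg(label)
    bam <- ensureBam(file)
    fa <- openReference(reference)
    refNames <- as.character(GenomeInfoDb::seqnames(
        Rsamtools::seqinfo(fa)))

    param <- Rsamtools::ScanBamParam(
        what = c("flag", "rname", "strand", "pos", "mapq", "cigar", "seq"))
    b <- Rsamtools::scanBam(bam, param = param)[[1]]

    keep <- !is.na(b$pos) & filterAlignment(b$flag, b$mapq, minMapq)
    empty <- S4Vectors::DataFrame(
        contig = character(0), pos = integer(0), strand = character(0),
        depth = integer(0), nU = integer(0), nC = integer(0),
        nA = integer(0), nG = integer(0), nDel = integer(0),
        mismatch_frac = numeric(0))
    params <- list(file = file, reference = reference, minMapq = minMapq,
                   clipMask = clipMask)
    if (!any(keep))
        return(new("CountTable", sites = empty, label = label,
                   replicate = replicate, params = params))

    cig <- b$cigar[keep]
    pos <- b$pos[keep]
    seqs <- b$seq[keep]
    strand <- as.character(b$strand[keep])
    rname <- as.character(b$rname[keep])

    bad <- setdiff(unique(rname), refNames)
    if (length(bad))
        stop("contig(s) in alignments but not in reference FASTA: ",
             paste(bad, collapse = ", "))

    matchOps <- c("M", "=", "X")
    refR <- GenomicAlignments::cigarRangesAlongReferenceSpace(
        cig, ops = matchOps, pos = pos)
    qryR <- GenomicAlignments::cigarRangesAlongQuerySpace(
        cig, ops = matchOps)

    nOps <- S4Vectors::elementNROWS(refR)
    readPerOp <- rep(seq_along(cig), nOps)
    w <- unlist(IRanges::width(refR), use.names = FALSE)
    st <- unlist(IRanges::start(refR), use.names = FALSE)
    refpos <- sequence(w, from = st)              # 1-based, grouped by read
    readIdx <- rep(readPerOp, w)
    bases <- strsplit(paste(as.character(unlist(
        Biostrings::extractAt(seqs, qryR))), collapse = ""), "")[[1]]
    stopifnot(length(bases) == length(refpos))

    # clip-adjacent masking via per-read position thresholds
    clips <- .clipLengths(cig)
    alnPerRead <- as.integer(rowsum(w, readPerOp)[, 1L])
    off <- cumsum(c(0L, alnPerRead[-length(alnPerRead)]))
    leftThr <- rep(-1L, length(cig))
    rightThr <- rep(.Machine$integer.max, length(cig))
    if (clipMask > 0L) {
        hasL <- clips$left > 0L
        leftThr[hasL] <- refpos[off[hasL] +
                                pmin(clipMask, alnPerRead[hasL])]
        hasR <- clips$right > 0L
        rightThr[hasR] <- refpos[off[hasR] +
                                 pmax(1L, alnPerRead[hasR] - clipMask + 1L)]
    }
    maskedM <- refpos <= leftThr[readIdx] | refpos >= rightThr[readIdx]

    delR <- GenomicAlignments::cigarRangesAlongReferenceSpace(
        cig, ops = "D", pos = pos)
    dw <- unlist(IRanges::width(delR), use.names = FALSE)
    dst <- unlist(IRanges::start(delR), use.names = FALSE)
    delpos <- sequence(dw, from = dst)
    delReadIdx <- rep(rep(seq_along(cig), S4Vectors::elementNROWS(delR)), dw)
    maskedD <- delpos <= leftThr[delReadIdx] | delpos >= rightThr[delReadIdx]

    ev <- data.table::data.table(
        contig = c(rname[readIdx[!maskedM]], rname[delReadIdx[!maskedD]]),
        pos1 = c(refpos[!maskedM], delpos[!maskedD]),
        strand = c(strand[readIdx[!maskedM]], strand[delReadIdx[!maskedD]]),
        base = c(bases[!maskedM], rep("del", sum(!maskedD))))

    # transcript-space call: minus-strand reads are stored reverse
    # complemented in the BAM, so complement their plus-strand base
    minus <- ev$strand == "-" & ev$base != "del"
    ev$base[minus] <- .complementBase(ev$base[minus])
    ev <- ev[ev$base != "N", ]
    ev$base[ev$base == "T"] <- "U"

    tal <- ev[, list(n = .N), by = c("contig", "pos1", "strand", "base")]

    # restrict to transcript-space U sites on the read's own strand
    usite <- unique(tal[, c("contig", "pos1", "strand")])
    gr <- GenomicRanges::GRanges(usite$contig,
                                 IRanges::IRanges(usite$pos1, usite$pos1))
    refbase <- toupper(as.character(Biostrings::getSeq(fa, gr)))
    isU <- (usite$strand == "+" & refbase == "T") |
           (usite$strand == "-" & refbase == "A")
    usite <- usite[isU, ]
    tal <- tal[usite, on = c("contig", "pos1", "strand")]
    if (nrow(tal) == 0L)
        return(new("CountTable", sites = empty, label = label,
                   replicate = replicate, params = params))

    wide <- data.table::dcast(tal, contig + pos1 + strand ~ base,
                              value.var = "n", fill = 0L)
    for (col in c("U", "C", "A", "G", "del"))
        if (!col %in% colnames(wide)) wide[[col]] <- 0L
    data.table::setorderv(wide, c("contig", "pos1", "strand"))
    depth <- wide$U + wide$C + wide$A + wide$G + wide$del
    sites <- S4Vectors::DataFrame(
        contig = wide$contig, pos = wide$pos1 - 1L, strand = wide$strand,
        depth = as.integer(depth),
        nU = as.integer(wide$U), nC = as.integer(wide$C),
        nA = as.integer(wide$A), nG = as.integer(wide$G),
        nDel = as.integer(wide$del),
        mismatch_frac = wide$C / depth)
    new("CountTable", sites = sites, label = label,
        replicate = replicate, params = params)
}

#' Pool count tables of replicates from the same library type
#'
#' Element-wise sum of the per-site counts across replicates;
#' \code{mismatch_frac} is recomputed from the pooled counts (a pooled
#' fraction, not a mean of fractions).
#'
#' @param tables list of [CountTable-class] objects sharing a library
#'   label.
#' @return a merged [CountTable-class] with replicate id
#'   \code{"merged"}.
#' @export
mergeReplicates <- function(tables) {
    if (is(tables, "CountTable")) tables <- list(tables)
    if (length(tables) == 0L) stop("no tables to merge")
    labels <- unique(vapply(tables, libraryLabel, character(1)))
    if (length(labels) != 1L)
        stop("cannot merge tables with mixed library labels: ",
             paste(labels, collapse = ", "))
    if (length(tables) == 1L) return(tables[[1]])
    dt <- data.table::rbindlist(lapply(tables, function(t)
        as.data.frame(siteCounts(t))))
    agg <- dt[, lapply(.SD, sum), by = c("contig", "pos", "strand"),
              .SDcols = c("depth", "nU", "nC", "nA", "nG", "nDel")]
    data.table::setorderv(agg, c("contig", "pos", "strand"))
    sites <- S4Vectors::DataFrame(
        contig = agg$contig, pos = agg$pos, strand = agg$strand,
        depth = as.integer(agg$depth), nU = as.integer(agg$nU),
        nC = as.integer(agg$nC), nA = as.integer(agg$nA),
        nG = as.integer(agg$nG), nDel = as.integer(agg$nDel),
        mismatch_frac = agg$nC / agg$depth)
    new("CountTable", sites = sites, label = labels,
        replicate = "merged",
        params = list(merged_from = vapply(tables, replicateId,
                                           character(1))))
}

#' Write a count table as TSV
#'
#' Adds a 1-based position column alongside the internal 0-based one, and
#' the centered transcript-space 5-mer when a reference is supplied.
#'
#' @param x a [CountTable-class].
#' @param path output TSV path.
#' @param reference optional reference FASTA path for the kmer column.
#' @return the path, invisibly.
#' @export
writeCountTable <- function(x, path, reference = NULL) {
    s <- as.data.frame(siteCounts(x))
    kmer <- rep(NA_character_, nrow(s))
    if (!is.null(reference) && nrow(s) > 0L) {
        fa <- openReference(reference)
        kmer <- extractKmer(fa, s$contig, s$pos, s$strand)
    }
    out <- data.frame(contig = s$contig, pos0 = s$pos, pos1 = s$pos + 1L,
                      strand = s$strand, kmer = kmer, depth = s$depth,
                      nU = s$nU, nC = s$nC, nA = s$nA, nG = s$nG,
                      nDel = s$nDel, mismatch_frac = s$mismatch_frac)
    .writeTSV(out, path)
}
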