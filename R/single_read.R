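#' Read-by-site call matrix for one transcript
#'
#' For two or more called uridine sites of a single transcript, records
#' each filtered read's transcript-space call at each site: \code{"C"},
#' \code{"U"}, \code{"other"} (A/G/deletion) or \code{"uncovered"} when
#' the alignment does not span the position or the position is
#' clip-masked.  The same read-level filters as [buildCountTable()]
#' apply; reads covering no site are dropped.  Sites are ordered 5' to 3'
#' along the transcript (position 1 = 5'-most).
#'
#' @param bam BAM or SAM path.
#' @param contig contig of the transcript.
#' @param positions 0-based genomic site positions (length >= 2).
#' @param strand transcribed strand of all sites.
#' @param transcript_id label for the matrix.
#' @param minMapq,clipMask read filters as in [buildCountTable()].
#' @return a [ReadSiteMatrix-class].
#' @export
buildReadSiteMatrix <- function(bam, contig, positions, strand,
                                transcript_id = "tx", minMapq = 20L,
                                clipMask = 3L) {
    if (length(positions) < 2L)
        stop("at least two sites are required")
    if (length(strand) > 1L && length(unique(strand)) > 1L)
        stop("sites on mixed strands within one transcript")
    strand <- strand[1]
    o <- if (strand == "+") order(positions) else order(-positions)
    positions <- positions[o]
    pos1 <- positions + 1L

    bam <- ensureBam(bam)
    which <- GenomicRanges::GRanges(
        contig, IRanges::IRanges(min(pos1), max(pos1)))
    param <- Rsamtools::ScanBamParam(
        what = c("qname", "flag", "strand", "pos", "mapq", "cigar", "seq"),
        which = which)
    b <- Rsamtools::scanBam(bam, param = param)[[1]]
    keep <- !is.na(b$pos) &
        filterAlignment(b$flag, b$mapq, minMapq) &
        as.character(b$strand) == strand
    nRead <- sum(keep)
    sitesDf <- S4Vectors::DataFrame(contig = rep(contig, length(positions)),
                                    pos = positions,
                                    strand = rep(strand, length(positions)))
    if (nRead == 0L)
        return(new("ReadSiteMatrix", transcript_id = transcript_id,
                   sites = sitesDf,
                   calls = matrix(character(0), 0L, length(positions))))

    cig <- b$cigar[keep]; pos <- b$pos[keep]; seqs <- b$seq[keep]
    qname <- b$qname[keep]
    calls <- matrix("uncovered", nRead, length(positions),
                    dimnames = list(qname, NULL))
    clips <- .clipLengths(cig)
    for (i in seq_len(nRead)) {
        refR <- GenomicAlignments::cigarRangesAlongReferenceSpace(
            cig[i], ops = c("M", "=", "X"), pos = pos[i])[[1]]
        qryR <- GenomicAlignments::cigarRangesAlongQuerySpace(
            cig[i], ops = c("M", "=", "X"))[[1]]
        rp <- sequence(IRanges::width(refR), from = IRanges::start(refR))
        qp <- sequence(IRanges::width(qryR), from = IRanges::start(qryR))
        masked <- maskClipAdjacent(rp, clips$left[i], clips$right[i],
                                   clipMask)
        delR <- GenomicAlignments::cigarRangesAlongReferenceSpace(
            cig[i], ops = "D", pos = pos[i])[[1]]
        dp <- sequence(IRanges::width(delR), from = IRanges::start(delR))
        for (j in seq_along(pos1)) {
            p <- pos1[j]
            if (p %in% masked) next
            k <- match(p, rp)
            if (!is.na(k)) {
                base <- substr(as.character(seqs[[i]]), qp[k], qp[k])
                if (strand == "-") base <- .complementBase(base)
                calls[i, j] <- switch(base, "T" = "U", "U" = "U",
                                      "C" = "C", "N" = "uncovered",
                                      "other")
            } else if (p %in% dp) {
                calls[i, j] <- "other"
            }
        }
    }
    covered <- rowSums(calls != "uncovered") > 0L
    new("ReadSiteMatrix", transcript_id = transcript_id, sites = sitesDf,
        calls = calls[covered, , drop = FALSE])
}

#' Single-read co-modification fraction for a site pair
#'
#' Among reads covering both sites, the fraction calling C at both
#' positions, together with the marginal C fractions among the same
#' co-covering reads.  Denominators count all co-covering reads
#' regardless of call, matching the pileup \code{mismatch_frac}
#' convention.
#'
#' @param x a [ReadSiteMatrix-class].
#' @param i,j site column indices (default first pair).
#' @return list with \code{n_cocover}, \code{marginal_i},
#'   \code{marginal_j} and \code{comod_fraction} (all \code{NA} except
#'   the zero count when no read covers both sites).
#' @export
comodFraction <- function(x, i = 1L, j = 2L) {
    m <- readCalls(x)
    co <- m[, i] != "uncovered" & m[, j] != "uncovered"
    n <- sum(co)
    if (n == 0L)
        return(list(n_cocover = 0L, marginal_i = NA_real_,
                    marginal_j = NA_real_, comod_fraction = NA_real_))
    list(n_cocover = n,
         marginal_i = sum(m[co, i] == "C") / n,
         marginal_j = sum(m[co, j] == "C") / n,
         comod_fraction = sum(m[co, i] == "C" & m[co, j] == "C") / n)
}

#' Correlation of mismatch between the two sites of 2-site transcripts
#'
#' Ordinary-least-squares coefficient of determination between the
#' merged mismatch fraction at position 1 (the 5'-most site) and
#' position 2 across transcripts carrying exactly two highly significant
#' sites.  Independent per-site errors give an R-squared near zero.
#'
#' @param mismatch1,mismatch2 per-transcript merged mismatch fractions.
#' @return R-squared, or \code{NA} with fewer than 3 transcripts or
#'   degenerate (zero-variance) input.
#' @export
pairwiseMismatchCorrelation <- function(mismatch1, mismatch2) {
    ok <- is.finite(mismatch1) & is.finite(mismatch2)
    x <- mismatch1[ok]; y <- mismatch2[ok]
    if (length(x) < 3L) return(NA_real_)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)^2
}

#' Write a read-site matrix and its pair statistics as TSV
#'
#' @param x a [ReadSiteMatrix-class].
#' @param prefix output path prefix; writes
#'   \code{<prefix>_matrix.tsv} and \code{<prefix>_pairs.tsv}.
#' @return the files written, invisibly.
#' @export
writeReadSiteMatrix <- function(x, prefix) {
    m <- readCalls(x)
    s <- x@sites
    mat_tsv <- paste0(prefix, "_matrix.tsv")
    out <- data.frame(read_id = rownames(m), m, check.names = FALSE)
    colnames(out) <- c("read_id", .siteName1(s$contig, s$pos))
    .writeTSV(out, mat_tsv)
    pairs <- expand.grid(i = seq_len(ncol(m)), j = seq_len(ncol(m)))
    pairs <- pairs[pairs$i < pairs$j, , drop = FALSE]
    stats <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
        cf <- comodFraction(x, pairs$i[r], pairs$j[r])
        data.frame(site_i = .siteName1(s$contig, s$pos)[pairs$i[r]],
                   site_j = .siteName1(s$contig, s$pos)[pairs$j[r]],
                   n_cocover = cf$n_cocover, marginal_i = cf$marginal_i,
                   marginal_j = cf$marginal_j,
                   comod_fraction = cf$comod_fraction)
    }))
    pair_tsv <- paste0(prefix, "_pairs.tsv")
    .writeTSV(stats, pair_tsv)
    invisible(c(mat_tsv, pair_tsv))
}
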