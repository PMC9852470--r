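.validTranscriptModel <- function(object) {
    msg <- NULL
    ex <- object@exons
    if (!is.matrix(ex) || ncol(ex) != 2L)
        msg <- c(msg, "exons must be a 2-column (start0, end0) matrix")
    else if (nrow(ex) > 0L) {
        if (any(ex[, 2] <= ex[, 1]))
            msg <- c(msg, "exon end must exceed start (0-based half-open)")
        if (is.unsorted(ex[, 1], strictly = TRUE) && nrow(ex) > 1L)
            msg <- c(msg, "exons must be sorted by genomic start")
        if (nrow(ex) > 1L && any(ex[-1L, 1] < ex[-nrow(ex), 2]))
            msg <- c(msg, "exons must not overlap")
    }
    if (!(object@strand %in% c("+", "-")))
        msg <- c(msg, "strand must be '+' or '-'")
    if (is.null(msg)) TRUE else msg
}

#' Exon/CDS model of a single annotated transcript
#'
#' Exons are 0-based half-open genomic intervals sorted by genomic start;
#' the CDS bounds are genomic and \code{NA} for non-coding transcripts.
#'
#' @slot transcript_id,gene_id annotation identifiers.
#' @slot contig reference sequence name.
#' @slot strand transcribed strand.
#' @slot exons numeric matrix of (start0, end0) rows.
#' @slot cdsStart,cdsEnd genomic CDS bounds (0-based half-open), NA if
#'   non-coding.
#' @export
setClass("TranscriptModel",
    representation(transcript_id = "character", gene_id = "character",
                   contig = "character", strand = "character",
                   exons = "matrix", cdsStart = "numeric",
                   cdsEnd = "numeric"),
    prototype(cdsStart = NA_real_, cdsEnd = NA_real_),
    validity = .validTranscriptModel)

#' @describeIn TranscriptModel-class constructor
#' @param transcript_id,gene_id,contig,strand,exonStarts,exonEnds,cdsStart,cdsEnd
#'   model fields; exon coordinates are 0-based half-open.
#' @export
transcriptModel <- function(transcript_id, gene_id = transcript_id, contig,
                            strand, exonStarts, exonEnds,
                            cdsStart = NA_real_, cdsEnd = NA_real_) {
    o <- order(exonStarts)
    new("TranscriptModel", transcript_id = transcript_id,
        gene_id = gene_id, contig = contig, strand = strand,
        exons = cbind(start = as.numeric(exonStarts[o]),
                      end = as.numeric(exonEnds[o])),
        cdsStart = as.numeric(cdsStart), cdsEnd = as.numeric(cdsEnd))
}

#' @describeIn TranscriptModel-class spliced transcript length (nt)
#' @param x a \code{TranscriptModel}
#' @export
txLength <- function(x) sum(x@exons[, 2] - x@exons[, 1])

setMethod("show", "TranscriptModel", function(object) {
    cds <- if (is.na(object@cdsStart)) "non-coding" else
        paste0("CDS ", object@cdsStart, "-", object@cdsEnd)
    cat("TranscriptModel", object@transcript_id, "(", object@gene_id, ")",
        object@contig, object@strand, nrow(object@exons), "exon(s),",
        txLength(object), "nt,", cds, "\n")
})

#' Load transcript models from a GTF annotation
#'
#' Reads an Ensembl-dialect GTF (exon and CDS features carrying
#' \code{transcript_id} / \code{gene_id} attributes) and returns a named
#' list of [TranscriptModel-class] objects.
#'
#' @param path GTF file path.
#' @return named list of \code{TranscriptModel}s.
#' @export
loadTranscriptModels <- function(path) {
    g <- rtracklayer::import(path, format = "gtf")
    if (!all(c("transcript_id", "gene_id") %in%
             colnames(S4Vectors::mcols(g))))
        stop("GTF must carry transcript_id and gene_id attributes")
    ex <- g[g$type == "exon"]
    cds <- g[g$type == "CDS"]
    models <- list()
    for (tx in unique(ex$transcript_id)) {
        e <- ex[ex$transcript_id == tx]
        cc <- cds[cds$transcript_id == tx]
        cs <- if (length(cc)) min(GenomicRanges::start(cc)) - 1 else NA_real_
        ce <- if (length(cc)) max(GenomicRanges::end(cc)) else NA_real_
        models[[tx]] <- transcriptModel(
            transcript_id = tx, gene_id = e$gene_id[1],
            contig = as.character(GenomicRanges::seqnames(e))[1],
            strand = as.character(GenomicRanges::strand(e))[1],
            exonStarts = GenomicRanges::start(e) - 1,
            exonEnds = GenomicRanges::end(e),
            cdsStart = cs, cdsEnd = ce)
    }
    models
}

# genomic 0-based position -> 0-based transcript coordinate; NA if intronic
.txCoord <- function(model, pos) {
    ex <- model@exons
    widths <- ex[, 2] - ex[, 1]
    if (model@strand == "+") {
        cum <- cumsum(c(0, widths[-length(widths)]))
        i <- which(pos >= ex[, 1] & pos < ex[, 2])
        if (length(i) == 0L) return(NA_real_)
        cum[i] + (pos - ex[i, 1])
    } else {
        rw <- rev(widths)
        cum <- cumsum(c(0, rw[-length(rw)]))
        ri <- which(pos >= ex[, 1] & pos < ex[, 2])
        if (length(ri) == 0L) return(NA_real_)
        j <- nrow(ex) - ri + 1L       # exon rank in transcript order
        cum[j] + (ex[ri, 2] - 1 - pos)
    }
}

#' Place a site on transcript anatomy
#'
#' Assigns a genomic U site to the 5'UTR, CDS or 3'UTR of a transcript
#' model (region \code{noncoding} for transcripts without a CDS) and
#' reports the distance, in spliced transcript coordinates, to the
#' nearest exon-exon junction (\code{NA} for single-exon transcripts).
#'
#' @param pos 0-based genomic position of the site.
#' @param model a [TranscriptModel-class].
#' @return list with elements \code{region} and \code{splice_distance}.
#' @examples
#' m <- transcriptModel("tx1", "g1", "chr1", "+",
#'                      c(100, 300), c(200, 400), 150, 350)
#' assignRegion(160, m)  # CDS, splice distance 40
#' @export
assignRegion <- function(pos, model) {
    txpos <- .txCoord(model, pos)
    if (is.na(txpos))
        stop("site ", pos, " is intronic in ", model@transcript_id,
             " (model/assignment mismatch)")
    widths <- model@exons[, 2] - model@exons[, 1]
    if (model@strand == "-") widths <- rev(widths)
    n <- length(widths)
    sd <- if (n < 2L) NA_real_ else {
        bounds <- cumsum(widths[-n])
        min(abs(txpos - bounds))
    }
    region <- "noncoding"
    if (!is.na(model@cdsStart)) {
        csTx <- .txCoord(model, if (model@strand == "+") model@cdsStart
                                else model@cdsEnd - 1)
        ceTx <- .txCoord(model, if (model@strand == "+") model@cdsEnd - 1
                                else model@cdsStart)
        region <- if (txpos < csTx) "5UTR"
                  else if (txpos > ceTx) "3UTR"
                  else "CDS"
    }
    list(region = region, splice_distance = sd)
}

#' Tag a 5-mer with its pseudouridine-synthase motif
#'
#' \code{UGUAG} is the PUS7 recognition motif and \code{GUUCN} the TRUB1
#' motif; everything else is \code{other}.
#'
#' @param kmer character vector of center-U 5-mers.
#' @return character vector in \{PUS7, TRUB1, other\}.
#' @export
motifTag <- function(kmer) {
    if (any(substr(kmer, 3, 3) != "U", na.rm = TRUE))
        stop("motifTag expects center-U 5-mers")
    out <- rep("other", length(kmer))
    out[kmer == "UGUAG"] <- "PUS7"
    out[grepl("^GUUC[ACGU]$", kmer)] <- "TRUB1"
    out
}

#' Hypermodification type I classification
#'
#' A consensus site is hypermodified type I when its merged direct
#' U-to-C mismatch exceeds the cutoff (strictly greater than 40\% by
#' default): given the basecaller's systematic under-calling, such sites
#' correspond to occupancies of roughly one half and above.
#'
#' @param mergedMismatch merged direct mismatch fraction (vector).
#' @param cutoff mismatch cutoff (default 0.40, strict).
#' @return logical vector.
#' @export
classifyType1 <- function(mergedMismatch, cutoff = 0.40) {
    mergedMismatch > cutoff
}

#' Hypermodification type II classification per transcript
#'
#' Counts the unique highly significant (p <= 0.001 under the consensus
#' quorum) site positions per transcript; a transcript is type II when it
#' carries two or more.
#'
#' @param transcript_id,pos,tier parallel vectors describing annotated
#'   calls (one element per call).
#' @return \code{data.frame} per transcript with \code{n_high_sites} and
#'   \code{type2}, plus the histogram of transcripts by site count as
#'   attribute \code{"histogram"}.
#' @export
classifyType2 <- function(transcript_id, pos, tier) {
    keep <- tier == "highly_significant" & !is.na(transcript_id)
    dt <- data.table::data.table(tx = transcript_id[keep], pos = pos[keep])
    if (nrow(dt) == 0L) {
        out <- data.frame(transcript_id = character(0),
                          n_high_sites = integer(0), type2 = logical(0))
        attr(out, "histogram") <- data.frame(n_sites = integer(0),
                                             n_transcripts = integer(0))
        return(out)
    }
    agg <- dt[, list(n_high_sites = length(unique(pos))), by = "tx"]
    out <- data.frame(transcript_id = agg$tx,
                      n_high_sites = agg$n_high_sites,
                      type2 = agg$n_high_sites >= 2L)
    h <- table(out$n_high_sites)
    attr(out, "histogram") <- data.frame(
        n_sites = as.integer(names(h)),
        n_transcripts = as.integer(h))
    out
}

#' 5-mer frequencies among selected calls
#'
#' @param kmer character vector of call 5-mers.
#' @return \code{data.frame} of (kmer, count, fraction), sorted by
#'   descending count; fractions sum to 1.
#' @export
kmerFrequency <- function(kmer) {
    kmer <- kmer[!is.na(kmer)]
    if (length(kmer) == 0L)
        return(data.frame(kmer = character(0), count = integer(0),
                          fraction = numeric(0)))
    t <- sort(table(kmer), decreasing = TRUE)
    data.frame(kmer = names(t), count = as.integer(t),
               fraction = as.integer(t) / length(kmer))
}

#' Position frequency matrix of the sequence context around called sites
#'
#' Counts bases at every offset within \code{flank} nt of the called U in
#' transcript orientation (13-nt window for the default flank of 6).
#' Sites without full flanks or with an N in the window are dropped;
#' every column of the returned matrix sums to the number of sites used
#' and the center column is all U.
#'
#' @param reference FASTA path or \code{FaFile}.
#' @param contig,pos,strand call site vectors (\code{pos} 0-based).
#' @param flank half-window in nt (default 6).
#' @return 4 x (2*flank+1) integer matrix with rows A, C, G, U and
#'   column names the offsets -flank..flank.
#' @export
positionFrequencyMatrix <- function(reference, contig, pos, strand,
                                    flank = 6L) {
    fa <- if (is.character(reference)) openReference(reference) else reference
    si <- Rsamtools::seqinfo(fa)
    clen <- GenomeInfoDb::seqlengths(si)[as.character(contig)]
    pos1 <- pos + 1L
    ok <- !is.na(clen) & pos1 - flank >= 1L & pos1 + flank <= clen
    w <- 2L * flank + 1L
    pfm <- matrix(0L, 4L, w,
                  dimnames = list(c("A", "C", "G", "U"),
                                  as.character(seq(-flank, flank))))
    if (!any(ok)) return(pfm)
    gr <- GenomicRanges::GRanges(
        contig[ok], IRanges::IRanges(pos1[ok] - flank, pos1[ok] + flank),
        strand = strand[ok])
    ctx <- .toRNA(as.character(Biostrings::getSeq(fa, gr)))
    ctx <- ctx[!grepl("N", ctx)]
    for (s in ctx) {
        b <- strsplit(s, "")[[1]]
        for (j in seq_len(w)) pfm[b[j], j] <- pfm[b[j], j] + 1L
    }
    pfm
}

# all aligned blocks inside exons, all junction gaps matching introns
.readCompatible <- function(blockStarts0, blockEnds0, model) {
    ex <- model@exons
    inExon <- vapply(seq_along(blockStarts0), function(i)
        any(blockStarts0[i] >= ex[, 1] & blockEnds0[i] <= ex[, 2]),
        logical(1))
    if (!all(inExon)) return(FALSE)
    nb <- length(blockStarts0)
    if (nb > 1L) {
        introns <- cbind(ex[-nrow(ex), 2], ex[-1L, 1])
        for (i in seq_len(nb - 1L)) {
            gapS <- blockEnds0[i]; gapE <- blockStarts0[i + 1L]
            if (gapE > gapS &&
                !any(introns[, 1] == gapS & introns[, 2] == gapE))
                return(FALSE)
        }
    }
    TRUE
}

#' Dominant isoform at a site by read compatibility
#'
#' Among annotated transcripts overlapping a called site, returns the one
#' supported by the most site-covering reads whose aligned blocks are
#' compatible with its exon chain (blocks inside exons, junction gaps
#' matching introns).  Ties break to the longest transcript, then to the
#' lexicographically smallest identifier.
#'
#' @param bam BAM/SAM path of the direct library.
#' @param models list of [TranscriptModel-class] candidates.
#' @param contig,pos,strand the site (0-based \code{pos}).
#' @param minMapq read filter as in [buildCountTable()].
#' @return the winning \code{TranscriptModel}, or \code{NULL} when no
#'   candidate overlaps the site.
#' @export
dominantIsoform <- function(bam, models, contig, pos, strand,
                            minMapq = 20L) {
    cand <- Filter(function(m) m@contig == contig &&
                       m@strand == strand &&
                       !is.na(.txCoord(m, pos)), models)
    if (length(cand) == 0L) return(NULL)
    if (length(cand) > 1L && !is.null(bam)) {
        bam <- ensureBam(bam)
        which <- GenomicRanges::GRanges(contig,
                                        IRanges::IRanges(pos + 1L, pos + 1L))
        gal <- GenomicAlignments::readGAlignments(
            bam, param = Rsamtools::ScanBamParam(
                which = which,
                what = c("flag", "mapq")))
        keep <- filterAlignment(S4Vectors::mcols(gal)$flag,
                                S4Vectors::mcols(gal)$mapq, minMapq) &
                as.character(GenomicAlignments::strand(gal)) == strand
        gal <- gal[keep]
        blocks <- GenomicAlignments::grglist(gal)
        support <- vapply(cand, function(m) {
            sum(vapply(seq_along(blocks), function(i) {
                b <- blocks[[i]]
                .readCompatible(GenomicRanges::start(b) - 1,
                                GenomicRanges::end(b), m)
            }, logical(1)))
        }, numeric(1))
    } else support <- rep(0, length(cand))
    lens <- vapply(cand, txLength, numeric(1))
    ids <- vapply(cand, function(m) m@transcript_id, character(1))
    o <- order(-support, -lens, ids)
    cand[[o[1]]]
}

#' Annotate consensus calls with transcript anatomy and motifs
#'
#' For every consensus site, resolves the dominant isoform (majority of
#' compatible covering reads when a BAM is given, longest-transcript
#' tie-break otherwise), assigns 5'UTR/CDS/3'UTR/noncoding region and
#' splice distance, tags the synthase motif, and classifies type I
#' hypermodification.  Sites without an overlapping model are reported
#' with \code{transcript_id} NA.
#'
#' @param x a [ModCallSet-class].
#' @param models named list of [TranscriptModel-class] (see
#'   [loadTranscriptModels()]).
#' @param bam optional direct-library BAM for dominant-isoform support.
#' @param type1Cutoff mismatch cutoff for type I (default 0.40).
#' @return \code{data.frame} of consensus calls with columns
#'   \code{transcript_id}, \code{gene_id}, \code{region},
#'   \code{splice_distance}, \code{motif}, \code{type1} added.
#' @export
annotateCalls <- function(x, models, bam = NULL, type1Cutoff = 0.40) {
    cl <- as.data.frame(modCalls(x)[, setdiff(colnames(modCalls(x)),
                                              "pvalues")])
    cl <- cl[cl$consensus, , drop = FALSE]
    n <- nrow(cl)
    cl$transcript_id <- rep(NA_character_, n)
    cl$gene_id <- rep(NA_character_, n)
    cl$region <- rep(NA_character_, n)
    cl$splice_distance <- rep(NA_real_, n)
    if (n > 0L) for (i in seq_len(n)) {
        m <- dominantIsoform(bam, models, cl$contig[i], cl$pos[i],
                             cl$strand[i])
        if (is.null(m)) next
        cl$transcript_id[i] <- m@transcript_id
        cl$gene_id[i] <- m@gene_id
        r <- assignRegion(cl$pos[i], m)
        cl$region[i] <- r$region
        cl$splice_distance[i] <- r$splice_distance
    }
    cl$motif <- if (n) motifTag(cl$kmer) else character(0)
    cl$type1 <- classifyType1(cl$merged_mismatch, type1Cutoff)
    cl
}
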