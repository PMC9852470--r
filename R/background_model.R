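#' Centered transcript-space 5-mer at a uridine site
#'
#' Returns the 5-nt sequence context read 5' to 3' in transcript
#' orientation with the candidate U at the center; minus-strand sites are
#' reverse complemented.  Sites within 2 nt of a contig end or with an N
#' in the window return \code{NA} (skipped downstream).
#'
#' @param fa an \code{Rsamtools::FaFile} (see [openReference()]) or a
#'   FASTA path.
#' @param contig,pos,strand vectors describing the sites; \code{pos} is
#'   0-based.
#' @return character vector of 5-mers over \{A,C,G,U\}, \code{NA} where
#'   the context is unavailable.
#' @export
extractKmer <- function(fa, contig, pos, strand) {
    if (is.character(fa)) fa <- openReference(fa)
    si <- Rsamtools::seqinfo(fa)
    clen <- GenomeInfoDb::seqlengths(si)[as.character(contig)]
    pos1 <- pos + 1L
    out <- rep(NA_character_, length(pos))
    ok <- !is.na(clen) & pos1 >= 3L & pos1 <= clen - 2L
    if (any(ok)) {
        gr <- GenomicRanges::GRanges(
            contig[ok], IRanges::IRanges(pos1[ok] - 2L, pos1[ok] + 2L),
            strand = strand[ok])
        km <- toupper(as.character(Biostrings::getSeq(fa, gr)))  # strand-aware
        km[grepl("N", km)] <- NA_character_
        out[ok] <- .toRNA(km)
    }
    bad <- !is.na(out) & substr(out, 3, 3) != "U"
    if (any(bad))
        stop("center base is not U at ",
             paste(.siteName1(contig[bad], pos[bad]), collapse = ", "),
             " (caller bug: sites must be transcript-space U)")
    out
}

#' Estimate the per-5-mer background U-to-C error from the IVT control
#'
#' Pools (read-weighted) the U-to-C mismatch over every IVT uridine site
#' of each center-U 5-mer with at least \code{minSiteDepth} reads, and
#' records a global pooled error over all qualifying sites as the
#' fallback for sparse k-mers.
#'
#' @param ivtTable a [CountTable-class] with label \code{"ivt"}
#'   (replicates merged beforehand with [mergeReplicates()]).
#' @param reference reference FASTA path or \code{FaFile}.
#' @param minSiteDepth minimum site depth to contribute (default 7).
#' @param minKmerSites minimum contributing sites for a k-mer estimate to
#'   be used downstream instead of the global fallback (default 10).
#' @return a [KmerBackground-class].
#' @export
buildKmerTable <- function(ivtTable, reference, minSiteDepth = 7L,
                           minKmerSites = 10L) {
    if (libraryLabel(ivtTable) != "ivt")
        stop("background model must be built from an IVT table")
    s <- as.data.frame(siteCounts(ivtTable))
    if (nrow(s) == 0L) stop("empty IVT count table")
    s <- s[s$depth >= minSiteDepth, ]
    if (nrow(s) == 0L) stop("no IVT site reaches minSiteDepth")
    fa <- if (is.character(reference)) openReference(reference) else reference
    s$kmer <- extractKmer(fa, s$contig, s$pos, s$strand)
    s <- s[!is.na(s$kmer), ]
    dt <- data.table::as.data.table(s)
    tab <- dt[, list(n_sites = .N, n_reads = sum(depth),
                     pooled_error = sum(nC) / sum(depth)), by = "kmer"]
    data.table::setorderv(tab, "kmer")
    new("KmerBackground",
        table = S4Vectors::DataFrame(as.data.frame(tab)),
        global_error = sum(s$nC) / sum(s$depth),
        total_reads = sum(s$depth),
        params = list(minSiteDepth = minSiteDepth,
                      minKmerSites = minKmerSites))
}

#' Expected unmodified U-to-C error p0 for candidate sites
#'
#' The null error a site is tested against is the maximum of the k-mer
#' background (global fallback when the k-mer has too few contributing
#' sites), the site-specific IVT error when the IVT covers the site with
#' at least \code{minIvtDepth} reads, and a small floor
#' \eqn{1/(n_{reads}+2)} that keeps the binomial test non-degenerate.
#' Taking the maximum means a site whose IVT control itself mismatches is
#' tested against its own elevated error rather than the k-mer average.
#'
#' @param kmer character vector of centered 5-mers (NA allowed).
#' @param background a [KmerBackground-class].
#' @param ivtError per-site IVT mismatch fraction (NA if uncovered).
#' @param ivtDepth per-site merged IVT depth (0 if uncovered).
#' @param minIvtDepth minimum IVT depth for the site term (default 7).
#' @return \code{DataFrame} with columns \code{p0} and \code{source}
#'   (\code{kmer_avg}, \code{site_ivt} or \code{global_fallback}).
#' @export
expectedError <- function(kmer, background, ivtError = NA_real_,
                          ivtDepth = 0L, minIvtDepth = 7L) {
    n <- length(kmer)
    ivtError <- rep_len(ivtError, n)
    ivtDepth <- rep_len(ivtDepth, n)
    tab <- kmerTable(background)
    minKmerSites <- background@params$minKmerSites
    if (is.null(minKmerSites)) minKmerSites <- 10L
    idx <- match(kmer, tab$kmer)
    useKmer <- !is.na(idx) & tab$n_sites[pmax(idx, 1L)] >= minKmerSites
    kmerErr <- ifelse(useKmer, tab$pooled_error[pmax(idx, 1L)],
                      globalError(background))
    kmerReads <- ifelse(useKmer, tab$n_reads[pmax(idx, 1L)],
                        background@total_reads)
    floorErr <- 1 / (kmerReads + 2)
    siteErr <- ifelse(!is.na(ivtError) & ivtDepth >= minIvtDepth,
                      ivtError, -Inf)
    p0 <- pmax(kmerErr, siteErr, floorErr)
    source <- ifelse(siteErr >= kmerErr & is.finite(siteErr), "site_ivt",
                     ifelse(useKmer, "kmer_avg", "global_fallback"))
    S4Vectors::DataFrame(p0 = p0, source = source)
}

#' Flag SNP-like sites by equivalent mismatch in direct and IVT
#'
#' A genomic variant shows the same apparent U-to-C "mismatch" in the
#' modification-free IVT control as in the direct library.  A site is
#' flagged when the IVT mismatch fraction is at least \code{minIvtFrac}
#' and a two-proportion z-test finds no significant difference between
#' the direct and IVT fractions.  Flagged sites are excluded from
#' modification calling.
#'
#' @param directDepth,directC direct depth and C count (vectors).
#' @param ivtDepth,ivtC IVT depth and C count.
#' @param minIvtFrac minimum IVT mismatch for a site to look SNP-like
#'   (default 0.20).
#' @param alpha significance level of the equality test (default 0.05).
#' @return logical vector.
#' @export
flagSNP <- function(directDepth, directC, ivtDepth, ivtC,
                    minIvtFrac = 0.20, alpha = 0.05) {
    p1 <- directC / directDepth
    p2 <- ivtC / ivtDepth
    pool <- (directC + ivtC) / (directDepth + ivtDepth)
    se <- sqrt(pool * (1 - pool) * (1 / directDepth + 1 / ivtDepth))
    z <- ifelse(se > 0, (p1 - p2) / se, 0)
    pval <- 2 * stats::pnorm(-abs(z))
    ok <- directDepth >= 7L & ivtDepth >= 7L
    ok & p2 >= minIvtFrac & pval > alpha
}
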