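#' Binomial upper-tail significance of an observed U-to-C mismatch
#'
#' Probability of observing at least \code{Nmm} U-to-C mismatches among
#' \code{N} reads when every read independently mismatches with the
#' expected unmodified error \code{p0}:
#' \deqn{p(N, N_{mm}, p_0) = \sum_{k=N_{mm}}^{N} \binom{N}{k} p_0^k (1-p_0)^{N-k}}
#' Computed through the survival function of the binomial distribution
#' (regularized incomplete beta route), numerically stable up to
#' coverages of 1e6 and beyond.
#'
#' @param N read depth at the site (vector ok).
#' @param Nmm observed C calls at the site.
#' @param p0 expected unmodified mismatch probability.
#' @return upper-tail probability in [0, 1]; \code{P[X >= 0]} is exactly 1.
#' @examples
#' binomialPValue(50, 0, 0.05)   # 1
#' binomialPValue(20, 10, 0.05)  # ~1.6e-8
#' @export
binomialPValue <- function(N, Nmm, p0) {
    if (any(Nmm < 0 | Nmm > N))
        stop("Nmm must satisfy 0 <= Nmm <= N")
    if (any(p0 < 0 | p0 > 1))
        stop("p0 must lie in [0, 1]")
    stats::pbinom(Nmm - 1, N, p0, lower.tail = FALSE)
}

#' Score sites against p0 and apply the replicate-consensus rule
#'
#' Per-replicate binomial tail p-values are combined by requiring the
#' quorum \eqn{k = \lceil f \cdot R \rceil} of the \eqn{R} direct
#' replicates at \eqn{p \le 0.01} (2-of-3 for three replicates).  The
#' significance tier is set from the k-th smallest replicate p-value, so
#' \code{highly_significant} requires the same quorum at
#' \eqn{p \le 0.001}.  Sites where any replicate (or the merged IVT,
#' enforced by the caller) has fewer than \code{minDepth} reads are
#' ineligible and reported as \code{low_coverage}; SNP-flagged sites are
#' never consensus.
#'
#' @param depth,nC integer matrices, sites x replicates.
#' @param p0 per-site expected error vector.
#' @param snp logical vector of SNP flags (default all FALSE).
#' @param minDepth minimum reads per replicate (default 7).
#' @param pSig consensus p-value cutoff (default 0.01, inclusive).
#' @param pHigh highly-significant cutoff (default 0.001, inclusive).
#' @param consensusFrac required replicate fraction (default 2/3).
#' @return \code{DataFrame} with matrix column \code{pvalues} and columns
#'   \code{consensus}, \code{tier}, \code{merged_mismatch},
#'   \code{merged_depth}, \code{reason}.
#' @export
callSites <- function(depth, nC, p0, snp = NULL, minDepth = 7L,
                      pSig = 0.01, pHigh = 0.001, consensusFrac = 2 / 3) {
    depth <- as.matrix(depth); nC <- as.matrix(nC)
    R <- ncol(depth)
    if (R == 0L) stop("at least one direct replicate is required")
    if (is.null(snp)) snp <- rep(FALSE, nrow(depth))
    k <- ceiling(consensusFrac * R)

    pv <- matrix(1, nrow(depth), R)
    for (j in seq_len(R))
        pv[, j] <- binomialPValue(depth[, j], nC[, j], p0)
    kth <- apply(pv, 1L, function(x) sort(x)[k])
    eligible <- rowSums(depth >= minDepth) == R
    consensus <- eligible & !snp & kth <= pSig
    tier <- rep("not_significant", nrow(depth))
    tier[consensus & kth <= pSig] <- "significant"
    tier[consensus & kth <= pHigh] <- "highly_significant"
    reason <- rep("", nrow(depth))
    reason[!eligible] <- "low_coverage"
    reason[eligible & snp] <- "snp"
    md <- rowSums(depth)
    S4Vectors::DataFrame(
        pvalues = I(pv), consensus = consensus, tier = tier,
        merged_mismatch = rowSums(nC) / pmax(md, 1L),
        merged_depth = as.integer(md), reason = reason)
}

#' Transcriptome-wide uridine-modification detection
#'
#' Orchestrates the full caller: merges the IVT replicates, fits the
#' per-5-mer background model, derives the expected error p0 for every
#' uridine site covered by the direct libraries, flags SNP-like sites,
#' scores each direct replicate with the binomial tail test and applies
#' the replicate-consensus rule.  Deterministic given its inputs.
#'
#' @param directTables list of direct [CountTable-class] replicates.
#' @param ivtTables list of IVT [CountTable-class] replicates.
#' @param reference reference FASTA path.
#' @param minDepth minimum reads per replicate and for the merged IVT
#'   (default 7).
#' @param pSig,pHigh,consensusFrac see [callSites()].
#' @param snpMinIvtFrac,snpAlpha see [flagSNP()].
#' @param minKmerSites,minSiteDepth see [buildKmerTable()].
#' @return a [ModCallSet-class].
#' @export
detectModifications <- function(directTables, ivtTables, reference,
                                minDepth = 7L, pSig = 0.01, pHigh = 0.001,
                                consensusFrac = 2 / 3,
                                snpMinIvtFrac = 0.20, snpAlpha = 0.05,
                                minKmerSites = 10L, minSiteDepth = 7L) {
    if (is(directTables, "CountTable")) directTables <- list(directTables)
    if (is(ivtTables, "CountTable")) ivtTables <- list(ivtTables)
    if (length(directTables) == 0L) stop("at least one direct replicate required")
    if (length(ivtTables) == 0L) stop("at least one IVT replicate required")

    ivt <- mergeReplicates(ivtTables)
    bg <- buildKmerTable(ivt, reference, minSiteDepth = minSiteDepth,
                         minKmerSites = minKmerSites)
    fa <- openReference(reference)

    # site universe: any U site covered by any direct replicate
    dsites <- unique(data.table::rbindlist(lapply(directTables, function(t)
        as.data.frame(siteCounts(t))[, c("contig", "pos", "strand")])))
    mkManifest <- function(n) list(
        parameters = list(minDepth = minDepth, pSig = pSig, pHigh = pHigh,
            consensusFrac = consensusFrac, snpMinIvtFrac = snpMinIvtFrac,
            snpAlpha = snpAlpha, minKmerSites = minKmerSites,
            minSiteDepth = minSiteDepth),
        n_direct_replicates = length(directTables),
        direct_replicates = vapply(directTables, replicateId, character(1)),
        n_ivt_replicates = length(ivtTables),
        global_ivt_error = globalError(bg),
        n_tested_sites = n)
    emptyCalls <- S4Vectors::DataFrame(
        contig = character(0), pos = integer(0), strand = character(0),
        kmer = character(0), consensus = logical(0), tier = character(0),
        merged_mismatch = numeric(0), merged_depth = integer(0),
        p0 = numeric(0), p0_source = character(0),
        snp_flagged = logical(0), reason = character(0))
    if (nrow(dsites) == 0L)
        return(new("ModCallSet", calls = emptyCalls,
                   manifest = mkManifest(0L)))
    data.table::setorderv(dsites, c("contig", "pos", "strand"))

    dsites$kmer <- extractKmer(fa, dsites$contig, dsites$pos, dsites$strand)
    dsites <- dsites[!is.na(dsites$kmer), ]
    if (nrow(dsites) == 0L)
        return(new("ModCallSet", calls = emptyCalls,
                   manifest = mkManifest(0L)))

    key <- .siteKey(dsites$contig, dsites$pos, dsites$strand)
    R <- length(directTables)
    depth <- matrix(0L, nrow(dsites), R)
    nC <- matrix(0L, nrow(dsites), R)
    for (j in seq_len(R)) {
        s <- siteCounts(directTables[[j]])
        i <- match(key, .siteKey(s$contig, s$pos, s$strand))
        depth[, j] <- ifelse(is.na(i), 0L, s$depth[pmax(i, 1L)])
        nC[, j] <- ifelse(is.na(i), 0L, s$nC[pmax(i, 1L)])
    }
    is_ <- siteCounts(ivt)
    ii <- match(key, .siteKey(is_$contig, is_$pos, is_$strand))
    ivtDepth <- ifelse(is.na(ii), 0L, is_$depth[pmax(ii, 1L)])
    ivtC <- ifelse(is.na(ii), 0L, is_$nC[pmax(ii, 1L)])
    ivtFrac <- ifelse(ivtDepth > 0, ivtC / pmax(ivtDepth, 1L), NA_real_)

    ee <- expectedError(dsites$kmer, bg, ivtError = ivtFrac,
                        ivtDepth = ivtDepth, minIvtDepth = minDepth)
    mergedD <- rowSums(depth); mergedC <- rowSums(nC)
    snp <- flagSNP(pmax(mergedD, 1L), mergedC, pmax(ivtDepth, 1L), ivtC,
                   minIvtFrac = snpMinIvtFrac, alpha = snpAlpha) &
           mergedD >= minDepth & ivtDepth >= minDepth

    res <- callSites(depth, nC, ee$p0, snp = snp, minDepth = minDepth,
                     pSig = pSig, pHigh = pHigh,
                     consensusFrac = consensusFrac)
    # the merged IVT must also clear the coverage threshold
    lowIvt <- ivtDepth < minDepth
    res$consensus[lowIvt] <- FALSE
    res$tier[lowIvt] <- "not_significant"
    res$reason[lowIvt] <- "low_coverage"

    calls <- S4Vectors::DataFrame(
        contig = dsites$contig, pos = dsites$pos, strand = dsites$strand,
        kmer = dsites$kmer, pvalues = I(res$pvalues),
        consensus = res$consensus, tier = res$tier,
        merged_mismatch = res$merged_mismatch,
        merged_depth = res$merged_depth,
        p0 = ee$p0, p0_source = ee$source,
        ivt_depth = as.integer(ivtDepth), ivt_mismatch = ivtFrac,
        snp_flagged = snp, reason = res$reason)
    new("ModCallSet", calls = calls, manifest = mkManifest(nrow(calls)))
}

#' Write detection results as TSV / BED / JSON manifest
#'
#' Emits \code{<prefix>_calls.tsv} (all tested sites),
#' \code{<prefix>_snp.tsv} (SNP-flagged sites), \code{<prefix>.bed}
#' (0-based intervals of consensus sites) and
#' \code{<prefix>_manifest.json}.
#'
#' @param x a [ModCallSet-class].
#' @param prefix output path prefix.
#' @return character vector of the files written, invisibly.
#' @export
writeModCalls <- function(x, prefix) {
    cl <- modCalls(x)
    pv <- cl$pvalues
    flat <- as.data.frame(cl[, setdiff(colnames(cl), "pvalues")])
    if (nrow(cl) > 0L) {
        pvdf <- as.data.frame(unclass(pv))
        colnames(pvdf) <- paste0("p_rep", seq_len(ncol(pvdf)))
        flat <- cbind(flat[, c("contig", "pos", "strand")],
                      pos1 = flat$pos + 1L,
                      site = .siteName1(flat$contig, flat$pos),
                      kmer = flat$kmer, pvdf,
                      flat[, !colnames(flat) %in%
                               c("contig", "pos", "strand", "kmer")])
    }
    calls_tsv <- paste0(prefix, "_calls.tsv")
    snp_tsv <- paste0(prefix, "_snp.tsv")
    bed <- paste0(prefix, ".bed")
    man <- paste0(prefix, "_manifest.json")
    .writeTSV(flat, calls_tsv)
    .writeTSV(flat[flat$snp_flagged %in% TRUE, ], snp_tsv)
    cons <- as.data.frame(cl[cl$consensus, , drop = FALSE])
    bedDf <- if (nrow(cons) == 0L)
        data.frame(chrom = character(0), start = integer(0),
                   end = integer(0), name = character(0),
                   score = integer(0), strand = character(0))
    else data.frame(chrom = cons$contig, start = cons$pos,
                    end = cons$pos + 1L,
                    name = paste0(cons$kmer, "|", cons$tier),
                    score = pmin(1000L, as.integer(
                        -10 * log10(pmax(1e-100, cons$p0)))),
                    strand = cons$strand)
    utils::write.table(bedDf, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(manifest(x), man, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(c(calls_tsv, snp_tsv, bed, man))
}
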