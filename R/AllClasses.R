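#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.validCountTable <- function(object) {
    msg <- NULL
    s <- object@sites
    required <- c("contig", "pos", "strand", "depth",
                  "nU", "nC", "nA", "nG", "nDel", "mismatch_frac")
    if (!all(required %in% colnames(s)))
        msg <- c(msg, paste("sites must have columns:",
                            paste(setdiff(required, colnames(s)), collapse = ", ")))
    if (!(object@label %in% c("direct", "ivt")))
        msg <- c(msg, "label must be 'direct' or 'ivt'")
    if (length(msg) == 0L && nrow(s) > 0L) {
        if (!all(s$strand %in% c("+", "-")))
            msg <- c(msg, "strand must be '+' or '-'")
        tot <- s$nU + s$nC + s$nA + s$nG + s$nDel
        if (!all(tot == s$depth))
            msg <- c(msg, "base counts must sum to depth at every site")
        if (any(s$mismatch_frac < 0 | s$mismatch_frac > 1))
            msg <- c(msg, "mismatch_frac must lie in [0, 1]")
        key <- paste(s$contig, s$pos, s$strand)
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate (contig, pos, strand) site keys")
    }
    if (is.null(msg)) TRUE else msg
}

#' Per-site base-call tallies for one sequencing library
#'
#' A \code{CountTable} holds the filtered, strand-aware per-uridine-site
#' base-call counts for a single replicate of either a native (direct)
#' library or an in-vitro-transcribed (IVT) control.  Sites are keyed by
#' \code{(contig, pos, strand)} with \code{pos} 0-based; counts are recorded
#' in transcript space, so on a minus-strand site a read-space C call
#' (plus-strand G in the BAM) increments \code{nC}.
#'
#' @slot sites a \code{DataFrame} with columns \code{contig}, \code{pos}
#'   (0-based), \code{strand}, \code{depth}, \code{nU}, \code{nC},
#'   \code{nA}, \code{nG}, \code{nDel}, \code{mismatch_frac}.
#' @slot label \code{"direct"} or \code{"ivt"}.
#' @slot replicate replicate identifier.
#' @slot params the filter parameters used to build the table.
#'
#' @seealso [buildCountTable()], [mergeReplicates()]
#' @export
setClass("CountTable",
    representation(sites = "DataFrame", label = "character",
                   replicate = "character", params = "list"),
    prototype(label = "direct", replicate = "rep1", params = list()),
    validity = .validCountTable)

.validKmerBackground <- function(object) {
    msg <- NULL
    tab <- object@table
    if (!all(c("kmer", "n_sites", "n_reads", "pooled_error") %in% colnames(tab)))
        msg <- c(msg, "table must have columns kmer, n_sites, n_reads, pooled_error")
    if (nrow(tab) > 0L) {
        if (any(tab$pooled_error < 0 | tab$pooled_error > 1))
            msg <- c(msg, "pooled_error must lie in [0, 1]")
        if (any(nchar(tab$kmer) != 5L) || any(substr(tab$kmer, 3, 3) != "U"))
            msg <- c(msg, "kmers must be 5-mers with U at the center")
    }
    if (length(object@global_error) != 1L ||
        object@global_error < 0 || object@global_error > 1)
        msg <- c(msg, "global_error must be a single value in [0, 1]")
    if (is.null(msg)) TRUE else msg
}

#' Per-5-mer background U-to-C error model estimated from the IVT control
#'
#' Holds the read-weighted (pooled) U-to-C mismatch error of the IVT
#' control for every center-U 5-mer with enough data, plus a global
#' fallback rate, and the per-site IVT error table used by the
#' site-versus-kmer maximum rule.
#'
#' @slot table \code{DataFrame} with columns \code{kmer}, \code{n_sites},
#'   \code{n_reads}, \code{pooled_error}.
#' @slot global_error pooled error over all qualifying IVT uridine sites.
#' @slot total_reads total IVT read calls behind \code{global_error}.
#' @slot params model-building parameters.
#'
#' @seealso [buildKmerTable()], [expectedError()]
#' @export
setClass("KmerBackground",
    representation(table = "DataFrame", global_error = "numeric",
                   total_reads = "numeric", params = "list"),
    prototype(global_error = 0, total_reads = 0, params = list()),
    validity = .validKmerBackground)

.validModCallSet <- function(object) {
    msg <- NULL
    cl <- object@calls
    required <- c("contig", "pos", "strand", "kmer", "consensus", "tier",
                  "merged_mismatch", "merged_depth", "p0", "p0_source",
                  "snp_flagged", "reason")
    if (!all(required %in% colnames(cl)))
        msg <- c(msg, paste("calls missing columns:",
                 paste(setdiff(required, colnames(cl)), collapse = ", ")))
    if (length(msg) == 0L && nrow(cl) > 0L) {
        if (!all(cl$tier %in% c("not_significant", "significant",
                                "highly_significant")))
            msg <- c(msg, "invalid tier value")
        if (any(cl$merged_mismatch < 0 | cl$merged_mismatch > 1, na.rm = TRUE))
            msg <- c(msg, "merged_mismatch must lie in [0, 1]")
    }
    if (is.null(msg)) TRUE else msg
}

#' Per-site modification calls with replicate p-values
#'
#' Result container of [detectModifications()]: one row per tested uridine
#' site carrying the per-replicate binomial tail p-values (matrix column
#' \code{pvalues}), the consensus verdict, significance tier, pooled direct
#' mismatch and the expected error \code{p0} the test was run against.
#'
#' @slot calls \code{DataFrame} of per-site results.
#' @slot manifest list recording all parameters and input provenance.
#'
#' @export
setClass("ModCallSet",
    representation(calls = "DataFrame", manifest = "list"),
    prototype(manifest = list()),
    validity = .validModCallSet)

.validReadSiteMatrix <- function(object) {
    msg <- NULL
    m <- object@calls
    if (!is.matrix(m) || !is.character(m))
        msg <- c(msg, "calls must be a character matrix")
    else {
        if (!all(m %in% c("C", "U", "other", "uncovered")))
            msg <- c(msg, "calls must be C, U, other or uncovered")
        if (nrow(m) > 0L && any(rowSums(m != "uncovered") == 0L))
            msg <- c(msg, "reads with no covered site must be excluded")
        if (ncol(m) != nrow(object@sites))
            msg <- c(msg, "one matrix column per site required")
    }
    if (is.null(msg)) TRUE else msg
}

#' Read-by-site call matrix for single-molecule co-modification analysis
#'
#' Rows are filtered reads of one transcript, columns its called uridine
#' sites (5'-most first); entries are \code{"C"}, \code{"U"},
#' \code{"other"} (A/G/deletion) or \code{"uncovered"}.
#'
#' @slot transcript_id transcript the matrix belongs to.
#' @slot sites \code{DataFrame} with columns \code{contig}, \code{pos},
#'   \code{strand} in 5'-to-3' transcript order.
#' @slot calls character matrix, reads x sites.
#'
#' @seealso [buildReadSiteMatrix()], [comodFraction()]
#' @export
setClass("ReadSiteMatrix",
    representation(transcript_id = "character", sites = "DataFrame",
                   calls = "matrix"),
    validity = .validReadSiteMatrix)

#' @describeIn CountTable-class number of sites in the table
#' @param x,object a \code{CountTable}
#' @export
setMethod("length", "CountTable", function(x) nrow(x@sites))

#' Accessors for psiNano result containers
#'
#' @param x a psiNano S4 object.
#' @return \code{siteCounts} the per-site \code{DataFrame};
#'   \code{libraryLabel} / \code{replicateId} the library metadata;
#'   \code{kmerTable} / \code{globalError} the background-model pieces;
#'   \code{modCalls} the per-site call \code{DataFrame}; \code{manifest}
#'   the run manifest list; \code{readCalls} the read x site matrix.
#' @name accessors
NULL

#' @rdname accessors
#' @export
siteCounts <- function(x) x@sites

#' @rdname accessors
#' @export
libraryLabel <- function(x) x@label

#' @rdname accessors
#' @export
replicateId <- function(x) x@replicate

#' @rdname accessors
#' @export
kmerTable <- function(x) x@table

#' @rdname accessors
#' @export
globalError <- function(x) x@global_error

#' @rdname accessors
#' @export
modCalls <- function(x) x@calls

#' @rdname accessors
#' @export
manifest <- function(x) x@manifest

#' @rdname accessors
#' @export
readCalls <- function(x) x@calls

setMethod("show", "CountTable", function(object) {
    cat("CountTable:", object@label, "library, replicate",
        object@replicate, "\n")
    cat(" ", nrow(object@sites), "uridine sites on",
        length(unique(object@sites$contig)), "contig(s)\n")
    if (nrow(object@sites) > 0L)
        cat("  median depth:", stats::median(object@sites$depth),
            " mean U-to-C mismatch:",
            signif(mean(object@sites$mismatch_frac), 3), "\n")
})

setMethod("show", "KmerBackground", function(object) {
    cat("KmerBackground: ", nrow(object@table), " center-U 5-mers, ",
        "global U-to-C error ", signif(object@global_error, 4), "\n", sep = "")
})

setMethod("show", "ModCallSet", function(object) {
    cl <- object@calls
    cat("ModCallSet:", nrow(cl), "tested uridine sites\n")
    if (nrow(cl) > 0L) {
        cat("  consensus calls:", sum(cl$consensus), "(",
            sum(cl$tier == "highly_significant"), "highly significant )\n")
        cat("  SNP-flagged:", sum(cl$snp_flagged), "\n")
    }
})

setMethod("show", "ReadSiteMatrix", function(object) {
    cat("ReadSiteMatrix for", object@transcript_id, ":",
        nrow(object@calls), "reads x", ncol(object@calls), "sites\n")
})
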