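## Internal helpers shared across modules.

# DNA -> transcript-space (RNA) alphabet, T becomes U
.toRNA <- function(x) chartr("Tt", "Uu", toupper(x))

.complementBase <- function(x) chartr("ACGTN", "TGCAN", x)

# read-space base of a minus-strand alignment stored on the plus strand
.txBase <- function(base, strand) {
    ifelse(strand == "-", .complementBase(base), base)
}

.siteKey <- function(contig, pos, strand) paste(contig, pos, strand, sep = ":")

#' Ensure a coordinate-sorted, indexed BAM for an alignment file
#'
#' Accepts either a BAM (indexed or not) or a plain-text SAM file; SAM
#' input is converted with \code{Rsamtools::asBam}, which also sorts and
#' indexes.  Returns the path to the usable BAM.
#'
#' @param path path to a SAM or BAM file.
#' @return path to a sorted, indexed BAM.
#' @export
ensureBam <- function(path) {
    if (!file.exists(path))
        stop("alignment file not found: ", path)
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
        dest <- sub("\\.sam$", "", path, ignore.case = TRUE)
        bam <- paste0(dest, ".bam")
        if (!file.exists(bam) ||
            file.mtime(bam) < file.mtime(path))
            bam <- Rsamtools::asBam(path, destination = dest,
                                    overwrite = TRUE, indexDestination = TRUE)
        bam
    } else {
        if (!file.exists(paste0(path, ".bai")))
            Rsamtools::indexBam(path)
        path
    }
}

#' Open (and index if needed) a reference FASTA
#'
#' @param path path to an uncompressed FASTA file.
#' @return an \code{Rsamtools::FaFile} with an up-to-date index.
#' @export
openReference <- function(path) {
    if (!file.exists(path))
        stop("reference FASTA not found: ", path)
    fa <- Rsamtools::FaFile(path)
    if (!file.exists(paste0(path, ".fai")))
        Rsamtools::indexFa(path)
    fa
}

# 1-based site name in the style chr10:1044099 used in reports
.siteName1 <- function(contig, pos0) paste0(contig, ":", pos0 + 1L)

.writeTSV <- function(df, path) {
    utils::write.table(as.data.frame(df), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
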