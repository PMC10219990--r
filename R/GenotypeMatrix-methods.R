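#' Construct a GenotypeMatrix
#'
#' @param calls integer matrix of counted-allele copies, variants in rows
#'   and samples in columns, values 0/1/2 with NA for missing.
#' @param variants data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{id} and optionally \code{counted}
#'   (defaults to \code{alt}).
#' @param samples data.frame with \code{sample_id} and optional
#'   \code{reported_sex}, \code{reported_race}, \code{clinical_group},
#'   \code{plate} columns, or a character vector of sample ids.
#' @return A \linkS4class{GenotypeMatrix}.
#' @examples
#' gm <- GenotypeMatrix(
#'   calls = matrix(c(0L, 1L, 2L, NA), 2, 2),
#'   variants = data.frame(chrom = "1", pos = c(100L, 200L),
#'                         ref = "A", alt = "G", id = c("rs1", "rs2")),
#'   samples = c("S1", "S2"))
#' nVariants(gm)
#' @export
GenotypeMatrix <- function(calls, variants, samples) {
    if (is.character(samples))
        samples <- data.frame(sample_id = samples)
    variants <- as.data.frame(variants)
    samples <- as.data.frame(samples)
    if (is.null(variants$counted))
        variants$counted <- variants$alt
    variants$chrom <- as.character(variants$chrom)
    variants$pos <- as.integer(variants$pos)
    calls <- as.matrix(calls)
    storage.mode(calls) <- "integer"
    if (nrow(calls) != nrow(variants))
        stop("calls rows (", nrow(calls), ") do not match variants (",
             nrow(variants), ")")
    if (ncol(calls) != nrow(samples))
        stop("calls columns (", ncol(calls), ") do not match samples (",
             nrow(samples), ")")
    dimnames(calls) <- list(variants$id, samples$sample_id)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(calls = calls),
        rowData = S4Vectors::DataFrame(variants),
        colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id))
    new("GenotypeMatrix", se)
}

#' Construct a DosageMatrix
#'
#' @param dosages numeric matrix, variants x samples, values in [0, 2].
#' @param variants data.frame of variant keys as in [GenotypeMatrix()],
#'   plus optional \code{imputation_r2} (defaults to 1).
#' @param samples sample ids or data.frame as in [GenotypeMatrix()].
#' @return A \linkS4class{DosageMatrix}.
#' @export
DosageMatrix <- function(dosages, variants, samples) {
    if (is.character(samples))
        samples <- data.frame(sample_id = samples)
    variants <- as.data.frame(variants)
    if (is.null(variants$counted))
        variants$counted <- variants$alt
    if (is.null(variants$imputation_r2))
        variants$imputation_r2 <- 1
    variants$chrom <- as.character(variants$chrom)
    variants$pos <- as.integer(variants$pos)
    dosages <- as.matrix(dosages)
    storage.mode(dosages) <- "double"
    dimnames(dosages) <- list(variants$id, samples$sample_id)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = dosages),
        rowData = S4Vectors::DataFrame(variants),
        colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id))
    new("DosageMatrix", se)
}

#' @rdname GenotypeMatrix
#' @param x a GenotypeMatrix or DosageMatrix.
#' @export
genotypeCalls <- function(x) SummarizedExperiment::assay(x, "calls")

#' @rdname GenotypeMatrix
#' @export
dosageValues <- function(x) SummarizedExperiment::assay(x, "dosage")

#' @rdname GenotypeMatrix
#' @export
variantInfo <- function(x) as.data.frame(SummarizedExperiment::rowData(x))

#' @rdname GenotypeMatrix
#' @export
sampleInfo <- function(x) as.data.frame(SummarizedExperiment::colData(x))

#' @rdname GenotypeMatrix
#' @export
sampleIds <- function(x) SummarizedExperiment::colData(x)$sample_id

#' @rdname GenotypeMatrix
#' @export
nVariants <- function(x) nrow(x)

#' @rdname GenotypeMatrix
#' @export
nSamples <- function(x) ncol(x)

setMethod("show", "GenotypeMatrix", function(object) {
    m <- genotypeCalls(object)
    miss <- if (length(m)) mean(is.na(m)) else 0
    cat("GenotypeMatrix:", nrow(object), "variants x", ncol(object),
        "samples\n")
    chroms <- unique(SummarizedExperiment::rowData(object)$chrom)
    cat("  chromosomes:", paste(head(chroms, 8), collapse = ", "),
        if (length(chroms) > 8) "..." else "", "\n")
    cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
})

setMethod("show", "DosageMatrix", function(object) {
    cat("DosageMatrix:", nrow(object), "variants x", ncol(object),
        "samples\n")
    r2 <- SummarizedExperiment::rowData(object)$imputation_r2
    if (length(r2))
        cat(sprintf("  imputation R2: median %.3f [%.3f-%.3f]\n",
            median(r2, na.rm = TRUE),
            min(r2, na.rm = TRUE), max(r2, na.rm = TRUE)))
})

setMethod("show", "AncestryModel", function(object) {
    cat("AncestryModel:", length(object@populations), "populations x",
        ncol(object@freq), "variants\n")
    cat("  populations:", paste(object@populations, collapse = ", "), "\n")
})

setMethod("show", "GRSModel", function(object) {
    cat("GRSModel '", object@name, "': ", nrow(object@snpTerms),
        " SNP terms, ", nrow(object@interactionTerms),
        " HLA terms, ", nrow(object@proxyMap), " proxies, R2 > ",
        object@r2Min, "\n", sep = "")
})

# internal: autosomal row indices
.autosomalIdx <- function(x)
    which(SummarizedExperiment::rowData(x)$chrom %in% as.character(1:22))

# internal: X-chromosome row indices
.xIdx <- function(x) which(SummarizedExperiment::rowData(x)$chrom == "X")
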