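#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats cor median prcomp quantile rbeta rbinom runif sd setNames rgamma
#' @importFrom utils read.table write.table head
NULL

.VALID_CHROMS <- c(as.character(1:22), "X")

#' GenotypeMatrix: hard-call genotypes with variant and sample metadata
#'
#' A \linkS4class{SummarizedExperiment} holding one assay, \code{"calls"},
#' a variants x samples integer matrix of counted-allele copy numbers
#' \{0, 1, 2\} with \code{NA} for missing calls.  The counted allele is
#' recorded per variant in \code{rowData(x)$counted}; missingness is never
#' conflated with a zero count.
#'
#' Required \code{rowData} columns: \code{chrom} (1-22 or X), \code{pos}
#' (1-based), \code{ref}, \code{alt}, \code{id}, \code{counted}.
#' Required \code{colData} columns: \code{sample_id}; optional
#' \code{reported_sex} (\code{"male"}, \code{"female"}, \code{"unknown"}),
#' \code{reported_race}, \code{clinical_group}, \code{plate}.
#'
#' @seealso [GenotypeMatrix()] for the constructor.
#' @aliases GenotypeMatrix-class
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

#' DosageMatrix: imputed allele dosages with per-variant imputation quality
#'
#' A \linkS4class{SummarizedExperiment} with one assay, \code{"dosage"},
#' variants x samples real values in [0, 2] (expected counted-allele
#' copies), and \code{rowData(x)$imputation_r2} in [0, 1].
#'
#' @aliases DosageMatrix-class
#' @exportClass DosageMatrix
setClass("DosageMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
    msg <- character()
    if (!"calls" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'calls' is required")
    else {
        m <- SummarizedExperiment::assay(object, "calls")
        bad <- m[!is.na(m)]
        if (length(bad) && !all(bad %in% 0:2))
            msg <- c(msg, "calls must be 0, 1, 2 or NA")
    }
    rd <- SummarizedExperiment::rowData(object)
    need <- c("chrom", "pos", "ref", "alt", "id", "counted")
    miss <- setdiff(need, colnames(rd))
    if (length(miss))
        msg <- c(msg, paste0("rowData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if (!length(miss) && nrow(rd)) {
        if (!all(rd$chrom %in% .VALID_CHROMS))
            msg <- c(msg, "chrom must be one of 1-22, X")
        if (any(rd$pos < 1))
            msg <- c(msg, "pos must be >= 1")
        if (any(!nzchar(rd$ref)) || any(!nzchar(rd$alt)))
            msg <- c(msg, "alleles must be non-empty")
        if (anyDuplicated(rd$id))
            msg <- c(msg, paste0("duplicated variant id(s): ",
                paste(unique(rd$id[duplicated(rd$id)]), collapse = ", ")))
        if (!all(rd$counted == rd$ref | rd$counted == rd$alt))
            msg <- c(msg, "counted allele must equal ref or alt")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!"sample_id" %in% colnames(cd))
        msg <- c(msg, "colData lacks sample_id")
    else if (anyDuplicated(cd$sample_id))
        msg <- c(msg, "sample_id values must be unique")
    if (length(msg)) msg else TRUE
})

setValidity("DosageMatrix", function(object) {
    msg <- character()
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- SummarizedExperiment::assay(object, "dosage")
        dd <- d[!is.na(d)]
        if (length(dd) && (min(dd) < 0 || max(dd) > 2))
            msg <- c(msg, "dosages must lie in [0, 2]")
    }
    rd <- SummarizedExperiment::rowData(object)
    if (!"imputation_r2" %in% colnames(rd))
        msg <- c(msg, "rowData lacks imputation_r2")
    else {
        r2 <- rd$imputation_r2
        if (any(!is.na(r2) & (r2 < 0 | r2 > 1)))
            msg <- c(msg, "imputation_r2 must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' AncestryModel: per-population counted-allele frequencies on a variant panel
#'
#' Holds the K x M frequency matrix of a K-population ancestry model over
#' M variants, with frequencies clamped away from 0 and 1 so the
#' projection likelihood stays finite.
#'
#' @slot freq K x M numeric matrix of counted-allele frequencies in (0,1);
#'   rownames are population names.
#' @slot populations character vector of K population labels.
#' @slot variantKeys data.frame with one row per variant (columns
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{id},
#'   \code{counted}), aligned with the columns of \code{freq}.
#' @aliases AncestryModel-class
#' @exportClass AncestryModel
setClass("AncestryModel",
    representation(freq = "matrix", populations = "character",
                   variantKeys = "data.frame"))

setValidity("AncestryModel", function(object) {
    msg <- character()
    if (length(object@populations) < 2)
        msg <- c(msg, "at least 2 populations required")
    if (nrow(object@freq) != length(object@populations))
        msg <- c(msg, "freq rows must match populations")
    if (ncol(object@freq) != nrow(object@variantKeys))
        msg <- c(msg, "freq columns must match variantKeys rows")
    f <- object@freq
    if (length(f) && (min(f) <= 0 || max(f) >= 1))
        msg <- c(msg, "frequencies must lie strictly in (0, 1)")
    if (length(msg)) msg else TRUE
})

#' GRSModel: a configurable polygenic risk score model
#'
#' Describes a weighted-sum genetic risk score: per-SNP effect-allele
#' weights, optional HLA diplotype interaction and per-haplotype additive
#' weights, an ordered proxy map for SNPs absent from the dosage source,
#' an imputation-quality floor, and an optional affine normalization
#' applied as \code{a + b * score}.
#'
#' @slot name score name (e.g. "GRS2").
#' @slot snpTerms data.frame(id, effect_allele, weight).
#' @slot interactionTerms data.frame(hap1, hap2, weight); \code{hap2 = NA}
#'   marks a per-haplotype additive weight counted once per copy.
#' @slot proxyMap data.frame(variant, proxy); proxy chains are refused.
#' @slot r2Min imputation R-squared floor; variants kept when R2 is
#'   strictly greater.
#' @slot normalization numeric(2) \code{c(a, b)} or numeric(0) for none.
#' @aliases GRSModel-class
#' @exportClass GRSModel
setClass("GRSModel",
    representation(name = "character", snpTerms = "data.frame",
                   interactionTerms = "data.frame", proxyMap = "data.frame",
                   r2Min = "numeric", normalization = "numeric"))

setValidity("GRSModel", function(object) {
    msg <- character()
    st <- object@snpTerms
    if (nrow(st)) {
        if (!all(c("id", "effect_allele", "weight") %in% colnames(st)))
            msg <- c(msg, "snpTerms needs id, effect_allele, weight")
        else if (any(!is.finite(st$weight)))
            msg <- c(msg, "snpTerms weights must be finite")
    }
    pm <- object@proxyMap
    if (nrow(pm) && any(pm$proxy %in% pm$variant))
        msg <- c(msg, "proxy chains are not allowed (a proxy is itself proxied)")
    if (!length(object@r2Min) == 1)
        msg <- c(msg, "r2Min must be a single number")
    if (length(object@normalization) %in% c(0L, 2L) == FALSE)
        msg <- c(msg, "normalization must be numeric(0) or c(a, b)")
    if (length(msg)) msg else TRUE
})
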