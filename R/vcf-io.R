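# VCF 4.2 interface: reading goes through VariantAnnotation; writing is
# a compact text writer so the synthetic generators control the DS and
# R2 fields exactly.  Readers accept gzip via VariantAnnotation.

#' Write genotypes or dosages as VCF 4.2
#'
#' GenotypeMatrix input writes GT; DosageMatrix input writes GT (rounded
#' hard call) plus DS per sample and R2 in INFO.
#'
#' @param x a \linkS4class{GenotypeMatrix} or \linkS4class{DosageMatrix}.
#' @param path output path (plain text; use a .vcf name).
#' @return \code{path}, invisibly.
#' @export
writeVcf <- function(x, path) {
    vi <- variantInfo(x)
    isDosage <- is(x, "DosageMatrix")
    hdr <- c("##fileformat=VCFv4.2",
        "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation R-squared\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        if (isDosage)
            "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", sampleIds(x)), collapse = "\t"))
    # VCF ALT dosage convention: emit with counted allele as ALT
    ref <- ifelse(vi$counted == vi$alt, vi$ref, vi$alt)
    alt <- vi$counted
    gtStr <- function(g) ifelse(is.na(g), "./.",
        c("0/0", "0/1", "1/1")[g + 1])
    lines <- character(nrow(vi))
    if (isDosage) {
        ds <- dosageValues(x)
        for (m in seq_len(nrow(vi))) {
            d <- ds[m, ]
            gt <- gtStr(ifelse(is.na(d), NA_integer_, as.integer(round(d))))
            field <- ifelse(is.na(d), "./.",
                            paste0(gt, ":", formatC(d, format = "g",
                                                    digits = 6)))
            lines[m] <- paste(c(vi$chrom[m], vi$pos[m], vi$id[m], ref[m],
                alt[m], ".", "PASS",
                paste0("R2=", formatC(vi$imputation_r2[m], format = "g",
                                      digits = 6)),
                "GT:DS", field), collapse = "\t")
        }
    } else {
        calls <- genotypeCalls(x)
        for (m in seq_len(nrow(vi))) {
            lines[m] <- paste(c(vi$chrom[m], vi$pos[m], vi$id[m], ref[m],
                alt[m], ".", "PASS", ".", "GT", gtStr(calls[m, ])),
                collapse = "\t")
        }
    }
    writeLines(c(hdr, lines), path)
    invisible(path)
}

#' Read imputed dosages (or hard calls) from a VCF
#'
#' Extracts the per-sample DS field when present; when the VCF carries
#' only GT, dosages fall back to the hard-call count of the ALT allele.
#' Per-variant imputation quality is read from the INFO field named by
#' \code{r2_field} and an optional strict filter \code{dosage > r2_min}
#' is applied.
#'
#' @param path VCF path (may be bgzipped).
#' @param r2_field INFO field holding imputation R-squared ("R2" or
#'   "DR2" commonly).
#' @param r2_min optional quality floor; variants kept when R2 is
#'   strictly greater.  Requesting a filter when the field is absent is
#'   an error.
#' @return a \linkS4class{DosageMatrix}; counted allele is ALT.
#' @export
readVcfDosages <- function(path, r2_field = "R2", r2_min = NULL) {
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    fixed <- VariantAnnotation::fixed(vcf)
    alt <- as.character(unlist(fixed$ALT))
    variants <- data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(rr)),
        pos = BiocGenerics::start(rr),
        ref = as.character(fixed$REF),
        alt = alt, id = names(rr), counted = alt)
    info <- VariantAnnotation::info(vcf)
    hasR2 <- r2_field %in% colnames(info)
    if (!is.null(r2_min) && !hasR2)
        stop("R2 filter requested but INFO field '", r2_field,
             "' is absent from ", path)
    variants$imputation_r2 <- if (hasR2) as.numeric(info[[r2_field]])
        else NA_real_
    gen <- VariantAnnotation::geno(vcf)
    if ("DS" %in% names(gen)) {
        ds <- gen$DS
        storage.mode(ds) <- "double"
    } else {
        gt <- gen$GT
        ds <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
        ds[gt %in% c("0/0", "0|0")] <- 0
        ds[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
        ds[gt %in% c("1/1", "1|1")] <- 2
    }
    out <- DosageMatrix(ds, variants, colnames(ds))
    if (!is.null(r2_min))
        out <- out[which(variants$imputation_r2 > r2_min), ]
    out
}

#' Convert hard calls to a DosageMatrix
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param imputation_r2 per-variant quality to attach (recycled).
#' @return a \linkS4class{DosageMatrix} with dosages equal to the calls.
#' @export
asDosageMatrix <- function(x, imputation_r2 = 1) {
    vi <- variantInfo(x)
    vi$imputation_r2 <- rep_len(imputation_r2, nrow(vi))
    DosageMatrix(genotypeCalls(x), vi, sampleInfo(x))
}
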