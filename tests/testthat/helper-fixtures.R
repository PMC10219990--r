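# Small in-code fixtures shared across test files.

toyVariants <- function(M, chrom = "1", prefix = "rs") {
    data.frame(chrom = chrom, pos = seq(100, by = 100, length.out = M),
               ref = "A", alt = "G", id = paste0(prefix, seq_len(M)))
}

toyMatrix <- function(calls, chrom = "1", prefix = "rs",
                      samples = NULL) {
    calls <- as.matrix(calls)
    if (is.null(samples))
        samples <- paste0("S", seq_len(ncol(calls)))
    GenotypeMatrix(calls, toyVariants(nrow(calls), chrom, prefix),
                   samples)
}

# typed/imputed HLA table builders (single locus unless given)
hlaTyped <- function(donors, a1, a2, locus = "A") {
    data.frame(donor_id = donors, locus = locus, allele1 = a1,
               allele2 = a2)
}

hlaImputed <- function(donors, a1, a2, p1 = 1, p2 = 1, locus = "A") {
    data.frame(donor_id = donors, locus = locus, allele1 = a1,
               allele2 = a2, prob1 = p1, prob2 = p2)
}
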