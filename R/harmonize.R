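# Cross-callset harmonization: variant identity for merging is
# (chromosome, position, unordered allele pair); rsIDs are ignored
# because they differ across platforms.

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.isAmbiguous <- function(ref, alt)
    unname(.COMPLEMENT[ref] == alt)   # A/T and C/G pairs

#' Intersect two callsets on shared variants and align counted alleles
#'
#' Restricts both matrices to variants shared by chromosome and
#' position.  Where the two callsets count opposite alleles of the same
#' pair, calls in \code{b} are flipped (2 - g).  Strand-complement
#' ambiguous SNPs (A/T, C/G) are dropped, as are shared positions whose
#' allele pairs cannot be reconciled even after strand complementing;
#' both removals are counted in the harmonization report rather than
#' being fatal.
#'
#' @param a,b \linkS4class{GenotypeMatrix} objects.
#' @return list(a, b, report) where report lists n_shared, n_kept,
#'   n_flipped, n_ambiguous_dropped, n_irreconcilable_dropped.
#' @export
intersectAndHarmonize <- function(a, b) {
    va <- variantInfo(a); vb <- variantInfo(b)
    keyA <- paste(va$chrom, va$pos); keyB <- paste(vb$chrom, vb$pos)
    shared <- intersect(keyA, keyB)
    if (!length(shared)) {
        warning("no shared variants between the two callsets")
        return(list(a = a[integer(0), ], b = b[integer(0), ],
                    report = list(n_shared = 0L, n_kept = 0L,
                                  n_flipped = 0L, n_ambiguous_dropped = 0L,
                                  n_irreconcilable_dropped = 0L)))
    }
    ia <- match(shared, keyA); ib <- match(shared, keyB)
    refA <- va$ref[ia]; altA <- va$alt[ia]; cntA <- va$counted[ia]
    refB <- vb$ref[ib]; altB <- vb$alt[ib]; cntB <- vb$counted[ib]
    ambig <- .isAmbiguous(refA, altA) | .isAmbiguous(refB, altB)
    ambig[is.na(ambig)] <- FALSE      # indels/multibase: never strand-flipped
    sameSet <- (refB == refA & altB == altA) | (refB == altA & altB == refA)
    compSet <- (.COMPLEMENT[refB] == refA & .COMPLEMENT[altB] == altA) |
               (.COMPLEMENT[refB] == altA & .COMPLEMENT[altB] == refA)
    compSet[is.na(compSet)] <- FALSE
    keep <- !ambig & (sameSet | compSet)
    irrec <- sum(!ambig & !keep)
    # counted allele of b on a's strand
    cntB2 <- ifelse(sameSet, cntB, unname(.COMPLEMENT[cntB]))
    flip <- keep & (cntB2 != cntA)
    outA <- a[ia[keep], ]
    outB <- b[ib[keep], ]
    if (any(flip[keep])) {
        calls <- genotypeCalls(outB)
        fl <- flip[keep]
        calls[fl, ] <- 2L - calls[fl, ]
        vi <- variantInfo(outB)
        vi$counted[fl] <- ifelse(vi$counted[fl] == vi$ref[fl],
                                 vi$alt[fl], vi$ref[fl])
        outB <- GenotypeMatrix(calls, vi, sampleInfo(outB))
    }
    list(a = outA, b = outB,
         report = list(n_shared = length(shared), n_kept = sum(keep),
                       n_flipped = sum(flip), n_ambiguous_dropped = sum(ambig),
                       n_irreconcilable_dropped = irrec))
}
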