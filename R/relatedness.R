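# Pairwise kinship with the robust heterozygote-concordance estimator
# and relationship-degree classification on the power-of-two cutoff
# ladder.

#' Relationship-degree cutoff ladder
#'
#' Lower kinship cutoffs at the geometric midpoints between the expected
#' coefficients of adjacent degrees: 2^(-(2d+3)/2) for d = 0..3, i.e.
#' duplicate/MZ 2^(-3/2) ~ 0.354, first degree 2^(-5/2) ~ 0.177, second
#' 2^(-7/2) ~ 0.0884, third 2^(-9/2) ~ 0.0442.  A kinship estimate at or
#' above a lower cutoff takes the closer-related class.
#'
#' @return named numeric vector (duplicate_MZ, first, second, third),
#'   strictly decreasing.
#' @examples
#' degreeCutoffs()
#' @export
degreeCutoffs <- function() {
    c(duplicate_MZ = 2^(-3 / 2), first = 2^(-5 / 2),
      second = 2^(-7 / 2), third = 2^(-9 / 2))
}

# core estimator on two genotype vectors (autosomal hard calls, NA ok)
.kinshipPair <- function(ga, gb) {
    ok <- !is.na(ga) & !is.na(gb)
    ga <- ga[ok]; gb <- gb[ok]
    nAa_a <- sum(ga == 1L)
    nAa_b <- sum(gb == 1L)
    nAaAa <- sum(ga == 1L & gb == 1L)
    nAAaa <- sum((ga == 0L & gb == 2L) | (ga == 2L & gb == 0L))
    phi <- if (nAa_a > 0 && nAa_b > 0) {
        mn <- min(nAa_a, nAa_b)
        (nAaAa - 2 * nAAaa) / (2 * mn) + 0.5 - (nAa_a + nAa_b) / (4 * mn)
    } else NA_real_
    list(phi = phi, n_snps_used = length(ga),
         het_counts = c(N_Aa_a = nAa_a, N_Aa_b = nAa_b,
                        N_AaAa = nAaAa, N_AAaa = nAAaa))
}

#' Estimate pairwise kinship coefficients
#'
#' Implements the robust between-family heterozygote-concordance
#' estimator: over shared non-missing autosomal SNPs, with N_Aa,Aa the
#' count of SNPs where both samples are heterozygous, N_AA,aa the count
#' of opposite homozygotes and N_Aa(s) each sample's heterozygote count,
#' \deqn{\phi = \frac{N_{Aa,Aa} - 2 N_{AA,aa}}{2\,\min(N_{Aa}(a), N_{Aa}(b))}
#'   + \frac12 - \frac{N_{Aa}(a) + N_{Aa}(b)}{4\,\min(N_{Aa}(a), N_{Aa}(b))}.}
#' Identical samples give exactly 1/2; pairs where either sample has no
#' heterozygous call are returned with \code{NA} phi and excluded from
#' classification.  X-chromosome variants are excluded (the estimator
#' assumes autosomal diploidy); missing calls are skipped pairwise.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param pairs \code{"all"} or a data.frame(sample_a, sample_b).
#' @return data.frame(sample_a, sample_b, phi, n_snps_used, N_Aa_a,
#'   N_Aa_b, N_AaAa, N_AAaa).
#' @export
estimateKinship <- function(x, pairs = "all") {
    ids <- sampleIds(x)
    calls <- genotypeCalls(x)[.autosomalIdx(x), , drop = FALSE]
    if (!nrow(calls))
        stop("no autosomal variants available for kinship estimation")
    if (identical(pairs, "all")) {
        if (length(ids) < 2)
            return(data.frame(sample_a = character(),
                              sample_b = character(), phi = numeric(),
                              n_snps_used = integer(), N_Aa_a = integer(),
                              N_Aa_b = integer(), N_AaAa = integer(),
                              N_AAaa = integer()))
        return(.kinshipAllPairs(calls, ids))
    }
    ia <- match(pairs$sample_a, ids); ib <- match(pairs$sample_b, ids)
    if (anyNA(ia) || anyNA(ib))
        stop("pair references unknown sample id(s): ",
             paste(unique(c(pairs$sample_a[is.na(ia)],
                            pairs$sample_b[is.na(ib)])), collapse = ", "))
    res <- vector("list", nrow(pairs))
    for (p in seq_len(nrow(pairs))) {
        k <- .kinshipPair(calls[, ia[p]], calls[, ib[p]])
        res[[p]] <- data.frame(sample_a = pairs$sample_a[p],
                               sample_b = pairs$sample_b[p],
                               phi = k$phi, n_snps_used = k$n_snps_used,
                               t(k$het_counts))
    }
    do.call(rbind, res)
}

# all-pairs kinship via cross-products of indicator matrices; identical
# arithmetic to .kinshipPair, evaluated for every unordered pair at once
.kinshipAllPairs <- function(calls, ids) {
    nm <- !is.na(calls)
    H <- calls == 1L;  H[!nm] <- FALSE
    A0 <- calls == 0L; A0[!nm] <- FALSE
    A2 <- calls == 2L; A2[!nm] <- FALSE
    storage.mode(H) <- storage.mode(A0) <- storage.mode(A2) <- "double"
    storage.mode(nm) <- "double"
    nUsed <- crossprod(nm)
    hetA <- crossprod(H, nm)       # het in row-sample, non-missing in col
    nAaAa <- crossprod(H)
    nAAaa <- crossprod(A0, A2) + crossprod(A2, A0)
    n <- length(ids)
    iu <- which(upper.tri(nUsed))
    row <- ((iu - 1) %% n) + 1; col <- ((iu - 1) %/% n) + 1
    nAa_a <- hetA[iu]                       # [a, b]: het(a) on shared set
    nAa_b <- t(hetA)[iu]
    mn <- pmin(nAa_a, nAa_b)
    phi <- ifelse(mn > 0,
        (nAaAa[iu] - 2 * nAAaa[iu]) / (2 * mn) + 0.5 -
            (nAa_a + nAa_b) / (4 * mn), NA_real_)
    data.frame(sample_a = ids[row], sample_b = ids[col], phi = phi,
               n_snps_used = as.integer(nUsed[iu]),
               N_Aa_a = as.integer(nAa_a), N_Aa_b = as.integer(nAa_b),
               N_AaAa = as.integer(nAaAa[iu]),
               N_AAaa = as.integer(nAAaa[iu]))
}

#' Classify kinship estimates into relationship degrees
#'
#' @param phi numeric vector of kinship estimates (NA allowed).
#' @param cutoffs lower-cutoff ladder from [degreeCutoffs()].
#' @return character vector: duplicate_MZ, first, second, third,
#'   unrelated, or NA for undefined estimates.
#' @export
classifyDegree <- function(phi, cutoffs = degreeCutoffs()) {
    if (any(diff(cutoffs) >= 0))
        stop("cutoffs must be strictly decreasing")
    out <- rep(NA_character_, length(phi))
    ok <- !is.na(phi)
    out[ok] <- "unrelated"
    for (cls in rev(names(cutoffs)))    # third ... duplicate_MZ
        out[ok & phi >= cutoffs[[cls]]] <- cls
    out
}

#' Cohort-wide relatedness screen
#'
#' All-pairs kinship estimates, counts per degree class, flagged pairs
#' (third degree or closer) and per-class phi median/IQR.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param cutoffs lower-cutoff ladder.
#' @return list(pairs, class_counts, flagged, class_summary).
#' @export
relatednessScreen <- function(x, cutoffs = degreeCutoffs()) {
    est <- estimateKinship(x, "all")
    est$degree <- classifyDegree(est$phi, cutoffs)
    classes <- c(names(cutoffs), "unrelated")
    counts <- setNames(integer(length(classes)), classes)
    tb <- table(est$degree)
    counts[names(tb)] <- as.integer(tb)
    flagged <- est[!is.na(est$degree) & est$degree != "unrelated", ,
                   drop = FALSE]
    summ <- do.call(rbind, lapply(classes, function(cls) {
        ph <- est$phi[!is.na(est$degree) & est$degree == cls]
        data.frame(degree = cls, n = length(ph),
                   phi_median = if (length(ph)) median(ph) else NA_real_,
                   phi_q1 = if (length(ph)) unname(quantile(ph, 0.25))
                            else NA_real_,
                   phi_q3 = if (length(ph)) unname(quantile(ph, 0.75))
                            else NA_real_)
    }))
    list(pairs = est, class_counts = counts, flagged = flagged,
         class_summary = summ)
}
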