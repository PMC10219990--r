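# Call-rate QC, sex concordance from X heterozygosity, Bland-Altman
# replicate agreement, and cross-platform per-SNP concordance.

#' QC thresholds for call-rate screening
#'
#' Defaults follow common array best-practice stringency: sample QC call
#' rate >= 0.97, variant call rate >= 0.95, plate mean call rate (over
#' passing samples) >= 0.985, and an optional vendor dish-QC floor of
#' 0.82 applied only when a \code{dqc} column is supplied (dish QC is
#' defined on raw intensities and is consumed, never computed).
#'
#' @param sample_call_rate_min,variant_call_rate_min,plate_mean_call_rate_min
#'   fractions in [0, 1].
#' @param dqc_min vendor dish-QC floor.
#' @return a named list of class \code{"QCThresholds"}.
#' @export
qcThresholds <- function(sample_call_rate_min = 0.97,
                         variant_call_rate_min = 0.95,
                         plate_mean_call_rate_min = 0.985,
                         dqc_min = 0.82) {
    v <- c(sample_call_rate_min, variant_call_rate_min,
           plate_mean_call_rate_min, dqc_min)
    if (any(v < 0 | v > 1)) stop("all thresholds must lie in [0, 1]")
    structure(list(sample_call_rate_min = sample_call_rate_min,
                   variant_call_rate_min = variant_call_rate_min,
                   plate_mean_call_rate_min = plate_mean_call_rate_min,
                   dqc_min = dqc_min), class = "QCThresholds")
}

#' Per-sample, per-variant and per-plate call rates
#'
#' Call rate is the fraction of non-missing calls along each axis.
#' Plate summaries use the mean call rate of the samples passing the
#' sample threshold on each plate, matching the convention that plate
#' acceptance is judged on passing samples.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param thresholds a [qcThresholds()].
#' @return list(samples, variants, plates) of data.frames with rate and
#'   pass columns; \code{plates} is NULL without a \code{plate} column in
#'   the sample metadata.
#' @export
callRates <- function(x, thresholds = qcThresholds()) {
    calls <- genotypeCalls(x)
    sampleRate <- colMeans(!is.na(calls))
    variantRate <- rowMeans(!is.na(calls))
    si <- sampleInfo(x)
    samples <- data.frame(sample_id = si$sample_id,
                          call_rate = unname(sampleRate),
                          pass = unname(sampleRate >=
                              thresholds$sample_call_rate_min))
    if ("dqc" %in% names(si))
        samples$pass <- samples$pass & si$dqc >= thresholds$dqc_min
    vi <- variantInfo(x)
    variants <- data.frame(id = vi$id, call_rate = unname(variantRate),
                           pass = unname(variantRate >=
                               thresholds$variant_call_rate_min))
    plates <- NULL
    if ("plate" %in% names(si)) {
        sp <- split(seq_len(nrow(samples)), si$plate)
        plates <- do.call(rbind, lapply(names(sp), function(p) {
            idx <- sp[[p]]
            passing <- idx[samples$pass[idx]]
            mcr <- if (length(passing)) mean(samples$call_rate[passing])
                  else NA_real_
            data.frame(plate = p, n_samples = length(idx),
                       mean_call_rate = mcr,
                       pass = !is.na(mcr) &&
                           mcr >= thresholds$plate_mean_call_rate_min)
        }))
    }
    list(samples = samples, variants = variants, plates = plates)
}

#' Infer sex from X-chromosome heterozygosity
#'
#' The X heterozygosity rate (fraction of non-missing X calls that are
#' heterozygous) is thresholded directly: below \code{male_max_het} is
#' male, above \code{female_min_het} is female, between is ambiguous.
#' Ambiguous samples are never concordant with the report.
#'
#' @param x a \linkS4class{GenotypeMatrix} containing X variants.
#' @param male_max_het,female_min_het het-rate thresholds.
#' @return data.frame(sample_id, x_het_rate, inferred_sex,
#'   concordant_with_reported).
#' @export
inferSex <- function(x, male_max_het = 0.05, female_min_het = 0.20) {
    xi <- .xIdx(x)
    if (!length(xi))
        stop("no X-chromosome variants in the matrix; cannot infer sex")
    calls <- genotypeCalls(x)[xi, , drop = FALSE]
    het <- colSums(calls == 1L, na.rm = TRUE)
    nonmiss <- colSums(!is.na(calls))
    rate <- ifelse(nonmiss > 0, het / nonmiss, NA_real_)
    inferred <- ifelse(is.na(rate), "ambiguous",
                ifelse(rate < male_max_het, "male",
                ifelse(rate > female_min_het, "female", "ambiguous")))
    si <- sampleInfo(x)
    reported <- if ("reported_sex" %in% names(si)) si$reported_sex
                else rep("unknown", nrow(si))
    data.frame(sample_id = si$sample_id, x_het_rate = unname(rate),
               inferred_sex = unname(inferred),
               concordant_with_reported =
                   unname(inferred != "ambiguous" & inferred == reported))
}

#' Bland-Altman agreement between paired measurements
#'
#' Bias is \code{mean(a - b)}; the 95 percent limits of agreement are
#' \code{bias +/- 1.96 * sd(a - b)} with the sample (n - 1) standard
#' deviation.
#'
#' @param values_a,values_b equal-length paired numeric vectors, n >= 2.
#' @return list(bias, sd_diff, loa_low, loa_high, pairs_n).
#' @export
replicateBlandAltman <- function(values_a, values_b) {
    if (length(values_a) != length(values_b))
        stop("paired vectors must have equal length")
    if (length(values_a) < 2)
        stop("at least 2 pairs are required")
    d <- values_a - values_b
    bias <- mean(d)
    s <- sd(d)
    list(bias = bias, sd_diff = s,
         loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
         pairs_n = length(d))
}

#' Per-SNP concordance between two harmonized callsets
#'
#' Variant filters are applied in order: autosomal, biallelic, and
#' minor-allele count >= \code{mac_min} in the designated callset.
#' Concordance per variant is the fraction of samples, non-missing in
#' both callsets, whose calls agree; variants with zero comparable calls
#' are flagged rather than divided by zero.
#'
#' @param a,b \linkS4class{GenotypeMatrix} objects over the same samples
#'   and variants (see [intersectAndHarmonize()]).
#' @param mac_in which callset the MAC filter is evaluated in.
#' @param mac_min minimum minor-allele count.
#' @return data.frame(id, chrom, pos, n_compared, n_equal, concordance,
#'   no_comparable_calls).
#' @export
perSnpConcordance <- function(a, b, mac_in = c("b", "a"), mac_min = 1) {
    mac_in <- match.arg(mac_in)
    sharedSamples <- intersect(sampleIds(a), sampleIds(b))
    if (!length(sharedSamples))
        stop("no shared samples between the callsets")
    a <- a[, match(sharedSamples, sampleIds(a))]
    b <- b[, match(sharedSamples, sampleIds(b))]
    if (nrow(a) != nrow(b) ||
        !all(variantInfo(a)$pos == variantInfo(b)$pos))
        stop("callsets must be harmonized to the same variants first")
    keep <- .autosomalIdx(a)
    va <- variantInfo(a)
    biallelic <- nchar(va$ref) == 1 & nchar(va$alt) == 1 &
        va$ref != va$alt
    keep <- intersect(keep, which(biallelic))
    macSrc <- genotypeCalls(if (mac_in == "b") b else a)
    cnt <- rowSums(macSrc, na.rm = TRUE)
    nn <- rowSums(!is.na(macSrc))
    mac <- pmin(cnt, 2 * nn - cnt)
    keep <- intersect(keep, which(mac >= mac_min))
    ca <- genotypeCalls(a)[keep, , drop = FALSE]
    cb <- genotypeCalls(b)[keep, , drop = FALSE]
    both <- !is.na(ca) & !is.na(cb)
    nComp <- rowSums(both)
    nEq <- rowSums(both & ca == cb, na.rm = TRUE)
    data.frame(id = va$id[keep], chrom = va$chrom[keep],
               pos = va$pos[keep], n_compared = nComp, n_equal = nEq,
               concordance = ifelse(nComp > 0, nEq / nComp, NA_real_),
               no_comparable_calls = nComp == 0)
}
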