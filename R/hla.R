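# HLA imputation validation: allele parsing/normalization, multiset
# matching of imputed against typed pairs, locus accuracy Acc(L),
# genotype-of-interest concordance, donor accuracy Acc(S), and the
# stratified report.

#' Parse and normalize an HLA allele string
#'
#' Accepts \code{"LOCUS*ff:ss"}, \code{"LOCUS*ff"} (2-digit), or a bare
#' \code{"ff:ss"} / \code{"ff"} with the locus supplied separately.
#' Field 2 \code{"xx"} is the wildcard ("any sub-allele").  Fields are
#' upper-cased and zero-padded to two digits; suffix fields beyond the
#' protein level are truncated.
#'
#' @param allele allele string(s).
#' @param locus optional locus to attach to bare allele strings.
#' @return data.frame(locus, field1, field2, wildcard); \code{field2} is
#'   NA for 2-digit alleles and for wildcards.
#' @export
parseHLAAllele <- function(allele, locus = NA_character_) {
    allele <- toupper(trimws(allele))
    locus <- rep_len(toupper(ifelse(is.na(locus), NA, trimws(locus))),
                     length(allele))
    hasLocus <- grepl("\\*", allele)
    loc <- ifelse(hasLocus, sub("\\*.*$", "", allele), locus)
    loc <- sub("^HLA-", "", loc)
    rest <- ifelse(hasLocus, sub("^.*\\*", "", allele), allele)
    parts <- strsplit(rest, ":", fixed = TRUE)
    f1 <- vapply(parts, `[`, "", 1)
    f2 <- vapply(parts, function(p) if (length(p) >= 2) p[2] else
        NA_character_, "")
    wildcard <- !is.na(f2) & f2 == "XX"
    f2[wildcard] <- NA_character_
    pad <- function(v) ifelse(is.na(v) | !grepl("^[0-9]+$", v), v,
                              formatC(as.integer(v), width = 2,
                                      flag = "0"))
    if (any(is.na(loc) | !nzchar(loc) | !nzchar(f1)))
        stop("malformed HLA allele string(s): ",
             paste(allele[is.na(loc) | !nzchar(loc) | !nzchar(f1)],
                   collapse = ", "))
    data.frame(locus = loc, field1 = pad(f1), field2 = pad(f2),
               wildcard = wildcard)
}

# does imputed allele i match typed allele t at the given resolution?
.alleleMatches <- function(impF1, impF2, typF1, typF2, typWild,
                           resolution) {
    if (impF1 != typF1) return(FALSE)
    if (resolution == 2) return(TRUE)
    if (typWild || is.na(typF2)) return(TRUE)   # wildcard truth
    !is.na(impF2) && impF2 == typF2
}

#' Match an imputed allele pair against a typed pair
#'
#' Multiset matching: each typed allele can absorb at most one imputed
#' allele, so a homozygous imputed pair cannot double-claim a single
#' typed allele.  At 2-digit resolution only field 1 is compared;
#' wildcard typed alleles (\code{xx}) match any sub-allele.  Of the two
#' possible pairings the one maximizing the number of concordant alleles
#' is used.
#'
#' @param imputed character(2) imputed alleles.
#' @param typed character(2) typed alleles.
#' @param locus locus of all four alleles.
#' @param resolution 2 or 4 (digit).
#' @return logical(2): concordance flag per imputed allele.
#' @export
matchAlleles <- function(imputed, typed, locus, resolution = 4) {
    imp <- parseHLAAllele(imputed, locus)
    typ <- parseHLAAllele(typed, locus)
    m <- matrix(FALSE, 2, 2)
    for (i in 1:2) for (t in 1:2)
        m[i, t] <- .alleleMatches(imp$field1[i], imp$field2[i],
                                  typ$field1[t], typ$field2[t],
                                  typ$wildcard[t], resolution)
    # two possible assignments of imputed -> typed
    straight <- c(m[1, 1], m[2, 2])
    crossed <- c(m[1, 2], m[2, 1])
    if (sum(crossed) > sum(straight)) crossed else straight
}

.hlaJoin <- function(imputed, typed, locus) {
    it <- imputed[imputed$locus == locus, ]
    tt <- typed[typed$locus == locus, ]
    donors <- intersect(it$donor_id, tt$donor_id)
    excluded <- union(setdiff(it$donor_id, donors),
                      setdiff(tt$donor_id, donors))
    list(imp = it[match(donors, it$donor_id), ],
         typ = tt[match(donors, tt$donor_id), ],
         donors = donors, excluded = excluded)
}

#' Locus-level imputation accuracy Acc(L)
#'
#' \deqn{Acc(L) = \frac{\sum_i P_i(A1_{i,L}) + P_i(A2_{i,L})}{2n}}
#' with the reported probability of each discordant imputed allele set
#' to 0.  Donors absent from either table are excluded and reported via
#' the \code{n_excluded} attribute; missing probabilities count as 0
#' with a warning.
#'
#' @param imputed data.frame(donor_id, locus, allele1, allele2, prob1,
#'   prob2).
#' @param typed data.frame(donor_id, locus, allele1, allele2).
#' @param locus locus to score.
#' @param resolution 2 or 4.
#' @return Acc(L) in [0, 1] with attributes n (donors scored) and
#'   n_excluded.
#' @export
accLocus <- function(imputed, typed, locus, resolution = 4) {
    j <- .hlaJoin(imputed, typed, locus)
    n <- length(j$donors)
    if (n == 0)
        return(structure(NA_real_, n = 0L,
                         n_excluded = length(j$excluded)))
    tot <- 0
    for (i in seq_len(n)) {
        conc <- matchAlleles(c(j$imp$allele1[i], j$imp$allele2[i]),
                             c(j$typ$allele1[i], j$typ$allele2[i]),
                             locus, resolution)
        pr <- c(j$imp$prob1[i], j$imp$prob2[i])
        if (anyNA(pr)) {
            warning("missing imputed probability for donor ",
                    j$donors[i], " at ", locus, "; treated as 0")
            pr[is.na(pr)] <- 0
        }
        tot <- tot + sum(pr * conc)
    }
    structure(tot / (2 * n), n = n, n_excluded = length(j$excluded))
}

#' Genotype-of-interest concordance
#'
#' The number of imputed alleles matching the genotype of interest,
#' counted only where pairable with a typed allele matching it, divided
#' by the number of typed alleles matching it, summed over donors.  The
#' pairing cap keeps the ratio in [0, 1].  A zero denominator returns a
#' flagged undefined result, not 0.
#'
#' @param imputed,typed HLA call tables as in [accLocus()].
#' @param pattern allele pattern, e.g. \code{"DRB1*03:01"},
#'   \code{"DRB1*04:xx"} or \code{"A*02"}.
#' @param resolution 2 or 4.
#' @return fraction with attributes n_typed (denominator) and
#'   undefined flag.
#' @export
concordanceGenotype <- function(imputed, typed, pattern, resolution = 4) {
    pat <- parseHLAAllele(pattern)
    locus <- pat$locus[1]
    j <- .hlaJoin(imputed, typed, locus)
    matchPat <- function(alleles) {
        a <- parseHLAAllele(alleles, locus)
        vapply(seq_len(nrow(a)), function(i)
            .alleleMatches(a$field1[i], a$field2[i], pat$field1[1],
                           pat$field2[1], pat$wildcard[1], resolution),
            logical(1))
    }
    num <- 0L; den <- 0L
    for (i in seq_along(j$donors)) {
        tMatch <- sum(matchPat(c(j$typ$allele1[i], j$typ$allele2[i])))
        iMatch <- sum(matchPat(c(j$imp$allele1[i], j$imp$allele2[i])))
        den <- den + tMatch
        num <- num + min(iMatch, tMatch)
    }
    if (den == 0)
        return(structure(NA_real_, n_typed = 0L, undefined = TRUE))
    structure(num / den, n_typed = den, undefined = FALSE)
}

#' Donor-level imputation accuracy Acc(S)
#'
#' \deqn{Acc(S) = \frac{\sum_j P_j(A1_{j,S}) + P_j(A2_{j,S})}{2n}} over
#' the donor's typed loci among \code{loci}, discordant probabilities
#' set to 0.  Donors typed at fewer loci are scored over those, with the
#' per-donor locus count reported.
#'
#' @param imputed,typed HLA call tables as in [accLocus()].
#' @param loci loci to score over (default the four-locus panel).
#' @param resolution 2 or 4.
#' @return data.frame(donor_id, acc_s, n_loci).
#' @export
accSample <- function(imputed, typed,
                      loci = c("A", "DRB1", "DQA1", "DQB1"),
                      resolution = 2) {
    donors <- sort(unique(intersect(imputed$donor_id, typed$donor_id)))
    out <- data.frame(donor_id = donors, acc_s = NA_real_, n_loci = 0L)
    for (d in seq_along(donors)) {
        tot <- 0; nl <- 0L
        for (loc in loci) {
            ti <- typed[typed$donor_id == donors[d] &
                        typed$locus == loc, ]
            ii <- imputed[imputed$donor_id == donors[d] &
                          imputed$locus == loc, ]
            if (!nrow(ti) || !nrow(ii)) next
            conc <- matchAlleles(c(ii$allele1[1], ii$allele2[1]),
                                 c(ti$allele1[1], ti$allele2[1]),
                                 loc, resolution)
            pr <- c(ii$prob1[1], ii$prob2[1])
            pr[is.na(pr)] <- 0
            tot <- tot + sum(pr * conc)
            nl <- nl + 1L
        }
        if (nl > 0) {
            out$acc_s[d] <- tot / (2 * nl)
            out$n_loci[d] <- nl
        }
    }
    out
}

#' Stratified HLA validation report
#'
#' Produces a genotype-of-interest concordance table (label, locus,
#' pattern, resolution, n typed alleles, concordance) and per-group
#' Acc(S) median/IQR, grouped by a supplied per-donor factor such as
#' reported race or majority genetic ancestry.
#'
#' @param imputed,typed HLA call tables as in [accLocus()].
#' @param goi data.frame(label, pattern, effect) of genotypes of
#'   interest; may be empty.
#' @param grouping optional data.frame(donor_id, group).
#' @param loci loci for Acc(S).
#' @return list(goi_table, acc_s, group_summary, acc_locus).
#' @export
concordanceReport <- function(imputed, typed, goi = NULL,
                              grouping = NULL,
                              loci = c("A", "DRB1", "DQA1", "DQB1")) {
    accL <- do.call(rbind, lapply(loci, function(loc) {
        do.call(rbind, lapply(c(2, 4), function(res) {
            a <- accLocus(imputed, typed, loc, res)
            data.frame(locus = loc, resolution = res,
                       acc_l = as.numeric(a), n = attr(a, "n"))
        }))
    }))
    goiTab <- NULL
    if (!is.null(goi) && nrow(goi)) {
        goiTab <- do.call(rbind, lapply(seq_len(nrow(goi)), function(r) {
            pat <- parseHLAAllele(goi$pattern[r])
            res <- if (is.na(pat$field2[1]) && !pat$wildcard[1]) 2 else 4
            cc <- concordanceGenotype(imputed, typed, goi$pattern[r], res)
            data.frame(label = goi$label[r], locus = pat$locus[1],
                       pattern = goi$pattern[r], resolution = res,
                       effect = if ("effect" %in% names(goi))
                           goi$effect[r] else NA_character_,
                       n_typed_alleles = attr(cc, "n_typed"),
                       concordance = as.numeric(cc),
                       undefined = attr(cc, "undefined"))
        }))
    }
    accS <- accSample(imputed, typed, loci, resolution = 2)
    groupSummary <- NULL
    if (!is.null(grouping)) {
        accS$group <- grouping$group[match(accS$donor_id,
                                           grouping$donor_id)]
        groupSummary <- do.call(rbind, lapply(
            split(accS, accS$group), function(gdf)
                data.frame(group = gdf$group[1], n = nrow(gdf),
                           acc_s_median = median(gdf$acc_s, na.rm = TRUE),
                           acc_s_q1 = unname(quantile(gdf$acc_s, 0.25,
                                                      na.rm = TRUE)),
                           acc_s_q3 = unname(quantile(gdf$acc_s, 0.75,
                                                      na.rm = TRUE)))))
        rownames(groupSummary) <- NULL
    }
    list(goi_table = goiTab, acc_s = accS, group_summary = groupSummary,
         acc_locus = accL)
}
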