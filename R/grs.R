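# Generic polygenic risk score engine: weighted effect-allele dosage
# sums, HLA diplotype interaction terms, ordered proxy substitution,
# imputation-quality filtering and optional affine normalization.

#' Construct a GRSModel
#'
#' @param name score name.
#' @param snp_terms data.frame(id, effect_allele, weight).
#' @param interaction_terms data.frame(hap1, hap2, weight); rows with
#'   \code{hap2 = NA} are per-haplotype additive weights.
#' @param proxy_map data.frame(variant, proxy), ordered; a proxy may not
#'   itself be proxied.
#' @param r2_min imputation quality floor (kept when strictly greater).
#' @param normalization NULL or c(a, b) applied as \code{a + b * score}.
#' @return a \linkS4class{GRSModel}.
#' @export
grsModel <- function(name, snp_terms,
                     interaction_terms = NULL, proxy_map = NULL,
                     r2_min = 0.97, normalization = NULL) {
    emptyInt <- data.frame(hap1 = character(), hap2 = character(),
                           weight = numeric())
    emptyProxy <- data.frame(variant = character(), proxy = character())
    new("GRSModel", name = name,
        snpTerms = as.data.frame(snp_terms),
        interactionTerms = if (is.null(interaction_terms)) emptyInt
            else as.data.frame(interaction_terms),
        proxyMap = if (is.null(proxy_map)) emptyProxy
            else as.data.frame(proxy_map),
        r2Min = r2_min,
        normalization = if (is.null(normalization)) numeric(0)
            else as.numeric(normalization))
}

#' Read a GRS model from a YAML or JSON config file
#'
#' The config mirrors the [grsModel()] arguments: \code{name},
#' \code{r2_min}, \code{normalization: [a, b]}, \code{snp_terms} (list
#' of id/effect_allele/weight), \code{interaction_terms} (list of
#' hap1/hap2/weight, hap2 optional) and \code{proxy_map} (list of
#' variant/proxy).
#'
#' @param path config path (.yaml/.yml or .json).
#' @return a \linkS4class{GRSModel}.
#' @export
readGRSModel <- function(path) {
    cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    toDf <- function(x, cols) {
        if (is.null(x) || !length(x)) return(NULL)
        if (is.data.frame(x)) {
            for (cc in setdiff(cols, names(x))) x[[cc]] <- NA
            return(x[cols])
        }
        do.call(rbind, lapply(x, function(row) {
            r <- lapply(cols, function(cc) row[[cc]] %||% NA)
            names(r) <- cols
            as.data.frame(r, stringsAsFactors = FALSE)
        }))
    }
    grsModel(name = cfg$name %||% "GRS",
             snp_terms = toDf(cfg$snp_terms,
                              c("id", "effect_allele", "weight")),
             interaction_terms = toDf(cfg$interaction_terms,
                                      c("hap1", "hap2", "weight")),
             proxy_map = toDf(cfg$proxy_map, c("variant", "proxy")),
             r2_min = cfg$r2_min %||% 0.97,
             normalization = unlist(cfg$normalization))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve model SNP terms against a dosage matrix
#'
#' Each term uses its direct variant when present with imputation R2
#' strictly above the model floor, else its proxy under the same rule,
#' else it is recorded missing.  Effect alleles are aligned: when the
#' counted allele is the non-effect allele the dosage is flipped to
#' \code{2 - d}; terms whose effect allele matches neither allele are
#' recorded missing with reason \code{allele_mismatch}.
#'
#' @param model a \linkS4class{GRSModel}.
#' @param dosages a \linkS4class{DosageMatrix}.
#' @return data.frame(id, used_id, row, flip, substituted, missing,
#'   reason).
#' @export
resolveVariants <- function(model, dosages) {
    vi <- variantInfo(dosages)
    st <- model@snpTerms
    pm <- model@proxyMap
    passRow <- function(id) {
        r <- match(id, vi$id)
        if (is.na(r)) return(c(NA_integer_, 1L))       # absent
        r2 <- vi$imputation_r2[r]
        if (!is.na(r2) && r2 > model@r2Min) c(r, 0L) else
            c(NA_integer_, 2L)                         # low quality
    }
    out <- data.frame(id = st$id, used_id = NA_character_,
                      row = NA_integer_, flip = FALSE,
                      substituted = FALSE, missing = FALSE,
                      reason = NA_character_)
    for (i in seq_len(nrow(st))) {
        hit <- passRow(st$id[i]); used <- st$id[i]; sub <- FALSE
        if (is.na(hit[1])) {
            proxy <- pm$proxy[match(st$id[i], pm$variant)]
            if (!is.na(proxy)) {
                ph <- passRow(proxy)
                if (!is.na(ph[1])) { hit <- ph; used <- proxy; sub <- TRUE }
            }
        }
        if (is.na(hit[1])) {
            out$missing[i] <- TRUE
            out$reason[i] <- if (hit[2] == 2L) "low_r2" else "absent"
            next
        }
        r <- hit[1]
        eff <- st$effect_allele[i]
        other <- ifelse(vi$counted[r] == vi$alt[r], vi$ref[r], vi$alt[r])
        if (eff == vi$counted[r]) {
            out$flip[i] <- FALSE
        } else if (eff == other) {
            out$flip[i] <- TRUE
        } else {
            out$missing[i] <- TRUE
            out$reason[i] <- "allele_mismatch"
            next
        }
        out$row[i] <- r; out$used_id[i] <- used; out$substituted[i] <- sub
    }
    out
}

#' Weighted additive (non-HLA) score component
#'
#' Sum over resolved terms of weight times effect-allele dosage; missing
#' terms contribute 0 (no re-weighting) and are reported through the
#' resolution table.
#'
#' @param model a \linkS4class{GRSModel}.
#' @param dosages a \linkS4class{DosageMatrix}.
#' @param resolution optional precomputed [resolveVariants()] table.
#' @return named numeric vector of per-sample components.
#' @export
scoreAdditive <- function(model, dosages, resolution = NULL) {
    if (is.null(resolution)) resolution <- resolveVariants(model, dosages)
    d <- dosageValues(dosages)
    comp <- setNames(numeric(ncol(d)), colnames(d))
    st <- model@snpTerms
    for (i in seq_len(nrow(resolution))) {
        if (resolution$missing[i]) next
        dose <- d[resolution$row[i], ]
        if (resolution$flip[i]) dose <- 2 - dose
        dose[is.na(dose)] <- 0
        comp <- comp + st$weight[i] * dose
    }
    comp
}

#' HLA diplotype interaction score component
#'
#' Each sample's unordered pair of HLA haplotype classes (e.g. DR3/DR4
#' tags) is looked up in the model's interaction table; a matched pair
#' adds its weight once, and per-haplotype additive rows (hap2 = NA) add
#' their weight per copy carried.  Unmatched diplotypes contribute 0 and
#' are flagged.
#'
#' @param model a \linkS4class{GRSModel}.
#' @param hla_tags data.frame(sample_id, hap1, hap2) of per-sample
#'   diplotype class labels.
#' @return data.frame(sample_id, hla_component, matched).
#' @export
scoreHlaInteractions <- function(model, hla_tags) {
    it <- model@interactionTerms
    pairRows <- it[!is.na(it$hap2), , drop = FALSE]
    addRows <- it[is.na(it$hap2), , drop = FALSE]
    comp <- numeric(nrow(hla_tags))
    matched <- logical(nrow(hla_tags))
    for (s in seq_len(nrow(hla_tags))) {
        h <- c(hla_tags$hap1[s], hla_tags$hap2[s])
        hit <- which((pairRows$hap1 == h[1] & pairRows$hap2 == h[2]) |
                     (pairRows$hap1 == h[2] & pairRows$hap2 == h[1]))
        if (length(hit)) {
            comp[s] <- comp[s] + pairRows$weight[hit[1]]
            matched[s] <- TRUE
        }
        if (nrow(addRows)) {
            copies <- vapply(addRows$hap1, function(a) sum(h == a),
                             numeric(1))
            if (any(copies > 0)) matched[s] <- TRUE
            comp[s] <- comp[s] + sum(copies * addRows$weight)
        }
    }
    data.frame(sample_id = hla_tags$sample_id, hla_component = comp,
               matched = matched)
}

#' Compute a full genetic risk score
#'
#' Resolves variants, sums the weighted dosage component and the HLA
#' diplotype component, applies the affine normalization last, and
#' audits substitutions and missing terms.
#'
#' @param model a \linkS4class{GRSModel}.
#' @param dosages a \linkS4class{DosageMatrix}.
#' @param hla_tags optional data.frame(sample_id, hap1, hap2); without
#'   it the HLA component is 0.
#' @return data.frame(sample_id, hla_component, non_hla_component,
#'   total, n_terms_scored, n_terms_missing, completeness) with
#'   attributes substitutions_used and missing_terms.
#' @export
computeGRS <- function(model, dosages, hla_tags = NULL) {
    res <- resolveVariants(model, dosages)
    nonHla <- scoreAdditive(model, dosages, res)
    ids <- names(nonHla)
    hla <- setNames(numeric(length(ids)), ids)
    if (!is.null(hla_tags)) {
        hs <- scoreHlaInteractions(model, hla_tags)
        hla[hs$sample_id] <- hs$hla_component
    }
    raw <- hla + nonHla
    total <- if (length(model@normalization) == 2)
        model@normalization[1] + model@normalization[2] * raw else raw
    nTerms <- nrow(model@snpTerms)
    out <- data.frame(sample_id = ids, hla_component = unname(hla),
                      non_hla_component = unname(nonHla),
                      total = unname(total),
                      n_terms_scored = nTerms - sum(res$missing),
                      n_terms_missing = sum(res$missing),
                      completeness = if (nTerms) 1 - sum(res$missing) /
                          nTerms else 1)
    attr(out, "substitutions_used") <-
        res$used_id[res$substituted & !res$missing]
    attr(out, "missing_terms") <- res$id[res$missing]
    out
}

#' Median/IQR GRS summary per group
#'
#' @param results output of [computeGRS()].
#' @param grouping data.frame(sample_id, group) or a vector aligned with
#'   results rows.
#' @return data.frame(group, n, median, q1, q3); empty groups yield a
#'   row with n = 0.
#' @export
grsGroupSummary <- function(results, grouping) {
    grp <- if (is.data.frame(grouping))
        grouping$group[match(results$sample_id, grouping$sample_id)]
    else rep_len(grouping, nrow(results))
    levelsAll <- if (is.factor(grp)) levels(grp) else
        sort(unique(as.character(grp)))
    do.call(rbind, lapply(levelsAll, function(g) {
        v <- results$total[!is.na(grp) & grp == g]
        data.frame(group = g, n = length(v),
                   median = if (length(v)) median(v) else NA_real_,
                   q1 = if (length(v)) unname(quantile(v, 0.25))
                        else NA_real_,
                   q3 = if (length(v)) unname(quantile(v, 0.75))
                        else NA_real_)
    }))
}
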