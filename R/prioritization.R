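# Rare + deleterious candidate filtering in configured gene panels,
# with distribution summaries and a per-donor candidate report.

#' Load gene panels from YAML (or the shipped defaults)
#'
#' The default panels group autoimmune-diabetes genes (AIRE, FOXP3,
#' IL2RA, ITCH, LRBA, SKAP2, STAT1, STAT3) and MODY/neonatal-diabetes
#' genes (GCK, HNF1A, HNF4A, HNF1B, ABCC8, KCNJ11, INS).
#'
#' @param path YAML path mapping panel name to list(category, genes);
#'   NULL loads the shipped default panels.
#' @return named list of list(name, category, genes).
#' @export
genePanels <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "gene_panels.yaml",
                            package = "cohortval")
    cfg <- yaml::read_yaml(path)
    out <- lapply(names(cfg), function(nm) {
        p <- cfg[[nm]]
        if (!length(p$genes)) stop("panel '", nm, "' has no genes")
        list(name = nm, category = p$category %||% nm,
             genes = unlist(p$genes))
    })
    names(out) <- names(cfg)
    out
}

#' Load the shipped published monogenic-diabetes variant tables
#'
#' Two small annotated tables ship with the package as worked examples
#' for the rare + deleterious filter: \code{"published"} — six
#' previously published monogenic diabetes gene variants (KCNJ11, LMNA,
#' HNF1A, GLIS3, INSR, GATA6) with gnomAD-style percent frequencies and
#' scaled deleteriousness scores; \code{"candidate"} — two candidate
#' variants (HNF1A, STAT1) surfaced by the same filter.
#'
#' @param which table to load.
#' @return annotated variant data.frame.
#' @export
publishedVariants <- function(which = c("published", "candidate")) {
    which <- match.arg(which)
    fn <- c(published = "published_monogenic_variants.tsv",
            candidate = "candidate_monogenic_variants.tsv")[[which]]
    read.table(system.file("extdata", fn, package = "cohortval"),
               header = TRUE, sep = "\t", stringsAsFactors = FALSE,
               colClasses = c(donor_id = "character"))
}

#' Restrict an annotated variant table to a gene panel
#'
#' Case-insensitive gene symbol match; duplicate rows are retained
#' as-is.
#'
#' @param table annotated variant data.frame with a \code{gene} column.
#' @param panel a panel entry from [genePanels()] or a character vector
#'   of gene symbols.
#' @return the matching subset of \code{table}.
#' @export
filterPanel <- function(table, panel) {
    genes <- if (is.list(panel)) panel$genes else panel
    table[toupper(table$gene) %in% toupper(genes), , drop = FALSE]
}

#' Apply the rare + deleterious candidate filter
#'
#' A row passes when its population frequency (percent) is strictly
#' below \code{freq_max_pct} and its deleteriousness score is at least
#' \code{score_min}.  Missing frequencies are treated as 0 (absent from
#' the population database) and noted; frequencies above 100 are
#' rejected.
#'
#' @param table annotated variant data.frame with
#'   \code{population_frequency} (percent) and
#'   \code{deleteriousness_score} columns.
#' @param freq_max_pct frequency ceiling, percent (default 0.01).
#' @param score_min deleteriousness floor (default 20).
#' @param score_comparator \code{">="} (default) or \code{">"}.
#' @return \code{table} with added logical columns rare, deleterious,
#'   pass, freq_missing and a character fail_reason.
#' @export
applyRareDeleterious <- function(table, freq_max_pct = 0.01,
                                 score_min = 20,
                                 score_comparator = c(">=", ">")) {
    score_comparator <- match.arg(score_comparator)
    freq <- table$population_frequency
    if (any(!is.na(freq) & (freq < 0 | freq > 100)))
        stop("population_frequency must be a percent in [0, 100]")
    freqMissing <- is.na(freq)
    freq[freqMissing] <- 0
    rare <- freq < freq_max_pct
    score <- table$deleteriousness_score
    deleterious <- if (score_comparator == ">=") score >= score_min
                   else score > score_min
    deleterious[is.na(deleterious)] <- FALSE
    out <- table
    out$rare <- rare
    out$deleterious <- deleterious
    out$pass <- rare & deleterious
    out$freq_missing <- freqMissing
    out$fail_reason <- ifelse(out$pass, "",
        trimws(paste(ifelse(rare, "", "frequency"),
                     ifelse(deleterious, "", "score"))))
    out
}

#' Summarize an annotated variant table per panel category
#'
#' Four sections per panel: variant-type distribution, frequency bins,
#' count at the deleteriousness threshold, and the combined rare +
#' deleterious count; bin edges are explicit in the output.
#'
#' @param table annotated variant data.frame.
#' @param panels list of panels from [genePanels()].
#' @param freq_max_pct,score_min,score_comparator filter settings as in
#'   [applyRareDeleterious()].
#' @return named list per panel with elements variant_types,
#'   frequency_bins, deleterious_count, combined_count, n_total.
#' @export
summarizeVariants <- function(table, panels, freq_max_pct = 0.01,
                              score_min = 20, score_comparator = ">=") {
    freqBreaks <- c(0, 0.01, 0.1, 1, 10, 100)
    out <- lapply(panels, function(panel) {
        sub <- filterPanel(table, panel)
        flt <- applyRareDeleterious(sub, freq_max_pct, score_min,
                                    score_comparator)
        fr <- flt$population_frequency
        fr[is.na(fr)] <- 0
        bins <- table(cut(fr, freqBreaks, right = FALSE,
                          include.lowest = TRUE,
                          labels = paste0("[", head(freqBreaks, -1), ",",
                                          freqBreaks[-1], ")%")))
        list(panel = panel$name, category = panel$category,
             n_total = nrow(sub),
             variant_types = table(factor(sub$variant_type)),
             frequency_bins = bins,
             deleterious_count = sum(flt$deleterious),
             combined_count = sum(flt$pass))
    })
    names(out) <- vapply(panels, `[[`, "", "name")
    out
}

#' Per-donor candidate report
#'
#' Candidates (rows passing the combined filter) with donor, gene,
#' change, zygosity and evidence fields, flagged against a supplied
#' known-variant list; unknown candidates are marked as needing
#' functional study.
#'
#' @param subset output of [applyRareDeleterious()] (pass column used)
#'   or any annotated variant data.frame.
#' @param known optional data.frame(gene, dna_change) of previously
#'   validated variants.
#' @return data.frame of candidates with previously_validated and
#'   status columns (empty, with headers, when nothing passes).
#' @export
candidateReport <- function(subset, known = NULL) {
    if (!"pass" %in% names(subset))
        subset <- applyRareDeleterious(subset)
    cand <- subset[subset$pass, , drop = FALSE]
    keep <- intersect(c("donor_id", "gene", "dna_change",
                        "protein_change", "zygosity",
                        "population_frequency", "deleteriousness_score"),
                      names(cand))
    out <- cand[keep]
    validated <- rep(FALSE, nrow(out))
    if (!is.null(known) && nrow(out))
        validated <- paste(toupper(out$gene), out$dna_change) %in%
            paste(toupper(known$gene), known$dna_change)
    out$previously_validated <- validated
    out$status <- ifelse(validated, "previously validated",
                         "needs functional study")
    rownames(out) <- NULL
    out
}
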