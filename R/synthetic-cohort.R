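#' Specify a synthetic cohort
#'
#' Bundles and validates every parameter of the synthetic cohort
#' generators.  The defaults describe a 5-population reference with
#' moderate divergence, uniform Dirichlet admixture, a small planted
#' pedigree, and array-like missingness.
#'
#' @param n_samples number of admixed cohort samples.
#' @param n_variants number of autosomal variants.
#' @param n_populations K, number of ancestral populations (>= 2).
#' @param fst divergence parameter per population, each in (0, 1);
#'   recycled to length K.
#' @param alpha Dirichlet concentration vector (length K, all > 0).
#' @param pedigree_plan data.frame(relationship, count); relationships
#'   from duplicate, parent_offspring, full_sibling, second_degree,
#'   third_degree.
#' @param replicate_error_rate per-genotype corruption probability for
#'   duplicate samples, in [0, 1].
#' @param missing_rate probability any call is missing, in [0, 1].
#' @param x_variant_count number of X-chromosome variants.
#' @param seed integer seed; every generator taking the spec is
#'   deterministic given it.
#' @return A validated list of class \code{"CohortSpec"}.
#' @export
cohortSpec <- function(n_samples = 300, n_variants = 2000,
                       n_populations = 5, fst = 0.1, alpha = 1,
                       pedigree_plan = NULL,
                       replicate_error_rate = 0.001,
                       missing_rate = 0.002, x_variant_count = 100,
                       seed = 1L) {
    K <- as.integer(n_populations)
    if (is.na(K) || K < 2)
        stop("n_populations: must be an integer >= 2")
    fst <- rep_len(fst, K)
    if (any(fst <= 0) || any(fst >= 1))
        stop("fst: divergence parameters must lie in (0, 1)")
    alpha <- rep_len(alpha, K)
    if (any(alpha <= 0))
        stop("alpha: Dirichlet concentrations must be strictly positive")
    for (nm in c("replicate_error_rate", "missing_rate")) {
        v <- get(nm)
        if (length(v) != 1 || is.na(v) || v < 0 || v > 1)
            stop(nm, ": rate must lie in [0, 1]")
    }
    if (n_samples < 0 || n_variants < 1 || x_variant_count < 0)
        stop("n_samples/n_variants/x_variant_count: invalid count")
    if (!is.null(pedigree_plan)) {
        ok <- c("duplicate", "parent_offspring", "full_sibling",
                "second_degree", "third_degree")
        bad <- setdiff(pedigree_plan$relationship, ok)
        if (length(bad))
            stop("pedigree_plan: unknown relationship label(s): ",
                 paste(bad, collapse = ", "))
    }
    structure(list(n_samples = as.integer(n_samples),
                   n_variants = as.integer(n_variants),
                   n_populations = K, fst = fst, alpha = alpha,
                   pedigree_plan = pedigree_plan,
                   replicate_error_rate = replicate_error_rate,
                   missing_rate = missing_rate,
                   x_variant_count = as.integer(x_variant_count),
                   seed = as.integer(seed)),
              class = "CohortSpec")
}

# Balding-Nichols population frequencies: ancestral p ~ U(0.05, 0.95),
# population frequency ~ Beta(p(1-F)/F, (1-p)(1-F)/F).
.baldingNichols <- function(M, fst) {
    p <- runif(M, 0.05, 0.95)
    K <- length(fst)
    f <- matrix(0, K, M)
    for (k in seq_len(K)) {
        Fk <- fst[k]
        f[k, ] <- rbeta(M, p * (1 - Fk) / Fk, (1 - p) * (1 - Fk) / Fk)
    }
    pmin(pmax(f, 1e-4), 1 - 1e-4)
}

.variantTable <- function(M, chrom = NULL, prefix = "var") {
    if (is.null(chrom))   # spread over autosomes, ordered chrom then pos
        chrom <- as.character(sort(rep_len(1:22, M)))
    pos <- integer(M)
    for (cc in unique(chrom))
        pos[chrom == cc] <- seq(1e4, by = 5000, length.out = sum(chrom == cc))
    alleles <- c("A", "C", "G", "T")
    ref <- sample(alleles, M, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), "")
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               id = sprintf("%s%06d", prefix, seq_len(M)),
               counted = alt, stringsAsFactors = FALSE)
}

#' Simulate an unadmixed labeled reference panel
#'
#' Draws K divergent population allele-frequency vectors under the
#' Balding-Nichols model and binomial genotypes for
#' \code{samples_per_pop} individuals per population.
#'
#' @param spec a [cohortSpec()].
#' @param samples_per_pop individuals simulated per population.
#' @return list(genotypes = GenotypeMatrix, population = character
#'   per-sample labels, freq = K x M truth frequency matrix).
#' @export
simulateReferencePanel <- function(spec, samples_per_pop = 100) {
    stopifnot(inherits(spec, "CohortSpec"))
    set.seed(spec$seed)
    M <- spec$n_variants
    K <- spec$n_populations
    f <- .baldingNichols(M, spec$fst)
    pops <- paste0("POP", seq_len(K))
    rownames(f) <- pops
    n <- K * samples_per_pop
    calls <- matrix(NA_integer_, M, n)
    labels <- rep(pops, each = samples_per_pop)
    for (k in seq_len(K)) {
        idx <- which(labels == pops[k])
        calls[, idx] <- rbinom(M * length(idx), 2, f[k, ])
    }
    if (spec$missing_rate > 0)
        calls[runif(length(calls)) < spec$missing_rate] <- NA_integer_
    variants <- .variantTable(M)
    samples <- data.frame(sample_id = sprintf("REF%04d", seq_len(n)),
                          reported_sex = "unknown",
                          population = labels)
    list(genotypes = GenotypeMatrix(calls, variants, samples),
         population = labels, freq = f)
}

.rdirichlet <- function(n, alpha) {
    K <- length(alpha)
    g <- matrix(rgamma(n * K, shape = rep(alpha, each = n)), n, K)
    g / rowSums(g)
}

#' Simulate admixed samples from an ancestry model
#'
#' Each sample's ancestry vector q is drawn from Dirichlet(alpha) (or
#' supplied), and its genotype at variant m is Binomial(2, sum_k q_k
#' f_km).  The drawn q vectors are returned as ground truth.
#'
#' @param model an \linkS4class{AncestryModel}.
#' @param alpha Dirichlet concentration vector of length K.
#' @param n number of samples.
#' @param seed integer seed.
#' @param Q optional n x K matrix of ancestry vectors to use instead of
#'   Dirichlet draws.
#' @param missing_rate per-call missingness probability.
#' @return list(genotypes = GenotypeMatrix, Q = n x K truth matrix).
#' @export
simulateAdmixedSamples <- function(model, alpha, n, seed = 1L, Q = NULL,
                                   missing_rate = 0) {
    f <- model@freq
    K <- nrow(f)
    if (is.null(Q) && length(alpha) != K)
        stop("alpha length (", length(alpha), ") must equal K (", K, ")")
    set.seed(seed)
    M <- ncol(f)
    if (is.null(Q))
        Q <- if (n > 0) .rdirichlet(n, alpha) else
            matrix(0, 0, K)
    colnames(Q) <- model@populations
    calls <- matrix(NA_integer_, M, n)
    if (n > 0) {
        P <- t(Q %*% f)                     # M x n mixture frequencies
        calls <- matrix(rbinom(M * n, 2, as.vector(P)), M, n)
        if (missing_rate > 0)
            calls[runif(length(calls)) < missing_rate] <- NA_integer_
    }
    samples <- data.frame(sample_id = if (n > 0)
        sprintf("ADM%04d", seq_len(n)) else character())
    rownames(Q) <- samples$sample_id
    list(genotypes = GenotypeMatrix(calls, model@variantKeys, samples),
         Q = Q)
}

# gene-drop one meiosis: child allele matrix from two parent allele
# matrices (each M x 2 of 0/1 alleles)
.meiosis <- function(par1, par2) {
    M <- nrow(par1)
    pick1 <- par1[cbind(seq_len(M), sample(1:2, M, replace = TRUE))]
    pick2 <- par2[cbind(seq_len(M), sample(1:2, M, replace = TRUE))]
    cbind(pick1, pick2)
}

.founder <- function(freq) {
    M <- length(freq)
    cbind(rbinom(M, 1, freq), rbinom(M, 1, freq))
}

#' Simulate related sample pairs by Mendelian gene-dropping
#'
#' Builds, for each requested relationship, the minimal pedigree and
#' drops alleles through it so that each pair's genotypes are exactly
#' Mendelian-consistent: duplicates are copies with independent
#' per-genotype corruption, parent-offspring and full siblings share a
#' nuclear family, second degree is realized as half siblings and third
#' degree as first cousins.
#'
#' @param founder_freqs counted-allele frequency per variant, in (0, 1).
#' @param plan data.frame(relationship, count).
#' @param seed integer seed.
#' @param replicate_error_rate corruption rate for duplicate copies.
#' @param chrom chromosome label for the simulated variants.
#' @return list(genotypes = GenotypeMatrix of all pair members,
#'   relationships = data.frame(sample_a, sample_b, relationship)).
#' @export
simulatePedigreePairs <- function(founder_freqs, plan, seed = 1L,
                                  replicate_error_rate = 0) {
    if (any(founder_freqs <= 0) || any(founder_freqs >= 1))
        stop("founder_freqs must lie strictly in (0, 1)")
    ok <- c("duplicate", "parent_offspring", "full_sibling",
            "second_degree", "third_degree")
    bad <- setdiff(plan$relationship, ok)
    if (length(bad))
        stop("unknown relationship label(s): ", paste(bad, collapse = ", "))
    set.seed(seed)
    M <- length(founder_freqs)
    geno <- function(al) as.integer(al[, 1] + al[, 2])
    cols <- list(); ids <- character(); rel <- list()
    n <- 0L
    addPair <- function(g1, g2, label) {
        n2 <- length(cols)
        cols[[n2 + 1]] <<- g1; cols[[n2 + 2]] <<- g2
        a <- sprintf("PED%04d", n2 + 1); b <- sprintf("PED%04d", n2 + 2)
        ids <<- c(ids, a, b)
        rel[[length(rel) + 1]] <<- data.frame(sample_a = a, sample_b = b,
                                              relationship = label)
    }
    for (r in seq_len(nrow(plan))) {
        label <- plan$relationship[r]
        for (i in seq_len(plan$count[r])) {
            if (label == "duplicate") {
                g <- geno(.founder(founder_freqs))
                g2 <- g
                flip <- which(runif(M) < replicate_error_rate)
                if (length(flip))
                    g2[flip] <- vapply(g2[flip], function(v)
                        sample(setdiff(0:2, v), 1L), integer(1))
                addPair(g, g2, label)
            } else if (label == "parent_offspring") {
                p1 <- .founder(founder_freqs); p2 <- .founder(founder_freqs)
                ch <- .meiosis(p1, p2)
                addPair(geno(p1), geno(ch), label)
            } else if (label == "full_sibling") {
                p1 <- .founder(founder_freqs); p2 <- .founder(founder_freqs)
                addPair(geno(.meiosis(p1, p2)), geno(.meiosis(p1, p2)), label)
            } else if (label == "second_degree") {
                # half siblings: shared parent p1
                p1 <- .founder(founder_freqs)
                p2 <- .founder(founder_freqs); p3 <- .founder(founder_freqs)
                addPair(geno(.meiosis(p1, p2)), geno(.meiosis(p1, p3)), label)
            } else if (label == "third_degree") {
                # first cousins: siblings s1, s2 married into founders
                g1 <- .founder(founder_freqs); g2 <- .founder(founder_freqs)
                s1 <- .meiosis(g1, g2); s2 <- .meiosis(g1, g2)
                c1 <- .meiosis(s1, .founder(founder_freqs))
                c2 <- .meiosis(s2, .founder(founder_freqs))
                addPair(geno(c1), geno(c2), label)
            }
        }
    }
    calls <- if (length(cols)) do.call(cbind, cols) else
        matrix(NA_integer_, M, 0)
    variants <- .variantTable(M, prefix = "ped")
    gm <- GenotypeMatrix(calls, variants, data.frame(sample_id = ids))
    list(genotypes = gm,
         relationships = if (length(rel)) do.call(rbind, rel) else
             data.frame(sample_a = character(), sample_b = character(),
                        relationship = character()))
}

#' Simulate sex-linked X genotypes
#'
#' Males are hemizygous, coded 0/2 on the diploid scale as array exports
#' commonly do; females are diploid binomial draws.
#'
#' @param n_samples number of samples.
#' @param n_variants number of X variants.
#' @param seed integer seed.
#' @param maf allele-frequency range for the X variants.
#' @return list(genotypes = GenotypeMatrix with chrom "X",
#'   sex = character truth vector).
#' @export
simulateXGenotypes <- function(n_samples, n_variants, seed = 1L,
                               maf = c(0.2, 0.5)) {
    set.seed(seed)
    f <- runif(n_variants, maf[1], maf[2])
    sex <- sample(c("male", "female"), n_samples, replace = TRUE)
    calls <- matrix(NA_integer_, n_variants, n_samples)
    for (j in seq_len(n_samples)) {
        calls[, j] <- if (sex[j] == "male")
            2L * rbinom(n_variants, 1, f)
        else rbinom(n_variants, 2, f)
    }
    variants <- .variantTable(n_variants, chrom = rep("X", n_variants),
                              prefix = "xvar")
    samples <- data.frame(sample_id = sprintf("SMP%04d", seq_len(n_samples)),
                          reported_sex = sex)
    list(genotypes = GenotypeMatrix(calls, variants, samples), sex = sex)
}

#' Load the per-locus HLA allele dictionary shipped with the package
#'
#' @return data.frame(locus, allele) of 4-digit allele names used as
#'   truth and decoy pools by [simulateHLACalls()].
#' @export
hlaAlleleDictionary <- function() {
    read.table(system.file("extdata", "hla_allele_dictionary.tsv",
                           package = "cohortval"),
               header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Simulate imputed HLA calls against typed truth
#'
#' Each imputed allele equals the typed truth with probability
#' \code{1 - error_rate}; otherwise a decoy allele is drawn uniformly
#' from the other alleles of the same locus in the dictionary.  Reported
#' probabilities of correct calls are Beta-distributed with mean
#' \code{probability_calibration}, so downstream locus accuracy has
#' expectation \code{(1 - error_rate) * probability_calibration}.
#'
#' @param typed data.frame(donor_id, locus, allele1, allele2) of truth
#'   calls, 4-digit alleles.
#' @param probability_calibration target mean reported probability of
#'   correct calls, in (0, 1].
#' @param error_rate per-allele miscall probability in [0, 1].
#' @param seed integer seed.
#' @param calibration_concentration Beta concentration of reported
#'   probabilities.
#' @return data.frame(donor_id, locus, allele1, allele2, prob1, prob2).
#' @export
simulateHLACalls <- function(typed, probability_calibration = 0.95,
                             error_rate = 0, seed = 1L,
                             calibration_concentration = 60) {
    if (error_rate < 0 || error_rate > 1)
        stop("error_rate must lie in [0, 1]")
    set.seed(seed)
    dict <- hlaAlleleDictionary()
    drawProb <- function(n, mean) {
        if (mean >= 1) return(rep(1, n))
        k <- calibration_concentration
        rbeta(n, mean * k, (1 - mean) * k)
    }
    out <- typed[c("donor_id", "locus")]
    imp <- matrix("", nrow(typed), 2)
    prob <- matrix(0, nrow(typed), 2)
    for (i in seq_len(nrow(typed))) {
        loc <- typed$locus[i]
        pool <- dict$allele[dict$locus == loc]
        # decoys avoid the donor's whole typed set so a miscall is
        # always discordant under set-membership scoring
        typedSet <- c(typed$allele1[i], typed$allele2[i])
        for (a in 1:2) {
            truth <- typed[[paste0("allele", a)]][i]
            if (runif(1) < error_rate) {
                decoys <- setdiff(pool, typedSet)
                imp[i, a] <- sample(decoys, 1)
                prob[i, a] <- runif(1, 0.3, 0.9)
            } else {
                imp[i, a] <- truth
                prob[i, a] <- drawProb(1, probability_calibration)
            }
        }
    }
    out$allele1 <- imp[, 1]; out$allele2 <- imp[, 2]
    out$prob1 <- prob[, 1]; out$prob2 <- prob[, 2]
    out
}

#' Simulate typed HLA truth records
#'
#' @param n_donors number of donors.
#' @param loci loci to type; defaults to the four-locus panel A, DRB1,
#'   DQA1, DQB1.
#' @param seed integer seed.
#' @return data.frame(donor_id, locus, allele1, allele2).
#' @export
simulateTypedHLA <- function(n_donors,
                             loci = c("A", "DRB1", "DQA1", "DQB1"),
                             seed = 1L) {
    set.seed(seed)
    dict <- hlaAlleleDictionary()
    rows <- list()
    for (loc in loci) {
        pool <- dict$allele[dict$locus == loc]
        rows[[loc]] <- data.frame(
            donor_id = sprintf("DON%04d", seq_len(n_donors)),
            locus = loc,
            allele1 = sample(pool, n_donors, replace = TRUE),
            allele2 = sample(pool, n_donors, replace = TRUE))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[order(out$donor_id, out$locus), ]
}

#' Simulate a second genotyping platform from a base callset
#'
#' Copies the base matrix and corrupts each call independently with
#' probability \code{discordance_rate} (to a different hard call) and
#' sets it missing with probability \code{missing_rate_b}.
#'
#' @param base a \linkS4class{GenotypeMatrix}.
#' @param discordance_rate per-call corruption probability in [0, 1].
#' @param missing_rate_b per-call missingness probability in [0, 1].
#' @param seed integer seed.
#' @return a \linkS4class{GenotypeMatrix} of the same shape.
#' @export
simulatePlatformPair <- function(base, discordance_rate = 0,
                                 missing_rate_b = 0, seed = 1L) {
    if (discordance_rate < 0 || discordance_rate > 1 ||
        missing_rate_b < 0 || missing_rate_b > 1)
        stop("rates must lie in [0, 1]")
    set.seed(seed)
    calls <- genotypeCalls(base)
    flip <- !is.na(calls) & matrix(runif(length(calls)) < discordance_rate,
                                   nrow(calls))
    idx <- which(flip)
    if (length(idx))
        calls[idx] <- vapply(calls[idx], function(v)
            sample(setdiff(0:2, v), 1L), integer(1))
    if (missing_rate_b > 0)
        calls[matrix(runif(length(calls)) < missing_rate_b, nrow(calls))] <-
            NA_integer_
    GenotypeMatrix(calls, variantInfo(base), sampleInfo(base))
}

#' Simulate an annotated coding-variant table
#'
#' Rows carry gene, HGVS-style change strings, zygosity, a population
#' frequency (percent) and a scaled deleteriousness score.  Rarity and
#' deleteriousness are drawn independently so the expected count passing
#' the combined filter is \code{n * rare_fraction * deleterious_fraction};
#' the truth pass subset is recorded.
#'
#' @param genes character vector of gene symbols to draw from.
#' @param n number of rows.
#' @param rare_fraction probability a row is rare (< 0.01 percent).
#' @param deleterious_fraction probability a row is deleterious
#'   (score >= 20).
#' @param seed integer seed.
#' @return list(table = data.frame, truth_pass = logical vector).
#' @export
simulateAnnotatedVariants <- function(genes, n, rare_fraction = 0.1,
                                      deleterious_fraction = 0.2,
                                      seed = 1L) {
    set.seed(seed)
    types <- c("missense", "nonsense/stopgain", "frameshift",
               "inframe indel", "splice", "synonymous", "other")
    rare <- runif(n) < rare_fraction
    delet <- runif(n) < deleterious_fraction
    freq <- ifelse(rare, runif(n, 0, 0.0099), runif(n, 0.011, 5))
    score <- ifelse(delet, runif(n, 20, 45), runif(n, 0, 19.9))
    tab <- data.frame(
        donor_id = sprintf("DON%04d", sample(200, n, replace = TRUE)),
        gene = sample(genes, n, replace = TRUE),
        dna_change = sprintf("c.%dG>A", sample(3000, n, replace = TRUE)),
        protein_change = sprintf("p.V%dM", sample(900, n, replace = TRUE)),
        zygosity = sample(c("Het", "Hom"), n, replace = TRUE,
                          prob = c(0.95, 0.05)),
        variant_type = sample(types, n, replace = TRUE,
            prob = c(0.45, 0.03, 0.03, 0.03, 0.06, 0.35, 0.05)),
        population_frequency = freq,
        deleteriousness_score = score)
    list(table = tab, truth_pass = rare & delet)
}

#' Simulate a complete validation cohort
#'
#' Convenience wrapper tying the individual generators together with a
#' single seed: a labeled reference panel, admixed study samples with
#' known ancestry, planted related pairs, X genotypes with known sex,
#' typed + imputed HLA, a second platform, and an annotated variant
#' table.
#'
#' @param spec a [cohortSpec()].
#' @return named list with elements reference, admixed, pedigree, xchrom,
#'   hla, platform_b, variants, each keeping its own ground truth.
#' @export
simulateCohort <- function(spec) {
    stopifnot(inherits(spec, "CohortSpec"))
    ref <- simulateReferencePanel(spec, samples_per_pop = 60)
    model <- fitReference(ref$genotypes, ref$population)
    adm <- simulateAdmixedSamples(model, spec$alpha, spec$n_samples,
                                  seed = spec$seed + 1L,
                                  missing_rate = spec$missing_rate)
    plan <- spec$pedigree_plan
    if (is.null(plan))
        plan <- data.frame(relationship = "duplicate", count = 2)
    ped <- simulatePedigreePairs(runif(spec$n_variants, 0.1, 0.5),
                                 plan, seed = spec$seed + 2L,
                                 replicate_error_rate =
                                     spec$replicate_error_rate)
    xg <- simulateXGenotypes(spec$n_samples, spec$x_variant_count,
                             seed = spec$seed + 3L)
    typed <- simulateTypedHLA(spec$n_samples, seed = spec$seed + 4L)
    imputed <- simulateHLACalls(typed, probability_calibration = 0.95,
                                error_rate = 0.05, seed = spec$seed + 5L)
    platB <- simulatePlatformPair(adm$genotypes, discordance_rate = 0.02,
                                  missing_rate_b = spec$missing_rate,
                                  seed = spec$seed + 6L)
    panels <- genePanels()
    av <- simulateAnnotatedVariants(unlist(lapply(panels, `[[`, "genes")),
                                    n = 500, seed = spec$seed + 7L)
    list(reference = ref, model = model, admixed = adm, pedigree = ped,
         xchrom = xg, hla = list(typed = typed, imputed = imputed),
         platform_b = platB, variants = av)
}
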