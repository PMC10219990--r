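test_that("cohortSpec validates fields and names the offender", {
    expect_error(cohortSpec(n_populations = 1), "n_populations")
    expect_error(cohortSpec(fst = 1.2), "fst")
    expect_error(cohortSpec(alpha = c(1, -1)), "alpha")
    expect_error(cohortSpec(missing_rate = 1.5), "missing_rate")
    expect_error(cohortSpec(pedigree_plan = data.frame(
        relationship = "cousin_twice", count = 1)), "cousin_twice")
})

test_that("reference panel divergence scales with F and is seeded", {
    specLow <- cohortSpec(n_variants = 2000, n_populations = 2,
                          fst = 0.01, missing_rate = 0, seed = 11)
    specHigh <- cohortSpec(n_variants = 2000, n_populations = 2,
                           fst = 0.3, missing_rate = 0, seed = 11)
    freqDiff <- function(ref) {
        g <- genotypeCalls(ref$genotypes)
        f1 <- rowMeans(g[, ref$population == "POP1"]) / 2
        f2 <- rowMeans(g[, ref$population == "POP2"]) / 2
        mean(abs(f1 - f2))
    }
    low <- simulateReferencePanel(specLow, samples_per_pop = 200)
    high <- simulateReferencePanel(specHigh, samples_per_pop = 200)
    expect_gt(freqDiff(high), 3 * freqDiff(low))
    again <- simulateReferencePanel(specHigh, samples_per_pop = 200)
    expect_identical(genotypeCalls(again$genotypes),
                     genotypeCalls(high$genotypes))
    expect_identical(again$freq, high$freq)
})

test_that("admixed samples honor alpha, empty n, and frequency conservation", {
    spec <- cohortSpec(n_variants = 500, n_populations = 3, fst = 0.2,
                       missing_rate = 0, seed = 5)
    ref <- simulateReferencePanel(spec, samples_per_pop = 80)
    model <- fitReference(ref$genotypes, ref$population)
    expect_error(simulateAdmixedSamples(model, alpha = c(1, 1), n = 5),
                 "alpha length")
    empty <- simulateAdmixedSamples(model, alpha = rep(1, 3), n = 0)
    expect_equal(nSamples(empty$genotypes), 0)
    expect_equal(nrow(empty$Q), 0)

    adm <- simulateAdmixedSamples(model, alpha = rep(1, 3), n = 500,
                                  seed = 6)
    expect_true(all(abs(rowSums(adm$Q) - 1) < 1e-9))
    expect_true(all(abs(colMeans(adm$Q) - 1 / 3) < 0.03))

    big <- simulateAdmixedSamples(model, alpha = rep(1, 3), n = 2000,
                                  seed = 7)
    pooled <- rowMeans(genotypeCalls(big$genotypes)) / 2
    expected <- as.vector(colMeans(big$Q) %*% model@freq)
    expect_lt(max(abs(pooled - expected)), 0.02)
})

test_that("gene-dropped pairs are Mendelian-consistent and seeded", {
    freqs <- runif(300, 0.1, 0.5)
    plan <- data.frame(relationship = c("duplicate", "parent_offspring",
                                        "full_sibling", "second_degree",
                                        "third_degree"),
                       count = c(3, 3, 3, 3, 3))
    sim <- simulatePedigreePairs(freqs, plan, seed = 9,
                                 replicate_error_rate = 0)
    expect_equal(nrow(sim$relationships), 15)
    calls <- genotypeCalls(sim$genotypes)
    dup <- sim$relationships[sim$relationships$relationship ==
                             "duplicate", ]
    for (r in seq_len(nrow(dup)))
        expect_identical(calls[, dup$sample_a[r]], calls[, dup$sample_b[r]])
    # parent-offspring: offspring must carry at least one parental allele
    # at every variant (parent hom 0 forbids offspring 2 and vice versa)
    po <- sim$relationships[sim$relationships$relationship ==
                            "parent_offspring", ]
    for (r in seq_len(nrow(po))) {
        gp <- calls[, po$sample_a[r]]; gc <- calls[, po$sample_b[r]]
        expect_false(any(gp == 0 & gc == 2))
        expect_false(any(gp == 2 & gc == 0))
    }
    again <- simulatePedigreePairs(freqs, plan, seed = 9,
                                   replicate_error_rate = 0)
    expect_identical(genotypeCalls(again$genotypes), calls)
    expect_error(simulatePedigreePairs(freqs,
        data.frame(relationship = "uncle", count = 1)), "uncle")
    expect_error(simulatePedigreePairs(c(0, 0.5),
        data.frame(relationship = "duplicate", count = 1)),
        "strictly")
})

test_that("full-sibling pairs center at kinship 1/4", {
    freqs <- runif(5000, 0.1, 0.5)
    sim <- simulatePedigreePairs(freqs,
        data.frame(relationship = "full_sibling", count = 30), seed = 21)
    est <- estimateKinship(sim$genotypes, sim$relationships[1:2])
    expect_gt(mean(est$phi), 0.20)
    expect_lt(mean(est$phi), 0.30)
})

test_that("simulated HLA calls hit the error/calibration contract", {
    typed <- simulateTypedHLA(60, loci = "DRB1", seed = 2)
    clean <- simulateHLACalls(typed, probability_calibration = 1,
                              error_rate = 0, seed = 3)
    expect_equal(as.numeric(accLocus(clean, typed, "DRB1", 4)), 1)
    allWrong <- simulateHLACalls(typed, probability_calibration = 1,
                                 error_rate = 1, seed = 3)
    expect_equal(as.numeric(accLocus(allWrong, typed, "DRB1", 4)), 0)
    expect_error(simulateHLACalls(typed, error_rate = 1.4), "error_rate")
})

test_that("platform pair corruption matches its dials", {
    base <- toyMatrix(matrix(rbinom(600, 2, 0.4), 100, 6))
    same <- simulatePlatformPair(base, 0, 0, seed = 4)
    expect_identical(genotypeCalls(same), genotypeCalls(base))
    conc <- perSnpConcordance(base, same)
    expect_true(all(conc$concordance == 1))
    gone <- simulatePlatformPair(base, 0, 1, seed = 4)
    expect_true(all(is.na(genotypeCalls(gone))))
    conc2 <- perSnpConcordance(base, simulatePlatformPair(base, 0.05,
                                                          seed = 4),
                               mac_in = "a")
    expect_lt(abs(mean(conc2$concordance) - 0.95), 0.02)
})

test_that("annotated variant tables pass at the planted joint rate", {
    sim0 <- simulateAnnotatedVariants(c("GCK", "INS"), 200,
                                      rare_fraction = 0, seed = 5)
    flt0 <- applyRareDeleterious(sim0$table)
    expect_equal(sum(flt0$rare), 0)
    expect_equal(sum(flt0$pass), 0)
    sim <- simulateAnnotatedVariants(c("GCK", "INS"), 1000,
                                     rare_fraction = 0.1,
                                     deleterious_fraction = 0.2,
                                     seed = 6)
    flt <- applyRareDeleterious(sim$table)
    expect_identical(flt$pass, sim$truth_pass)
    # binomial(1000, 0.02): 3.5 sd band around 20
    expect_lt(abs(sum(flt$pass) - 20), 3.5 * sqrt(1000 * 0.02 * 0.98))
    again <- simulateAnnotatedVariants(c("GCK", "INS"), 1000,
                                       rare_fraction = 0.1,
                                       deleterious_fraction = 0.2,
                                       seed = 6)
    expect_identical(again$table, sim$table)
})

test_that("X genotypes encode hemizygous males as 0/2", {
    xg <- simulateXGenotypes(50, 80, seed = 8)
    calls <- genotypeCalls(xg$genotypes)
    males <- which(xg$sex == "male")
    expect_true(all(calls[, males] %in% c(0L, 2L)))
    females <- which(xg$sex == "female")
    expect_gt(mean(calls[, females] == 1L), 0.1)
})
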