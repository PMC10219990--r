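mkDosages <- function(ids, r2, dosages, counted = NULL, ref = "A",
                      alt = "G") {
    M <- length(ids)
    vi <- data.frame(chrom = "1", pos = seq(100, by = 100,
                                            length.out = M),
                     ref = ref, alt = alt, id = ids,
                     imputation_r2 = r2)
    if (!is.null(counted)) vi$counted <- counted
    DosageMatrix(matrix(dosages, M), vi, paste0("s", seq_len(
        length(dosages) / M)))
}

test_that("variant resolution prefers direct, falls back to proxy", {
    model <- grsModel("t", data.frame(id = "rs1", effect_allele = "G",
                                      weight = 1),
                      proxy_map = data.frame(variant = "rs1",
                                             proxy = "rsP"))
    direct <- resolveVariants(model, mkDosages(c("rs1", "rsP"),
                                               c(0.99, 0.99), c(1, 1)))
    expect_equal(direct$used_id, "rs1")
    expect_false(direct$substituted)

    absent <- resolveVariants(model, mkDosages("rsP", 0.99, 1))
    expect_equal(absent$used_id, "rsP")
    expect_true(absent$substituted)

    lowr2 <- resolveVariants(model, mkDosages(c("rs1", "rsP"),
                                              c(0.90, 0.99), c(1, 1)))
    expect_equal(lowr2$used_id, "rsP")
    expect_true(lowr2$substituted)

    gone <- resolveVariants(model, mkDosages(c("rs1", "rsP"),
                                             c(0.90, 0.90), c(1, 1)))
    expect_true(gone$missing)
})

test_that("R2 filtering is strictly greater-than", {
    model <- grsModel("t", data.frame(id = "rs1", effect_allele = "G",
                                      weight = 1), r2_min = 0.97)
    atThreshold <- resolveVariants(model, mkDosages("rs1", 0.97, 1))
    expect_true(atThreshold$missing)
    above <- resolveVariants(model, mkDosages("rs1", 0.9701, 1))
    expect_false(above$missing)
})

test_that("additive component is the weighted effect-dosage sum", {
    model <- grsModel("t", data.frame(id = paste0("rs", 1:3),
                                      effect_allele = "G",
                                      weight = c(0.5, 1.0, -0.2)))
    d <- mkDosages(paste0("rs", 1:3), 0.99, c(2, 1, 0))
    expect_equal(unname(scoreAdditive(model, d)), 2.0)
    zero <- grsModel("t", data.frame(id = paste0("rs", 1:3),
                                     effect_allele = "G", weight = 0))
    expect_equal(unname(scoreAdditive(zero, d)), 0)
})

test_that("effect alleles on the non-counted strand flip the dosage", {
    model <- grsModel("t", data.frame(id = "rs1", effect_allele = "A",
                                      weight = 1))
    d <- mkDosages("rs1", 0.99, 0.4)      # counted allele G, dosage 0.4
    expect_equal(unname(scoreAdditive(model, d)), 2 - 0.4)
    bad <- grsModel("t", data.frame(id = "rs1", effect_allele = "T",
                                    weight = 1))
    res <- resolveVariants(bad, d)
    expect_true(res$missing)
    expect_equal(res$reason, "allele_mismatch")
})

test_that("HLA diplotype lookup is unordered with additive rows per copy", {
    model <- grsModel("t", data.frame(id = character(),
                                      effect_allele = character(),
                                      weight = numeric()),
        interaction_terms = data.frame(
            hap1 = c("DR3", "DR15"), hap2 = c("DR4", NA),
            weight = c(3.0, -2.0)))
    tags <- data.frame(sample_id = c("a", "b", "c", "d"),
                       hap1 = c("DR3", "DR4", "DR8", "DR15"),
                       hap2 = c("DR4", "DR3", "DR8", "DR15"))
    sc <- scoreHlaInteractions(model, tags)
    expect_equal(sc$hla_component, c(3.0, 3.0, 0, -4.0))
    expect_equal(sc$matched, c(TRUE, TRUE, FALSE, TRUE))
})

test_that("computeGRS totals, normalizes last, and audits", {
    model <- grsModel("t", data.frame(id = "rs1", effect_allele = "G",
                                      weight = 1),
        interaction_terms = data.frame(hap1 = "DR3", hap2 = "DR4",
                                       weight = 3.0),
        normalization = c(0, 1 / 10))
    d <- mkDosages("rs1", 0.99, c(2, 2))
    tags <- data.frame(sample_id = c("s1", "s2"), hap1 = "DR3",
                       hap2 = "DR4")
    res <- computeGRS(model, d, tags)
    expect_equal(res$total, c(0.5, 0.5))  # (3 + 2) / 10
    expect_equal(res$hla_component, c(3, 3))
    expect_equal(res$non_hla_component, c(2, 2))
    noNorm <- grsModel("t", model@snpTerms,
                       interaction_terms = model@interactionTerms)
    expect_equal(computeGRS(noNorm, d, tags)$total, c(5, 5))
})

test_that("scores are additive in dosage increments", {
    set.seed(51)
    w <- runif(5, 0.1, 1)
    model <- grsModel("t", data.frame(id = paste0("rs", 1:5),
                                      effect_allele = "G", weight = w))
    base <- runif(5, 0, 1)
    for (i in 1:5) {
        d0 <- mkDosages(paste0("rs", 1:5), 0.99, base)
        bumped <- base; bumped[i] <- bumped[i] + 1
        d1 <- mkDosages(paste0("rs", 1:5), 0.99, bumped)
        expect_equal(unname(scoreAdditive(model, d1) -
                            scoreAdditive(model, d0)), w[i])
    }
})

test_that("proxy substitution is invisible when dosages agree", {
    st <- data.frame(id = "rs1", effect_allele = "G", weight = 0.7)
    withDirect <- grsModel("t", st)
    withProxy <- grsModel("t", st,
                          proxy_map = data.frame(variant = "rs1",
                                                 proxy = "rsP"))
    dDirect <- mkDosages("rs1", 0.99, 1.2)
    dProxy <- mkDosages("rsP", 0.99, 1.2)
    expect_equal(unname(scoreAdditive(withDirect, dDirect)),
                 unname(scoreAdditive(withProxy, dProxy)))
})

test_that("proxy chains are rejected at construction", {
    expect_error(grsModel("t", data.frame(id = "rs1",
                                          effect_allele = "G",
                                          weight = 1),
        proxy_map = data.frame(variant = c("rs1", "rsP"),
                               proxy = c("rsP", "rsQ"))), "chain")
})

test_that("the shipped example model config loads and scores", {
    model <- readGRSModel(system.file("extdata",
                                      "grs_model_example.yaml",
                                      package = "cohortval"))
    expect_s4_class(model, "GRSModel")
    expect_equal(nrow(model@snpTerms), 7)
    expect_equal(model@r2Min, 0.97)
    tags <- data.frame(sample_id = "x", hap1 = "DR3", hap2 = "DR4")
    sc <- scoreHlaInteractions(model, tags)
    expect_equal(sc$hla_component, 3.87)
})

test_that("group summaries recover a planted shift", {
    set.seed(52)
    res <- data.frame(sample_id = paste0("s", 1:200),
                      total = c(rnorm(100, 5), rnorm(100, 6)))
    grouping <- data.frame(sample_id = res$sample_id,
                           group = rep(c("ctrl", "case"), each = 100))
    gs <- grsGroupSummary(res, grouping)
    shift <- gs$median[gs$group == "case"] - gs$median[gs$group == "ctrl"]
    expect_lt(abs(shift - 1), 0.5)
    empty <- grsGroupSummary(res[0, ], data.frame(
        sample_id = character(), group = factor(character(),
                                                levels = "ghost")))
    expect_equal(empty$n, 0)
})
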