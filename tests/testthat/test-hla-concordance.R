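test_that("allele parsing normalizes case, padding and wildcards", {
    p <- parseHLAAllele(c("DRB1*04:xx", "hla-a*2:1", "A*02"))
    expect_equal(p$locus, c("DRB1", "A", "A"))
    expect_equal(p$field1, c("04", "02", "02"))
    expect_equal(p$field2, c(NA, "01", NA))
    expect_equal(p$wildcard, c(TRUE, FALSE, FALSE))
    bare <- parseHLAAllele("03:01:04", locus = "DQB1")
    expect_equal(bare$locus, "DQB1")
    expect_equal(bare$field2, "01")      # suffix fields truncated
    expect_error(parseHLAAllele("*:"), "malformed")
})

test_that("multiset matching never double-claims a typed allele", {
    expect_equal(matchAlleles(c("02:01", "24:02"), c("02:01", "24:02"),
                              "A"), c(TRUE, TRUE))
    # homozygous imputed pair against a single matching typed allele
    expect_equal(sum(matchAlleles(c("02:01", "02:01"),
                                  c("02:01", "03:01"), "A")), 1)
    # wildcard truth absorbs exactly one imputed allele
    expect_equal(sum(matchAlleles(c("04:05", "04:03"),
                                  c("04:xx", "03:01"), "DRB1", 4)), 1)
    # 2-digit resolution compares field 1 only
    expect_equal(matchAlleles(c("04:05", "03:02"), c("04:01", "03:01"),
                              "DRB1", 2), c(TRUE, TRUE))
    # pairing maximizes concordance over the two assignments
    expect_equal(sum(matchAlleles(c("04:01", "04:05"),
                                  c("04:xx", "04:01"), "DRB1", 4)), 2)
})

test_that("Acc(L) zeroes discordant probabilities", {
    typed <- hlaTyped(c("d1", "d2"), c("02:01", "03:01"),
                      c("24:02", "11:01"))
    perfect <- hlaImputed(c("d1", "d2"), c("02:01", "03:01"),
                          c("24:02", "11:01"))
    expect_equal(as.numeric(accLocus(perfect, typed, "A")), 1)
    allWrong <- hlaImputed(c("d1", "d2"), c("68:01", "68:02"),
                           c("68:01", "68:02"), p1 = 0.9, p2 = 0.9)
    expect_equal(as.numeric(accLocus(allWrong, typed, "A")), 0)
    # worked micro-example: (0.9 + 0.8 + 0.7 + 0) / 4 = 0.6
    mixed <- hlaImputed(c("d1", "d2"), c("02:01", "03:01"),
                        c("24:02", "68:01"),
                        p1 = c(0.9, 0.7), p2 = c(0.8, 0.9))
    expect_equal(as.numeric(accLocus(mixed, typed, "A")), 0.6)
})

test_that("Acc(L) excludes unmatched donors and reports them", {
    typed <- hlaTyped(c("d1", "d2"), "02:01", "24:02")
    imputed <- hlaImputed("d1", "02:01", "24:02")
    a <- accLocus(imputed, typed, "A")
    expect_equal(attr(a, "n"), 1)
    expect_equal(attr(a, "n_excluded"), 1)
    expect_equal(as.numeric(a), 1)
})

test_that("Acc(L) is non-increasing from 2-digit to 4-digit", {
    typed <- simulateTypedHLA(80, seed = 41)
    imputed <- simulateHLACalls(typed, probability_calibration = 0.9,
                                error_rate = 0.15, seed = 42)
    for (loc in c("A", "DRB1", "DQA1", "DQB1")) {
        a2 <- as.numeric(accLocus(imputed, typed, loc, 2))
        a4 <- as.numeric(accLocus(imputed, typed, loc, 4))
        expect_lte(a4, a2 + 1e-12)
        expect_gte(a4, 0); expect_lte(a2, 1)
    }
})

test_that("genotype-of-interest concordance is a capped allele ratio", {
    typed <- hlaTyped(c("d1", "d2", "d3"),
                      c("03:01", "03:01", "03:01"),
                      c("03:01", "15:01", "07:01"), locus = "DRB1")
    allFound <- hlaImputed(c("d1", "d2", "d3"),
                           c("03:01", "03:01", "03:01"),
                           c("03:01", "15:01", "07:01"), locus = "DRB1")
    expect_equal(as.numeric(concordanceGenotype(allFound, typed,
                                                "DRB1*03:01")), 1)
    # 4 typed DR3 alleles, one missed by imputation -> 3/4
    oneMiss <- hlaImputed(c("d1", "d2", "d3"),
                          c("03:01", "13:01", "03:01"),
                          c("03:01", "15:01", "07:01"), locus = "DRB1")
    cc <- concordanceGenotype(oneMiss, typed, "DRB1*03:01")
    expect_equal(as.numeric(cc), 0.75)
    expect_equal(attr(cc, "n_typed"), 4)
    # homozygous imputed cannot exceed the typed count
    dbl <- hlaImputed("d2", "03:01", "03:01", locus = "DRB1")
    one <- concordanceGenotype(dbl, typed["d2" == typed$donor_id, ],
                               "DRB1*03:01")
    expect_lte(as.numeric(one), 1)
    und <- concordanceGenotype(allFound, typed, "DRB1*09:01")
    expect_true(attr(und, "undefined"))
    expect_true(is.na(as.numeric(und)))
})

test_that("Acc(S) averages over the donor's typed loci", {
    loci <- c("A", "DRB1", "DQA1", "DQB1")
    typed <- do.call(rbind, lapply(loci, function(l)
        hlaTyped("d1", "02:01", "03:01", locus = l)))
    perfect <- do.call(rbind, lapply(loci, function(l)
        hlaImputed("d1", "02:01", "03:01", locus = l)))
    expect_equal(accSample(perfect, typed)$acc_s, 1)
    # one locus fully discordant -> 6/8
    oneBad <- perfect
    oneBad[oneBad$locus == "DQB1", c("allele1", "allele2")] <-
        c("11:01", "11:01")
    expect_equal(accSample(oneBad, typed, resolution = 4)$acc_s, 0.75)
    # donor typed at 3 loci -> n = 3
    typed3 <- typed[typed$locus != "A", ]
    r <- accSample(perfect, typed3)
    expect_equal(r$n_loci, 3)
    expect_equal(r$acc_s, 1)
})

test_that("group report ordering follows planted error rates", {
    typed <- simulateTypedHLA(120, seed = 43)
    donors <- unique(typed$donor_id)
    gA <- donors[1:60]; gB <- donors[61:120]
    impA <- simulateHLACalls(typed[typed$donor_id %in% gA, ],
                             probability_calibration = 0.95,
                             error_rate = 0.02, seed = 44)
    impB <- simulateHLACalls(typed[typed$donor_id %in% gB, ],
                             probability_calibration = 0.95,
                             error_rate = 0.10, seed = 45)
    grouping <- data.frame(donor_id = donors,
                           group = rep(c("low_err", "high_err"),
                                       each = 60))
    rep <- concordanceReport(rbind(impA, impB), typed,
                             goi = data.frame(label = "DR3",
                                              pattern = "DRB1*03:01",
                                              effect = "risk"),
                             grouping = grouping)
    gs <- rep$group_summary
    expect_gt(gs$acc_s_median[gs$group == "low_err"],
              gs$acc_s_median[gs$group == "high_err"])
    expect_true(all(rep$acc_locus$acc_l >= 0 & rep$acc_locus$acc_l <= 1))
    # empty genotype-of-interest table: accuracy sections only
    rep2 <- concordanceReport(impA, typed[typed$donor_id %in% gA, ])
    expect_null(rep2$goi_table)
    expect_false(is.null(rep2$acc_locus))
})

test_that("missing imputed probabilities count as zero with a warning", {
    typed <- hlaTyped("d1", "02:01", "24:02")
    imp <- hlaImputed("d1", "02:01", "24:02", p1 = NA, p2 = 1)
    expect_warning(a <- accLocus(imp, typed, "A"), "treated as 0")
    expect_equal(as.numeric(a), 0.5)
})
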