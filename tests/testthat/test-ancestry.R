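test_that("LD pruning removes the later of a correlated pair", {
    set.seed(1)
    g <- rbinom(200, 2, 0.4)
    calls <- cbind(g, g, rbinom(200, 2, 0.4))
    x <- toyMatrix(t(calls))
    kept <- ldPrune(x, window = 3, step = 1)
    expect_false("rs2" %in% kept)
    expect_true(all(c("rs1", "rs3") %in% kept))
    expect_error(ldPrune(x, window = 5, step = 10), "window < step")
    expect_error(ldPrune(x, window = 1, step = 1), "window")
})

test_that("independent variants survive pruning and the pass is idempotent", {
    set.seed(2)
    # variants in rows: draw each row with its own frequency
    calls <- t(vapply(runif(120, 0.2, 0.8),
                      function(f) rbinom(500, 2, f), integer(500)))
    x <- toyMatrix(calls)
    kept <- ldPrune(x)
    expect_gte(length(kept), 0.95 * 120)
    x2 <- x[match(kept, variantInfo(x)$id), ]
    expect_identical(ldPrune(x2), kept)
})

test_that("monomorphic variants are retained, not correlated", {
    calls <- rbind(rep(1L, 10), rep(1L, 10), rbinom(10, 2, 0.5))
    x <- toyMatrix(calls)
    kept <- ldPrune(x, window = 3, step = 1)
    expect_true(all(c("rs1", "rs2") %in% kept))
})

test_that("supervised frequency fit applies the pseudocount and clamp", {
    x <- toyMatrix(matrix(c(2L, 2L, 2L, NA, 0L, NA, 1L, NA), 2, 4),
                   samples = c("a", "b", "c", "d"))
    m <- fitReference(x, c("P1", "P1", "P2", "P2"))
    expect_equal(unname(m@freq["P1", 1]), 0.9)  # (4 + 0.5) / (4 + 1)
    expect_equal(unname(m@freq["P2", 2]), 0.5)  # all-missing: pseudocount
    expect_error(fitReference(x, c("P1", NA, "P2", "P2")), "b")
    big <- toyMatrix(matrix(rep(c(2L, 0L), each = 8), 2, 8,
                            byrow = TRUE))
    m2 <- fitReference(big, rep(c("P1", "P2"), 4))
    expect_true(all(m2@freq > 0 & m2@freq < 1))
})

test_that("projection recovers pure-population samples", {
    spec <- cohortSpec(n_variants = 2000, n_populations = 3, fst = 0.2,
                       missing_rate = 0, seed = 31)
    ref <- simulateReferencePanel(spec, samples_per_pop = 80)
    model <- fitReference(ref$genotypes, ref$population)
    Q <- diag(3)[rep(1, 10), ]           # ten pure POP1 samples
    adm <- simulateAdmixedSamples(model, alpha = rep(1, 3), n = 10,
                                  seed = 32, Q = Q)
    proj <- projectAncestry(adm$genotypes, model)
    expect_true(all(proj$Q[, "POP1"] >= 0.95))
    expect_true(all(abs(rowSums(proj$Q) - 1) < 1e-6))
    # interior (admixed) samples converge within the iteration cap
    mid <- simulateAdmixedSamples(model, alpha = rep(5, 3), n = 5,
                                  seed = 33)
    pm <- projectAncestry(mid$genotypes, model)
    expect_true(all(pm$details$converged))
})

test_that("flat likelihoods keep the uniform start and are flagged", {
    f <- matrix(0.4, 2, 50, dimnames = list(c("P1", "P2"), NULL))
    model <- new("AncestryModel", freq = f, populations = c("P1", "P2"),
                 variantKeys = toyVariants(50))
    x <- toyMatrix(matrix(rbinom(50 * 4, 2, 0.4), 50, 4))
    proj <- projectAncestry(x, model)
    expect_true(all(proj$details$non_identifiable))
    expect_true(all(abs(proj$Q - 0.5) < 1e-9))
})

test_that("samples without usable genotypes are flagged undefined", {
    f <- matrix(c(0.2, 0.8), 2, 10, dimnames = list(c("P1", "P2"), NULL))
    model <- new("AncestryModel", freq = f, populations = c("P1", "P2"),
                 variantKeys = toyVariants(10))
    calls <- matrix(NA_integer_, 10, 2)
    calls[, 2] <- rbinom(10, 2, 0.2)
    proj <- projectAncestry(toyMatrix(calls), model)
    expect_true(proj$details$undefined[1])
    expect_false(proj$details$undefined[2])
    expect_true(all(is.na(proj$Q[1, ])))
})

test_that("EM agrees with a 1-D grid-search oracle and never decreases", {
    set.seed(33)
    K <- 2; M <- 800
    f <- rbind(runif(M, 0.1, 0.9), runif(M, 0.1, 0.9))
    rownames(f) <- c("P1", "P2")
    qTrue <- 0.3
    g <- rbinom(M, 2, qTrue * f[1, ] + (1 - qTrue) * f[2, ])
    loglik <- function(q1) {
        p <- q1 * f[1, ] + (1 - q1) * f[2, ]
        sum(g * log(p) + (2 - g) * log(1 - p))
    }
    grid <- seq(0, 1, by = 1e-4)
    qOracle <- grid[which.max(vapply(grid, loglik, numeric(1)))]
    model <- new("AncestryModel", freq = f, populations = c("P1", "P2"),
                 variantKeys = toyVariants(M))
    proj <- projectAncestry(toyMatrix(matrix(g, M, 1)), model,
                            tol = 1e-9)
    expect_lt(abs(proj$Q[1, "P1"] - qOracle), 1e-3)
    # monotone likelihood along the EM path
    lls <- vapply(1:25, function(it)
        projectAncestry(toyMatrix(matrix(g, M, 1)), model, tol = 0,
                        max_iter = it)$details$loglik, numeric(1))
    expect_true(all(diff(lls) > -1e-8))
})

test_that("PCA of Q has deterministic signs and simplex rank K - 1", {
    Q <- matrix(1 / 3, 6, 3)
    pc <- pcaOfQ(Q)
    expect_true(all(abs(pc$coordinates) < 1e-12))

    Q2 <- rbind(matrix(rep(c(1, 0), each = 5), 5),
                matrix(rep(c(0, 1), each = 5), 5))
    pc2 <- pcaOfQ(Q2, n_components = 2)
    expect_equal(pc2$explained_variance[1], 1)
    expect_equal(length(unique(round(pc2$coordinates[, 1], 6))), 2)

    set.seed(34)
    Q5 <- cohortval:::.rdirichlet(50, rep(1, 5))
    pc5 <- pcaOfQ(Q5, n_components = 5)
    expect_lt(ncol(pc5$coordinates), 6)
    expect_equal(sum(pc5$explained_variance[1:4]), 1, tolerance = 1e-9)
    # sign convention: largest-magnitude loading positive
    for (j in seq_len(ncol(pc5$loadings)))
        expect_gt(pc5$loadings[which.max(abs(pc5$loadings[, j])), j], 0)
})

test_that("majority ancestry handles ties and undefined rows", {
    Q <- rbind(c(0.6, 0.4), c(0.5, 0.5), c(NA, NA))
    colnames(Q) <- c("AFR", "EUR")
    rownames(Q) <- c("s1", "s2", "s3")
    mj <- assignMajorityAncestry(Q)
    expect_equal(mj$label, c("AFR", "AFR", "unassigned"))
    expect_equal(mj$tie, c(FALSE, TRUE, FALSE))
})
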