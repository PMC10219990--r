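# Model-based ancestry: LD pruning, supervised per-population frequency
# estimation from a labeled reference, maximum-likelihood projection of
# new samples onto the K-population simplex by EM, and PCA of the
# resulting proportion vectors.

.FREQ_EPS <- 1e-4   # clamp keeping the projection likelihood finite

#' Greedy sliding-window LD pruning
#'
#' Within each window of \code{window} SNPs (advancing by \code{step}),
#' any pair of retained variants with squared genotype correlation above
#' \code{r2_max} loses its later member (by position; ties by lower
#' minor-allele frequency).  Removal is greedy left-to-right, per
#' chromosome.  Monomorphic variants have undefined correlation and are
#' retained without entering the r-squared computation.
#'
#' @param x a \linkS4class{GenotypeMatrix}, variants ordered by
#'   chromosome and position.
#' @param window window size in SNPs (>= 2, >= step).
#' @param step window advance in SNPs.
#' @param r2_max maximum squared correlation tolerated.
#' @return character vector of retained variant ids.
#' @export
ldPrune <- function(x, window = 50, step = 10, r2_max = 0.1) {
    if (window < step) stop("window < step")
    if (window < 2) stop("window must be >= 2")
    vi <- variantInfo(x)
    calls <- genotypeCalls(x)
    keep <- rep(TRUE, nrow(vi))
    for (chr in unique(vi$chrom)) {
        idx <- which(vi$chrom == chr)
        if (is.unsorted(vi$pos[idx]))
            stop("variants must be ordered by position within chromosome ",
                 chr)
        start <- 1
        while (start <= length(idx)) {
            win <- idx[start:min(start + window - 1, length(idx))]
            win <- win[keep[win]]
            if (length(win) >= 2) {
                g <- calls[win, , drop = FALSE]
                sds <- apply(g, 1, sd, na.rm = TRUE)
                poly <- which(!is.na(sds) & sds > 0)
                if (length(poly) >= 2) {
                    cc <- suppressWarnings(
                        cor(t(g[poly, , drop = FALSE]),
                            use = "pairwise.complete.obs"))
                    r2 <- cc^2
                    frq <- rowMeans(g[poly, , drop = FALSE],
                                    na.rm = TRUE) / 2
                    maf <- pmin(frq, 1 - frq)
                    for (i in seq_along(poly)) {
                        vi_i <- win[poly[i]]
                        if (!keep[vi_i]) next
                        for (j in seq_along(poly)) {
                            if (j <= i) next
                            vj <- win[poly[j]]
                            if (!keep[vj]) next
                            if (!is.na(r2[i, j]) && r2[i, j] > r2_max) {
                                # drop the later variant; position ties
                                # drop the lower-MAF one
                                drop_j <- vi$pos[vj] > vi$pos[vi_i] ||
                                    (vi$pos[vj] == vi$pos[vi_i] &&
                                     maf[j] <= maf[i])
                                keep[if (drop_j) vj else vi_i] <- FALSE
                                if (!drop_j) break
                            }
                        }
                        if (!keep[vi_i]) next
                    }
                }
            }
            start <- start + step
        }
    }
    vi$id[keep]
}

#' Fit a supervised ancestry model from a labeled reference panel
#'
#' Per population k and variant m the counted-allele frequency is the
#' pseudocount-smoothed sample frequency
#' \code{(count + pc) / (2 n_called + 2 pc)}, clamped to (0, 1).
#'
#' @param x reference \linkS4class{GenotypeMatrix}.
#' @param population_labels per-sample population label (no NA).
#' @param pseudocount additive smoothing, default 0.5.
#' @return an \linkS4class{AncestryModel}.
#' @export
fitReference <- function(x, population_labels, pseudocount = 0.5) {
    if (length(population_labels) != nSamples(x))
        stop("labels must match sample count")
    if (anyNA(population_labels)) {
        bad <- sampleIds(x)[is.na(population_labels)]
        stop("missing population label for sample(s): ",
             paste(bad, collapse = ", "))
    }
    pops <- sort(unique(population_labels))
    calls <- genotypeCalls(x)
    f <- matrix(NA_real_, length(pops), nrow(x),
                dimnames = list(pops, NULL))
    for (k in seq_along(pops)) {
        sub <- calls[, population_labels == pops[k], drop = FALSE]
        cnt <- rowSums(sub, na.rm = TRUE)
        ncall <- rowSums(!is.na(sub))
        f[k, ] <- (cnt + pseudocount) / (2 * ncall + 2 * pseudocount)
    }
    f <- pmin(pmax(f, .FREQ_EPS), 1 - .FREQ_EPS)
    new("AncestryModel", freq = f, populations = pops,
        variantKeys = variantInfo(x))
}

# one sample's EM projection; returns q, loglik, iterations, converged
.projectOne <- function(g, f, tol, max_iter) {
    ok <- !is.na(g)
    g <- g[ok]; f <- f[, ok, drop = FALSE]
    K <- nrow(f); M <- length(g)
    if (M == 0)
        return(list(q = rep(NA_real_, K), loglik = NA_real_, n_iter = 0L,
                    converged = FALSE, undefined = TRUE, flat = FALSE))
    flat <- all(apply(f, 2, function(col) diff(range(col))) < 1e-12)
    q <- rep(1 / K, K)
    ll <- -Inf
    iter <- 0L; converged <- FALSE
    while (iter < max_iter) {
        iter <- iter + 1L
        p <- as.vector(crossprod(f, q))        # M mixture frequencies
        # E-step responsibilities folded into the simplex update
        qNew <- as.vector((f / rep(p, each = K)) %*% g +
                          ((1 - f) / rep(1 - p, each = K)) %*% (2 - g)) *
                q / (2 * M)
        qNew <- qNew / sum(qNew)
        delta <- max(abs(qNew - q))
        q <- qNew
        if (delta < tol) { converged <- TRUE; break }
    }
    p <- as.vector(crossprod(f, q))
    ll <- sum(g * log(p) + (2 - g) * log(1 - p))
    list(q = q, loglik = ll, n_iter = iter, converged = converged,
         undefined = FALSE, flat = flat)
}

#' Project samples onto an ancestry model
#'
#' Maximizes, per sample, the binomial admixture log-likelihood
#' \deqn{\ell(q) = \sum_m g_m \log p_m + (2 - g_m) \log(1 - p_m),\quad
#'   p_m = \sum_k q_k f_{km},}
#' by expectation-maximization on the simplex from a uniform start.
#' Missing genotypes are skipped.  Samples with no non-missing
#' overlapping variants are flagged undefined; samples whose likelihood
#' is flat (all populations identical at every used variant) keep the
#' uniform start and are flagged non-identifiable.
#'
#' @param x \linkS4class{GenotypeMatrix} harmonized to the model panel
#'   (same variants, counted alleles aligned).
#' @param model an \linkS4class{AncestryModel}.
#' @param tol convergence tolerance on max |delta q|.
#' @param max_iter iteration cap.
#' @return list(Q = n x K matrix, details = data.frame(sample_id,
#'   loglik, n_iter, converged, undefined, non_identifiable)).
#' @export
projectAncestry <- function(x, model, tol = 1e-6, max_iter = 1000) {
    if (nrow(x) != ncol(model@freq))
        stop("matrix must be restricted to the model's variant panel")
    calls <- genotypeCalls(x)
    n <- ncol(calls); K <- nrow(model@freq)
    Q <- matrix(NA_real_, n, K,
                dimnames = list(sampleIds(x), model@populations))
    det <- vector("list", n)
    for (j in seq_len(n)) {
        r <- .projectOne(calls[, j], model@freq, tol, max_iter)
        Q[j, ] <- r$q
        det[[j]] <- data.frame(sample_id = sampleIds(x)[j],
                               loglik = r$loglik, n_iter = r$n_iter,
                               converged = r$converged,
                               undefined = r$undefined,
                               non_identifiable = r$flat)
    }
    list(Q = Q, details = do.call(rbind, det))
}

#' PCA of ancestry proportion vectors
#'
#' Centered principal components of the n x K proportion matrix with a
#' deterministic sign convention: each component's largest-magnitude
#' loading is made positive.  The simplex constraint caps the rank at
#' K - 1.
#'
#' @param Q n x K proportion matrix.
#' @param n_components number of components returned.
#' @return list(coordinates, loadings, explained_variance proportion per
#'   returned component).
#' @export
pcaOfQ <- function(Q, n_components = 2) {
    Q <- as.matrix(Q)
    keep <- stats::complete.cases(Q)
    pc <- prcomp(Q[keep, , drop = FALSE], center = TRUE, scale. = FALSE)
    k <- min(n_components, ncol(pc$x))
    rot <- pc$rotation[, seq_len(k), drop = FALSE]
    scores <- pc$x[, seq_len(k), drop = FALSE]
    for (j in seq_len(k)) {
        i <- which.max(abs(rot[, j]))
        if (rot[i, j] < 0) {
            rot[, j] <- -rot[, j]
            scores[, j] <- -scores[, j]
        }
    }
    coords <- matrix(NA_real_, nrow(Q), k,
                     dimnames = list(rownames(Q), colnames(scores)))
    coords[keep, ] <- scores
    totVar <- sum(pc$sdev^2)
    ev <- if (totVar > 0) pc$sdev[seq_len(k)]^2 / totVar else
        rep(0, k)
    list(coordinates = coords, loadings = rot, explained_variance = ev)
}

#' Majority-ancestry assignment
#'
#' Argmax over each sample's proportion vector; exact ties take the
#' first population in column order and are flagged; undefined rows get
#' label "unassigned".
#'
#' @param Q n x K proportion matrix with population column names.
#' @return data.frame(sample_id, label, tie).
#' @export
assignMajorityAncestry <- function(Q) {
    Q <- as.matrix(Q)
    ids <- rownames(Q)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(Q)))
    lab <- character(nrow(Q)); tie <- logical(nrow(Q))
    for (i in seq_len(nrow(Q))) {
        if (anyNA(Q[i, ])) { lab[i] <- "unassigned"; next }
        mx <- max(Q[i, ])
        hits <- which(Q[i, ] == mx)
        lab[i] <- colnames(Q)[hits[1]]
        tie[i] <- length(hits) > 1
    }
    data.frame(sample_id = ids, label = lab, tie = tie)
}
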