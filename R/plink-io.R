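# PLINK text (.ped/.map) and binary (.bed/.bim/.fam, v1.0 SNP-major)
# readers and writers.  Genotypes count the A1 allele of the .bim file
# (the matrix "counted" allele); missing calls round-trip as NA.

.SEX_TO_PLINK <- c(male = 1L, female = 2L, unknown = 0L)
.PLINK_TO_SEX <- c("1" = "male", "2" = "female", "0" = "unknown")

.famFrame <- function(x) {
    si <- sampleInfo(x)
    sex <- if ("reported_sex" %in% names(si))
        unname(.SEX_TO_PLINK[si$reported_sex]) else 0L
    sex[is.na(sex)] <- 0L
    data.frame(fid = si$sample_id, iid = si$sample_id, pat = 0L, mat = 0L,
               sex = sex, pheno = -9L)
}

.bimFrame <- function(x) {
    vi <- variantInfo(x)
    # A1 is the counted allele, A2 the other
    a2 <- ifelse(vi$counted == vi$alt, vi$ref, vi$alt)
    data.frame(chrom = ifelse(vi$chrom == "X", "23", vi$chrom), id = vi$id,
               cm = 0, pos = vi$pos, a1 = vi$counted, a2 = a2)
}

.chromFromPlink <- function(v) ifelse(v == "23", "X", v)

#' Write a GenotypeMatrix as PLINK files
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param prefix path prefix; files \code{prefix.bed/.bim/.fam} (binary)
#'   or \code{prefix.ped/.map} (text) are written.
#' @param format \code{"bed"} (binary, SNP-major v1.0) or \code{"ped"}.
#' @return \code{prefix}, invisibly.
#' @export
writePlink <- function(x, prefix, format = c("bed", "ped")) {
    format <- match.arg(format)
    bim <- .bimFrame(x)
    fam <- .famFrame(x)
    calls <- genotypeCalls(x)
    if (format == "ped") {
        write.table(bim[c("chrom", "id", "cm", "pos")],
                    paste0(prefix, ".map"), quote = FALSE, sep = "\t",
                    row.names = FALSE, col.names = FALSE)
        n <- ncol(calls); M <- nrow(calls)
        lines <- character(n)
        for (j in seq_len(n)) {
            g <- calls[, j]
            a <- ifelse(is.na(g), "0",
                        ifelse(g >= 1, bim$a1, bim$a2))
            b <- ifelse(is.na(g), "0",
                        ifelse(g == 2, bim$a1, bim$a2))
            lines[j] <- paste(c(fam$fid[j], fam$iid[j], 0, 0, fam$sex[j],
                                -9, as.vector(rbind(a, b))), collapse = " ")
        }
        writeLines(lines, paste0(prefix, ".ped"))
    } else {
        write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                    row.names = FALSE, col.names = FALSE)
        write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
                    row.names = FALSE, col.names = FALSE)
        n <- ncol(calls)
        bytesPerSnp <- ceiling(n / 4)
        # 2-bit codes, counted = A1: 2 copies -> 00, het -> 10,
        # 0 copies -> 11, missing -> 01
        code <- matrix(3L, nrow(calls), n)   # default 0 copies
        code[!is.na(calls) & calls == 2L] <- 0L
        code[!is.na(calls) & calls == 1L] <- 2L
        code[is.na(calls)] <- 1L
        con <- file(paste0(prefix, ".bed"), "wb")
        on.exit(close(con))
        writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
        pad <- bytesPerSnp * 4 - n
        for (m in seq_len(nrow(calls))) {
            cc <- c(code[m, ], integer(pad))
            dim(cc) <- c(4, bytesPerSnp)
            byte <- cc[1, ] + cc[2, ] * 4L + cc[3, ] * 16L + cc[4, ] * 64L
            writeBin(as.raw(byte), con)
        }
    }
    invisible(prefix)
}

#' Read PLINK files into a GenotypeMatrix
#'
#' Accepts either a \code{.bed/.bim/.fam} triplet or a \code{.ped/.map}
#' pair, inferred from the files present at \code{prefix}.  Inconsistent
#' dimensions, truncated binary payloads and duplicated variant ids are
#' errors, never silent truncation.
#'
#' @param prefix path prefix without extension.
#' @return a \linkS4class{GenotypeMatrix}; counted allele is PLINK A1.
#' @export
readPlink <- function(prefix) {
    if (file.exists(paste0(prefix, ".bed")))
        .readBed(prefix)
    else if (file.exists(paste0(prefix, ".ped")))
        .readPed(prefix)
    else stop("no PLINK fileset found at prefix: ", prefix)
}

.readBimLike <- function(path, ncols) {
    tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character")
    if (ncol(tab) != ncols)
        stop("malformed file (expected ", ncols, " columns): ", path)
    tab
}

.readBed <- function(prefix) {
    bim <- .readBimLike(paste0(prefix, ".bim"), 6)
    names(bim) <- c("chrom", "id", "cm", "pos", "a1", "a2")
    if (anyDuplicated(bim$id))
        stop("duplicate variant id(s) in ", prefix, ".bim: ",
             paste(unique(bim$id[duplicated(bim$id)]), collapse = ", "))
    fam <- .readBimLike(paste0(prefix, ".fam"), 6)
    names(fam) <- c("fid", "iid", "pat", "mat", "sex", "pheno")
    M <- nrow(bim); n <- nrow(fam)
    bytesPerSnp <- ceiling(n / 4)
    raw <- readBin(paste0(prefix, ".bed"), "raw",
                   n = 3 + M * bytesPerSnp + 1)
    if (length(raw) < 3 || raw[1] != 0x6c || raw[2] != 0x1b)
        stop("not a PLINK .bed file: ", prefix, ".bed")
    if (raw[3] != 0x01)
        stop("only SNP-major v1.0 .bed supported: ", prefix, ".bed")
    payload <- raw[-(1:3)]
    if (length(payload) != M * bytesPerSnp)
        stop(".bed payload size (", length(payload),
             " bytes) inconsistent with .bim/.fam dimensions (expected ",
             M * bytesPerSnp, "): ", prefix, ".bed")
    ints <- as.integer(payload)
    two <- ints %/% 4L; codes1 <- ints %% 4L
    codes2 <- two %% 4L; two <- two %/% 4L
    codes3 <- two %% 4L; codes4 <- two %/% 4L
    codeMat <- matrix(rbind(codes1, codes2, codes3, codes4),
                      nrow = 4 * bytesPerSnp)
    codeMat <- codeMat[seq_len(n), , drop = FALSE]   # samples x variants
    calls <- matrix(NA_integer_, n, M)
    calls[codeMat == 0L] <- 2L
    calls[codeMat == 2L] <- 1L
    calls[codeMat == 3L] <- 0L
    variants <- data.frame(chrom = .chromFromPlink(bim$chrom),
                           pos = as.integer(bim$pos),
                           ref = bim$a2, alt = bim$a1, id = bim$id,
                           counted = bim$a1)
    samples <- data.frame(sample_id = fam$iid,
                          reported_sex = unname(.PLINK_TO_SEX[fam$sex]))
    samples$reported_sex[is.na(samples$reported_sex)] <- "unknown"
    GenotypeMatrix(t(calls), variants, samples)
}

.readPed <- function(prefix) {
    map <- .readBimLike(paste0(prefix, ".map"), 4)
    names(map) <- c("chrom", "id", "cm", "pos")
    if (anyDuplicated(map$id))
        stop("duplicate variant id(s) in ", prefix, ".map: ",
             paste(unique(map$id[duplicated(map$id)]), collapse = ", "))
    lines <- readLines(paste0(prefix, ".ped"))
    M <- nrow(map)
    n <- length(lines)
    calls <- matrix(NA_integer_, M, n)
    ids <- character(n); sex <- character(n)
    a1 <- rep(NA_character_, M); a2 <- rep(NA_character_, M)
    alleleMat <- vector("list", n)
    for (j in seq_len(n)) {
        f <- strsplit(trimws(lines[j]), "[ \t]+")[[1]]
        if (length(f) != 6 + 2 * M)
            stop(".ped line ", j, " has ", length(f),
                 " fields; expected ", 6 + 2 * M, ": ", prefix, ".ped")
        ids[j] <- f[2]
        sex[j] <- .PLINK_TO_SEX[f[5]]
        alleleMat[[j]] <- matrix(f[-(1:6)], ncol = 2, byrow = TRUE)
    }
    sex[is.na(sex)] <- "unknown"
    # Allele coding per variant.  .ped stores unordered pairs; the writer
    # puts the counted (A1) allele first in heterozygous calls, so A1 is
    # recovered as the first allele of the first het sample, falling back
    # to the first non-missing allele seen when a variant has no hets.
    for (m in seq_len(M)) {
        pairs <- t(vapply(alleleMat, function(am) am[m, ], character(2)))
        seen <- setdiff(unique(as.vector(t(pairs))), "0")
        if (length(seen) > 2)
            stop("variant ", map$id[m], " has >2 alleles in ", prefix,
                 ".ped")
        het <- which(pairs[, 1] != pairs[, 2] & pairs[, 1] != "0" &
                     pairs[, 2] != "0")
        a1[m] <- if (length(het)) pairs[het[1], 1]
                 else if (length(seen)) seen[1] else "A"
        a2[m] <- if (length(setdiff(seen, a1[m])))
            setdiff(seen, a1[m])[1] else setdiff(c("A", "C"), a1[m])[1]
    }
    for (j in seq_len(n)) {
        am <- alleleMat[[j]]
        missing <- am[, 1] == "0" | am[, 2] == "0"
        g <- (am[, 1] == a1) + (am[, 2] == a1)
        g[missing] <- NA_integer_
        calls[, j] <- as.integer(g)
    }
    variants <- data.frame(chrom = .chromFromPlink(map$chrom),
                           pos = as.integer(map$pos),
                           ref = a2, alt = a1, id = map$id, counted = a1)
    GenotypeMatrix(calls, variants,
                   data.frame(sample_id = ids, reported_sex = sex))
}
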