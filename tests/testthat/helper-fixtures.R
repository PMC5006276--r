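# Fixtures built in code at test time.

# 4-sample / 2-SNP PLINK text fixture (phenotypes 1,1,2,2; one missing call)
write_ped_fixture <- function(dir) {
  ped <- c("f1 i1 0 0 1 1  A A  G T",
           "f2 i2 0 0 1 1  A C  T T",
           "f3 i3 0 0 2 2  C C  0 0",
           "f4 i4 0 0 1 2  A C  G T")
  map <- c("1 rs1 0 1000", "1 rs2 0 2000")
  writeLines(ped, file.path(dir, "fix.ped"))
  writeLines(map, file.path(dir, "fix.map"))
  file.path(dir, "fix")
}

# independent PLINK .bed writer (bit-packs by hand; deliberately not using
# any package code so it can serve as a cross-format oracle)
write_bed_independent <- function(G, pheno, meta, prefix) {
  n <- nrow(G); m <- ncol(G)
  fam <- data.frame(paste0("f", 1:n), paste0("i", 1:n), 0, 0, 0, pheno + 1)
  write.table(fam, paste0(prefix, ".fam"), col.names = FALSE,
              row.names = FALSE, quote = FALSE)
  bim <- data.frame(meta$chrom, meta$snp, 0, meta$pos, meta$allele1,
                    meta$allele2)
  write.table(bim, paste0(prefix, ".bim"), col.names = FALSE,
              row.names = FALSE, quote = FALSE)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  code <- function(g) if (is.na(g)) 1L else c(3L, 2L, 0L)[g + 1L]
  for (j in seq_len(m)) {
    bytes <- integer(ceiling(n / 4))
    for (i in seq_len(n)) {
      b <- (i - 1) %/% 4 + 1; sh <- (i - 1) %% 4
      bytes[b] <- bytes[b] + code(G[i, j]) * 4L^sh
    }
    writeBin(as.raw(bytes), con)
  }
  prefix
}

# cohort with prescribed per-SNP genotype count tables
# counts: list per SNP of c(n0_of_0, n0_of_1, n0_of_2, n1_of_0, n1_of_1, n1_of_2)
cohort_from_counts <- function(counts) {
  m <- length(counts)
  n0 <- sum(counts[[1]][1:3]); n1 <- sum(counts[[1]][4:6])
  G <- matrix(0L, n0 + n1, m)
  for (j in seq_len(m)) {
    cc <- counts[[j]]
    G[, j] <- c(rep(0:2, cc[1:3]), rep(0:2, cc[4:6]))
  }
  dda_cohort(G, c(rep(0L, n0), rep(1L, n1)))
}

# binary encoded matrix with exact carrier counts per group
enc_from_carriers <- function(k0, n0, k1, n1) {
  V <- cbind(c(rep(1, k0), rep(0, n0 - k0), rep(1, k1), rep(0, n1 - k1)))
  list(V = V, labels = c(rep(0L, n0), rep(1L, n1)))
}

# the saturated 2-SNP state-count fixture (n00, n10, n01, n11)
enc_2snp_counts <- function(n00 = 40, n10 = 20, n01 = 20, n11 = 20) {
  rbind(matrix(rep(c(0, 0), n00), ncol = 2, byrow = TRUE),
        matrix(rep(c(1, 0), n10), ncol = 2, byrow = TRUE),
        matrix(rep(c(0, 1), n01), ncol = 2, byrow = TRUE),
        matrix(rep(c(1, 1), n11), ncol = 2, byrow = TRUE))
}
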