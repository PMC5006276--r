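test_that("ped parsing maps phenotypes, alleles and missing calls", {
  td <- withr::local_tempdir()
  prefix <- write_ped_fixture(td)
  d <- load_genotypes(prefix, format = "ped")
  expect_s3_class(d, "dda_cohort")
  expect_equal(sum(d$phenotypes == 0), 2)
  expect_equal(sum(d$phenotypes == 1), 2)
  expect_equal(ncol(d$genotypes), 2)
  # rs1 alleles A/C balanced: minor-allele counts per sample
  expect_equal(unname(d$genotypes[, 1]), c(2L, 1L, 0L, 1L))
  # the "0 0" call is missing
  expect_true(is.na(d$genotypes[3, 2]))
  # malformed line reports its line number
  bad <- readLines(paste0(prefix, ".ped"))
  bad[2] <- "f2 i2 0 0 1 1 A C"
  writeLines(bad, file.path(td, "bad.ped"))
  file.copy(paste0(prefix, ".map"), file.path(td, "bad.map"))
  expect_error(load_genotypes(file.path(td, "bad"), format = "ped"),
               "line 2")
})

test_that("samples with unknown phenotype codes are dropped, empty groups error", {
  td <- withr::local_tempdir()
  ped <- c("f1 i1 0 0 1 1  A A",
           "f2 i2 0 0 1 2  A C",
           "f3 i3 0 0 1 -9  C C")
  writeLines(ped, file.path(td, "p.ped"))
  writeLines("1 rs1 0 500", file.path(td, "p.map"))
  expect_message(d <- load_genotypes(file.path(td, "p"), format = "ped"),
                 "dropped")
  expect_equal(length(d$phenotypes), 2)
  ped0 <- ped[c(1, 1)]  # controls only
  writeLines(ped0, file.path(td, "q.ped"))
  writeLines("1 rs1 0 500", file.path(td, "q.map"))
  expect_error(load_genotypes(file.path(td, "q"), format = "ped"),
               "degenerate")
})

test_that("binary .bed written by an independent writer matches its .ped twin", {
  td <- withr::local_tempdir()
  set.seed(42)
  n <- 37; m <- 5
  # keep the counted allele clearly minor so the text reader's
  # frequency-based allele identification matches the .bim assignment
  G <- matrix(sample(c(0:2, NA), n * m, replace = TRUE,
                     prob = c(.60, .25, .08, .07)), n, m)
  meta <- data.frame(snp = paste0("rs", 1:m), chrom = "1",
                     pos = (1:m) * 1000L, allele1 = "A", allele2 = "B",
                     stringsAsFactors = FALSE)
  pheno <- rep(c(0L, 1L), length.out = n)
  write_bed_independent(G, pheno, meta, file.path(td, "tw"))
  db <- load_genotypes(file.path(td, "tw"), format = "bed")
  expect_identical(unname(db$genotypes), unname(G))
  expect_identical(db$phenotypes, pheno)
  # ped twin via the package writer round-trips to the same table
  d0 <- dda_cohort(G, pheno, meta)
  write_plink_ped(d0, file.path(td, "tp"))
  dp <- load_genotypes(file.path(td, "tp"), format = "ped")
  expect_identical(unname(dp$genotypes), unname(G))
  # bad magic is rejected
  writeBin(as.raw(c(0x00, 0x1b, 0x01)), file.path(td, "tw.bed"))
  expect_error(load_genotypes(file.path(td, "tw"), format = "bed"), "magic")
})

test_that("exact HWE test matches brute-force conditional enumeration", {
  # independent oracle: P(het = h | allele count) by direct multinomial ratio
  hwe_brute <- function(ha, h, hb) {
    n <- ha + h + hb; na <- 2 * ha + h
    hs <- seq(na %% 2, min(na, 2 * n - na), by = 2)
    pr <- sapply(hs, function(x) {
      a <- (na - x) / 2; b <- n - a - x
      exp(lfactorial(n) - lfactorial(a) - lfactorial(x) - lfactorial(b) +
            x * log(2) + lfactorial(na) + lfactorial(2 * n - na) -
            lfactorial(2 * n))
    })
    pr <- pr / sum(pr)
    sum(pr[pr <= pr[match(h, hs)] + 1e-12])
  }
  for (tab in list(c(5, 20, 25), c(2, 5, 43), c(50, 0, 50), c(0, 10, 40))) {
    expect_equal(hwe_exact_test(tab[1], tab[2], tab[3]),
                 hwe_brute(tab[1], tab[2], tab[3]), tolerance = 1e-10)
  }
  # complete heterozygote deficit is catastrophically out of equilibrium
  expect_lt(hwe_exact_test(50, 0, 50), 1e-6)
})

test_that("qc_filter applies MAF, HWE and missingness criteria", {
  # three SNPs with pooled MAF 0.005, 0.05, 0.30 (n = 200, no missing)
  maf_counts <- function(maf, n = 200) {
    k <- round(2 * n * maf)   # minor allele copies, as heterozygotes
    c(n / 2 - ceiling(k / 2), ceiling(k / 2), 0,
      n / 2 - floor(k / 2), floor(k / 2), 0)
  }
  d <- cohort_from_counts(list(maf_counts(0.005), maf_counts(0.05),
                               maf_counts(0.30)))
  q <- qc_filter(d, maf_min = 0.01, hwe_p_min = 0, miss_max = 1)
  expect_equal(ncol(q$genotypes), 2)
  expect_false("snp1" %in% q$snp_meta$snp)
  # HWE failure in controls (AA=50, Aa=0, aa=50) removes the SNP
  d2 <- cohort_from_counts(list(c(50, 0, 50, 25, 50, 25),
                                c(25, 50, 25, 25, 50, 25)))
  q2 <- qc_filter(d2, maf_min = 0, hwe_p_min = 1e-6, miss_max = 1)
  expect_equal(q2$snp_meta$snp, "snp2")
  expect_equal(attr(q2, "qc_report")$removed[2], 1)
  # 10% missingness vs miss_max = 0.05 removes the SNP
  G <- matrix(rep(c(0L, 1L), 50), 100, 2)
  G[1:10, 1] <- NA
  d3 <- dda_cohort(G, rep(c(0L, 1L), 50))
  q3 <- qc_filter(d3, maf_min = 0, hwe_p_min = 0, miss_max = 0.05)
  expect_equal(q3$snp_meta$snp, "snp2")
})

test_that("qc_filter is idempotent and leaves pooled MAF at or below 0.5", {
  set.seed(7)
  n <- 120
  G <- cbind(rbinom(n, 2, 0.8), rbinom(n, 2, 0.3), rbinom(n, 2, 0.5))
  d <- dda_cohort(G, rep(c(0L, 1L), n / 2))
  q1 <- qc_filter(d)
  freq <- colMeans(q1$genotypes, na.rm = TRUE) / 2
  expect_true(all(freq <= 0.5))
  # the high-frequency column was flipped
  expect_true(attr(q1, "minor_allele_flipped")[1])
  expect_equal(q1$snp_meta$allele1[1], "B")
  q2 <- qc_filter(q1)
  expect_identical(q1$genotypes, q2$genotypes)
  expect_identical(q1$snp_meta, q2$snp_meta)
  # over-strict thresholds empty the panel
  expect_error(qc_filter(d, maf_min = 0.999), "empty panel")
})

test_that("encoding maps counts per model and imputes the modal genotype", {
  G <- matrix(c(0L, 1L, 2L, NA, 1L, 1L), ncol = 1)
  d <- dda_cohort(rbind(G, G), rep(c(0L, 1L), each = 6))
  dom <- encode_genotypes(d, "dominant")
  rec <- encode_genotypes(d, "recessive")
  gen <- encode_genotypes(d, "genotypic")
  expect_equal(dom$values[1:3, 1], c(0, 1, 1))
  expect_equal(rec$values[1:3, 1], c(0, 0, 1))
  expect_equal(gen$values[1:3, 1], c(0, 1, 2))
  # NA imputed to the modal genotype (1) before encoding
  expect_equal(unname(gen$values[4, 1]), 1)
  expect_false(anyNA(dom$values))
  expect_error(encode_genotypes(d, "additive"))
})

test_that("empirical moments match brute-force double loops", {
  V <- cbind(c(0, 1, 1, 0))
  mm <- empirical_moments(V, model = "dominant")
  expect_equal(unname(mm$f_single), 0.5)
  V2 <- cbind(a = c(0, 1, 1, 0), b = c(0, 1, 1, 0))
  mm2 <- empirical_moments(V2, model = "dominant")
  expect_equal(mm2$f_pair[1, 2], unname(mm2$f_single[1]))
  expect_equal(unname(diag(mm2$f_pair)), unname(mm2$f_single))
  set.seed(3)
  V3 <- matrix(rbinom(500, 1, 0.4), 100, 5)
  labels <- rep(c(0L, 1L), 50)
  mm3 <- empirical_moments(V3, labels, group = "case", model = "dominant")
  rows <- which(labels == 1)
  brute <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    s <- 0
    for (k in rows) s <- s + V3[k, i] * V3[k, j]
    brute[i, j] <- s / length(rows)
  }
  expect_equal(mm3$f_pair, brute, tolerance = 1e-12)
  expect_error(empirical_moments(V3, rep(0L, 100), group = "case"),
               "degenerate")
})
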