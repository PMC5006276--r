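test_that("SNPs are assigned to genes within the window and unioned by pathway", {
  meta <- data.frame(snp = c("rsA", "rsB"), chrom = "1",
                     pos = c(100000L, 100000L))
  genes <- data.frame(gene = c("G1", "G2"), chrom = "1",
                      start = c(140000L, 160001L), end = c(160000L, 170000L))
  paths <- list(P1 = "G1", P2 = "G2", P3 = c("G1", "G2"))
  cat_ <- build_snp_sets(meta, genes, paths, window_bp = 50000L,
                         min_snps = 1L)
  expect_true("rsA" %in% cat_$sets$P1)     # 40 kb upstream: inside window
  expect_false("P2" %in% names(cat_$sets)) # 60,001 bp: outside, set empty
  expect_error(build_snp_sets(meta, genes, list(P = "G2"), min_snps = 1L),
               "empty catalog")
  # a gene shared by several pathways contributes its SNPs to each
  meta2 <- data.frame(snp = paste0("rs", 1:6), chrom = "1",
                      pos = seq(10000L, 60000L, by = 10000L))
  genes2 <- data.frame(gene = c("GA", "GB"), chrom = "1",
                       start = c(10000L, 300000L), end = c(20000L, 310000L))
  paths2 <- list(X = c("GA"), Y = c("GA", "GB"), Z = c("GA", "ZZZ"))
  cat2 <- build_snp_sets(meta2, genes2, paths2, window_bp = 10000L,
                         min_snps = 1L)
  shared <- cat2$sets$X
  expect_true(all(shared %in% cat2$sets$Y))
  expect_true(all(shared %in% cat2$sets$Z))
  # deterministic and order-independent in its inputs
  cat3 <- build_snp_sets(meta2[sample(6), ], genes2[2:1, ], paths2,
                         window_bp = 10000L, min_snps = 1L)
  expect_identical(cat2$sets, cat3$sets)
})

test_that("null SNP sets score at chance level", {
  set.seed(51)
  n <- 400
  G <- matrix(rbinom(n * 16, 2, 0.3), n, 16)
  d <- dda_cohort(G, rep(0:1, n / 2))
  s1 <- score_snp_set(paste0("snp", 1:8), d, method = "MF",
                      grid = c(0, 0.5), seed = 3, set_name = "null1")
  expect_true(s1$ci[1] <= 0.5 && 0.5 <= s1$ci[2] + 0.02)
  s2 <- score_snp_set(paste0("snp", 9:16), d, method = "MF",
                      grid = c(0, 0.5), seed = 3, set_name = "null2")
  # two disjoint null sets agree within their combined uncertainty
  expect_lt(abs(s1$auc - s2$auc),
            (s1$ci[2] - s1$ci[1]) + (s2$ci[2] - s2$ci[1]))
  # a set absent from the panel is flagged
  s3 <- score_snp_set(c("nope1", "nope2"), d, set_name = "missing")
  expect_true(s3$flagged)
  expect_equal(s3$p_estimate, 1)
})

test_that("AUC-to-p calibration is monotone and anchored near chance", {
  set.seed(52)
  n <- 300
  # panel: 12 null SNPs plus 6 informative ones
  G0 <- matrix(rbinom(n * 12, 1, 0.4), n, 12)
  lb <- rep(0:1, n / 2)
  Gs <- sapply(1:6, function(j) rbinom(n, 1, plogis(-0.5 + 0.9 * lb)))
  d <- dda_cohort(cbind(G0, Gs), lb)
  sets <- c(lapply(1:4, function(k) paste0("snp", (3 * k - 2):(3 * k))),
            list(paste0("snp", 13:15), paste0("snp", 13:18)))
  names(sets) <- paste0("S", 1:6)
  catalog <- structure(list(sets = sets, n_dropped = 0L,
                            window_bp = 0L, min_snps = 1L),
                       class = "dda_snpsets")
  scores <- lapply(names(sets), function(nm)
    score_snp_set(sets[[nm]], d, method = "MF", grid = 0.5, seed = 4,
                  set_name = nm))
  cal <- suppressWarnings(
    calibrate_auc_to_p(scores, catalog, d, method = "MF", grid = 0.5,
                       n_perm = 39, seed = 6))
  expect_gte(cal$slope, 0)
  p_at_half <- cal$predict(0.5)
  expect_gt(p_at_half, 0.01)
  expect_true(all(diff(cal$predict(c(0.5, 0.6, 0.7))) <= 0))
  expect_gt(cal$bonferroni_auc, 0.5)
})

test_that("binomial state enrichment matches closed-form tails", {
  prox <- data.frame(snp = paste0("rs", 1:10), proxy_chrom = "1",
                     proxy_pos = seq(1000L, 10000L, by = 1000L))
  all_active <- state_annotation("E1", data.frame(chrom = "1", start = 1L,
                                                  end = 20000L,
                                                  active = TRUE), 0.1)
  r <- state_enrichment(paste0("rs", 1:10), prox, all_active)
  expect_equal(r$p, 0.1^10)
  expect_equal(r$k, 10)
  # observation at the background level is unremarkable
  half <- state_annotation("E2",
    data.frame(chrom = "1", start = c(1L, 5001L), end = c(5000L, 20000L),
               active = c(TRUE, FALSE)), 0.5)
  r2 <- state_enrichment(paste0("rs", 1:10), prox, half)
  expect_gte(r2$p, 0.5)
  # near-saturated background: nothing short of full activity matters
  sat <- state_annotation("E3", data.frame(chrom = "1", start = c(1L, 5001L),
                                           end = c(5000L, 20000L),
                                           active = c(TRUE, FALSE)), 0.999)
  r3 <- state_enrichment(paste0("rs", 1:10), prox, sat)
  expect_gt(r3$p, 0.99)
  expect_error(state_enrichment(character(0), prox, all_active), "empty")
})

test_that("pair enrichment multiplies fractions and backgrounds", {
  prox <- data.frame(snp = paste0("rs", 1:10), proxy_chrom = "1",
                     proxy_pos = seq(1000L, 10000L, by = 1000L))
  ann <- state_annotation("E1", data.frame(chrom = "1", start = 1L,
                                           end = 20000L, active = TRUE), 0.1)
  pairs <- data.frame(snp1 = paste0("rs", 1:10), snp2 = paste0("rs", 10:1))
  r <- pair_state_enrichment(pairs, prox, ann, ann)
  expect_equal(r$p, (0.1 * 0.1)^10)
  # self-pairing reduces to the squared-background test
  expect_equal(r$background_freq, 0.01)
  # fractions at the product background are unremarkable
  mixed <- state_annotation("E2",
    data.frame(chrom = "1", start = c(1L, 5001L), end = c(5000L, 20000L),
               active = c(TRUE, FALSE)), 0.5)
  r2 <- pair_state_enrichment(pairs, prox, mixed, mixed)
  expect_gte(r2$p, 0.5)
})

test_that("enrichment p-values are approximately uniform under a null annotation", {
  set.seed(53)
  n_snp <- 200; bg <- 0.4
  ps <- replicate(200, {
    flags <- rbinom(n_snp, 1, bg) == 1
    ann <- state_annotation("E", data.frame(chrom = "1",
                                            start = seq_len(n_snp) * 10L,
                                            end = seq_len(n_snp) * 10L,
                                            active = flags), bg)
    prox <- data.frame(snp = paste0("rs", seq_len(n_snp)),
                       proxy_chrom = "1", proxy_pos = seq_len(n_snp) * 10L)
    state_enrichment(paste0("rs", seq_len(n_snp)), prox, ann)$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("LD r-squared helper matches squared correlation", {
  set.seed(54)
  H <- matrix(rbinom(400, 1, 0.5), 100, 4)
  r2 <- ld_r2_from_haplotypes(H)
  expect_equal(r2[1, 2], cor(H[, 1], H[, 2])^2)
  expect_equal(diag(r2), rep(1, 4))
})

test_that("gene-region BED and pathway GMT files are read correctly", {
  td <- withr::local_tempdir()
  bed <- file.path(td, "genes.bed")
  # BED is 0-based half-open; [139999, 160000) is 1-based 140000..160000
  writeLines(c("1\t139999\t160000\tG1", "1\t200000\t260000\tG2"), bed)
  gr <- read_gene_regions(bed)
  expect_equal(gr$gene, c("G1", "G2"))
  expect_equal(gr$start[1], 140000)
  expect_equal(gr$end[1], 160000)
  gmt <- file.path(td, "paths.gmt")
  writeLines(c("P1\tdesc\tG1\tG2", "P2\tdesc\tG2"), gmt)
  pw <- read_gmt(gmt)
  expect_equal(sort(names(pw)), c("P1", "P2"))
  expect_equal(sort(pw$P1), c("G1", "G2"))
  meta <- data.frame(snp = c("rsA", "rsB"), chrom = "1",
                     pos = c(100000L, 210000L))
  cat_ <- build_snp_sets(meta, gr, pw, window_bp = 50000L, min_snps = 1L)
  expect_equal(cat_$sets$P1, c("rsA", "rsB"))
  expect_equal(cat_$sets$P2, "rsB")
})
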