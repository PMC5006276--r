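# Pathway-based SNP sets: construction from gene regions and pathway
# catalogs, collective-inference scoring by cross-validated AUC, AUC to
# p-value calibration, and binomial chromatin-state enrichment tests.

#' Read gene regions from a BED file
#'
#' BED intervals (0-based half-open) are converted to 1-based inclusive
#' coordinates; the name column holds the gene symbol.
#'
#' @param path BED file with at least 4 columns (chrom, start, end, name).
#' @return data frame with columns `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @export
read_gene_regions <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(gene = gr$name,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read a pathway catalog in GMT format
#'
#' @param path GMT file (tab-separated: set name, description, gene symbols).
#' @return named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Build phenotype-independent SNP sets from pathways
#'
#' Assigns each SNP to every gene whose region (extended by `window_bp` on
#' both sides) covers its position on the same chromosome, then forms one
#' SNP set per pathway as the union over the pathway's genes. Sets with
#' fewer than `min_snps` members are dropped.
#'
#' @param snp_meta per-SNP data frame with columns `snp`, `chrom`, `pos`.
#' @param gene_regions data frame from [read_gene_regions()] (or equivalent,
#'   1-based inclusive `start`/`end`, columns `gene`, `chrom`, `start`,
#'   `end`).
#' @param pathways named list of gene vectors (see [read_gmt()]).
#' @param window_bp gene-assignment window in base pairs.
#' @param min_snps minimum SNP-set size retained.
#' @return object of class `dda_snpsets`: named list `sets` of SNP id
#'   vectors, `n_dropped`, `window_bp`, `min_snps`.
#' @export
build_snp_sets <- function(snp_meta, gene_regions, pathways,
                           window_bp = 50000L, min_snps = 20L) {
  snp_gr <- GenomicRanges::GRanges(
    seqnames = as.character(snp_meta$chrom),
    ranges = IRanges::IRanges(start = snp_meta$pos, width = 1L))
  gene_gr <- GenomicRanges::GRanges(
    seqnames = as.character(gene_regions$chrom),
    ranges = IRanges::IRanges(
      start = pmax(1L, gene_regions$start - window_bp),
      end = gene_regions$end + window_bp))
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  gene2snp <- split(snp_meta$snp[S4Vectors::queryHits(hits)],
                    gene_regions$gene[S4Vectors::subjectHits(hits)])
  sets <- lapply(pathways, function(genes) {
    sort(unique(unlist(gene2snp[intersect(genes, names(gene2snp))],
                       use.names = FALSE)))
  })
  sizes <- lengths(sets)
  keep <- sizes >= min_snps
  if (!any(keep))
    stop("empty catalog: no pathway retains >= ", min_snps, " SNPs")
  structure(list(sets = sets[keep], n_dropped = sum(!keep),
                 window_bp = window_bp, min_snps = min_snps),
            class = "dda_snpsets")
}

#' @export
print.dda_snpsets <- function(x, ...) {
  cat("dda_snpsets:", length(x$sets), "sets (", x$n_dropped, "dropped below",
      x$min_snps, "SNPs ), window", x$window_bp, "bp\n")
  invisible(x)
}

#' Score one SNP set by cross-validated prediction AUC
#'
#' Restricts the panel to the set's SNPs and runs both collective inference
#' (penalizer optimized over the grid) and the independent-SNP fit under
#' identical fold assignments. For sets larger than `size_threshold`,
#' within-fold independent-SNP p-value filtering at `p_c_for_large` is
#' applied.
#'
#' @param set_snps character vector of SNP identifiers.
#' @param data a [dda_cohort] (QC-filtered).
#' @param method `"MF"` or `"PL"`.
#' @param model encoding label.
#' @param grid penalizer grid (default as in [cross_validate()]).
#' @param p_c_for_large optional p-value cutoff used when the set exceeds
#'   `size_threshold`.
#' @param size_threshold SNP count above which filtering activates.
#' @param folds,seed cross-validation controls; use one seed across sets so
#'   fold assignments (and hence scores) are comparable.
#' @param set_name label carried into the result.
#' @return object of class `dda_setscore`: `set_name`, `snp_count`, `auc`,
#'   `ci`, `independent_auc`, `independent_ci`, `best_penalizer`,
#'   `mean_snp_count`, `flagged`.
#' @export
score_snp_set <- function(set_snps, data, method = c("MF", "PL"),
                          model = "dominant", grid = NULL,
                          p_c_for_large = NULL, size_threshold = 6000L,
                          folds = 5L, seed = 1L, set_name = "set") {
  method <- match.arg(method)
  stopifnot(inherits(data, "dda_cohort"))
  idx <- match(intersect(set_snps, data$snp_meta$snp), data$snp_meta$snp)
  if (length(idx) == 0L) {
    return(structure(list(set_name = set_name, snp_count = 0L,
                          auc = NA_real_, ci = c(NA_real_, NA_real_),
                          independent_auc = NA_real_,
                          independent_ci = c(NA_real_, NA_real_),
                          best_penalizer = NA_real_, mean_snp_count = 0,
                          p_estimate = 1, flagged = TRUE),
                     class = "dda_setscore"))
  }
  sub <- dda_cohort(data$genotypes[, idx, drop = FALSE], data$phenotypes,
                    data$snp_meta[idx, , drop = FALSE], data$sample_ids)
  p_c <- if (length(idx) > size_threshold) p_c_for_large else NULL
  cv <- cross_validate(sub, method = method, model = model, grid = grid,
                       p_c = p_c, folds = folds, seed = seed)
  cvi <- cross_validate(sub, method = "independent", model = model,
                        p_c = p_c, folds = folds, seed = seed)
  bi <- which.max(cv$results$auc)
  structure(list(set_name = set_name, snp_count = length(idx),
                 auc = cv$best_auc,
                 ci = c(cv$results$ci_low[bi], cv$results$ci_high[bi]),
                 independent_auc = cvi$best_auc,
                 independent_ci = c(cvi$results$ci_low[1L],
                                    cvi$results$ci_high[1L]),
                 best_penalizer = cv$best_penalizer,
                 mean_snp_count = cv$mean_snp_count,
                 p_estimate = NA_real_, flagged = FALSE),
            class = "dda_setscore")
}

#' @export
print.dda_setscore <- function(x, ...) {
  cat("dda_setscore:", x$set_name, "(", x$snp_count, "SNPs ) AUC",
      signif(x$auc, 4), "[", signif(x$ci[1], 4), ",", signif(x$ci[2], 4),
      "] indep.", signif(x$independent_auc, 4), "\n")
  invisible(x)
}

#' Calibrate SNP-set AUC scores to p-values
#'
#' Samples the null AUC distribution of selected calibration sets by
#' phenotype-label permutation (AUC as the statistic), fits a linear map of
#' `-log10 p` on AUC restricted to `AUC > auc_floor`, and locates the
#' Bonferroni threshold, i.e. the AUC whose mapped p-value equals
#' `0.05 / #sets`. Calibration sets default to the 10 sets with AUC nearest
#' 0.5 plus 5 evenly spaced up to the maximum.
#'
#' @param scores list of `dda_setscore` objects.
#' @param sets the `dda_snpsets` catalog the scores came from.
#' @param data the [dda_cohort] used for scoring.
#' @param method,model,grid,folds as used for scoring.
#' @param n_perm permutations per calibration set.
#' @param seed master seed.
#' @param auc_floor lower AUC bound of the linear fit (default 0.52).
#' @param calibration_idx optional explicit indices of calibration sets.
#' @return object of class `dda_auc_calibration`: `slope`, `intercept`,
#'   `r_squared`, `bonferroni_auc`, `n_sets`, `points` (data frame auc,
#'   p_emp), and `predict` (function AUC -> p).
#' @export
calibrate_auc_to_p <- function(scores, sets, data, method = c("MF", "PL"),
                               model = "dominant", grid = NULL, folds = 5L,
                               n_perm = 99L, seed = 1L, auc_floor = 0.52,
                               calibration_idx = NULL) {
  method <- match.arg(method)
  if (length(scores) < 5L) stop("need at least 5 scored sets to calibrate")
  aucs <- vapply(scores, `[[`, numeric(1), "auc")
  if (is.null(calibration_idx)) {
    near_null <- order(abs(aucs - 0.5))[seq_len(min(10L, length(aucs)))]
    spread <- unique(round(seq(1L, length(aucs), length.out = 5L)))
    spread <- order(aucs)[spread]
    calibration_idx <- unique(c(near_null, spread))
  }
  seeds <- child_seeds(seed, length(calibration_idx))
  pts <- lapply(seq_along(calibration_idx), function(k) {
    ci_ <- calibration_idx[k]
    nm <- scores[[ci_]]$set_name
    snps <- sets$sets[[nm]]
    idx <- match(intersect(snps, data$snp_meta$snp), data$snp_meta$snp)
    sub_enc <- encode_genotypes(
      dda_cohort(data$genotypes[, idx, drop = FALSE], data$phenotypes,
                 data$snp_meta[idx, , drop = FALSE], data$sample_ids), model)
    obs <- scores[[ci_]]$auc
    pen <- scores[[ci_]]$best_penalizer
    set.seed(seeds[k])
    null_auc <- vapply(seq_len(n_perm), function(b) {
      lb <- sample(data$phenotypes)
      cv <- cross_validate(sub_enc, labels = lb, method = method,
                           model = model, grid = pen, folds = folds,
                           seed = seeds[k])
      cv$best_auc
    }, numeric(1))
    data.frame(auc = obs, p_emp = (1 + sum(null_auc >= obs)) / (1 + n_perm))
  })
  pts <- do.call(rbind, pts)
  fit_pts <- pts[pts$auc > auc_floor, , drop = FALSE]
  if (nrow(fit_pts) < 2L)
    stop("calibration error: fewer than 2 points with AUC > ", auc_floor)
  fit <- lm(-log10(p_emp) ~ auc, data = fit_pts)
  slope <- max(0, unname(coef(fit)[2L]))   # enforce monotone mapping
  intercept <- unname(coef(fit)[1L])
  r2 <- summary(fit)$r.squared
  n_sets <- length(scores)
  target <- -log10(0.05 / n_sets)
  bon <- if (slope > 0) (target - intercept) / slope else Inf
  pred <- function(auc) {
    lp <- pmax(0, intercept + slope * auc)
    10^(-lp)
  }
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 bonferroni_auc = bon, n_sets = n_sets, points = pts,
                 predict = pred),
            class = "dda_auc_calibration")
}

#' @export
print.dda_auc_calibration <- function(x, ...) {
  cat("dda_auc_calibration: -log10 p =", signif(x$intercept, 4), "+",
      signif(x$slope, 4), "x AUC (r2 =", signif(x$r_squared, 3), ")\n")
  cat("  Bonferroni AUC threshold (", x$n_sets, "sets ):",
      signif(x$bonferroni_auc, 4), "\n")
  invisible(x)
}

#' Chromatin-state annotation of one reference epigenome
#'
#' @param epigenome_id label of the epigenome.
#' @param regions data frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive) and logical `active` (membership in the 8 transcribed /
#'   promoter-flanking / enhancer states).
#' @param background_freq genome-wide active-state fraction in (0, 1).
#' @return object of class `dda_state_annotation`.
#' @export
state_annotation <- function(epigenome_id, regions, background_freq) {
  stopifnot(background_freq > 0, background_freq < 1,
            all(c("chrom", "start", "end", "active") %in% names(regions)))
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(regions$chrom),
    ranges = IRanges::IRanges(start = regions$start, end = regions$end))
  structure(list(epigenome_id = epigenome_id, gr = gr,
                 active = regions$active, background_freq = background_freq),
            class = "dda_state_annotation")
}

# fraction of proxy positions of each SNP falling in active states
active_fraction <- function(snps, proxies, annotation) {
  pg <- GenomicRanges::GRanges(
    seqnames = as.character(proxies$proxy_chrom),
    ranges = IRanges::IRanges(start = proxies$proxy_pos, width = 1L))
  hit <- GenomicRanges::findOverlaps(pg, annotation$gr, select = "first")
  act <- !is.na(hit) & annotation$active[ifelse(is.na(hit), 1L, hit)]
  vapply(snps, function(s) {
    rows <- proxies$snp == s
    if (!any(rows)) stop("SNP ", s, " has no proxies (it must list itself)")
    mean(act[rows])
  }, numeric(1))
}

#' Binomial enrichment of active chromatin states among associated SNPs
#'
#' For each SNP the fraction of its LD proxies lying in active states is
#' computed; the fractions are summed to an effective observed count and
#' tested against the epigenome's background active fraction with an
#' upper-tail binomial test. The effective count is rounded half-up; the
#' unrounded value is reported alongside.
#'
#' @param snp_list character vector of associated SNP identifiers.
#' @param ld_proxies data frame with columns `snp`, `proxy_chrom`,
#'   `proxy_pos` (and optionally `r2`); every SNP must list at least itself.
#' @param annotation a [state_annotation()] object.
#' @return list with `p`, `k_eff` (unrounded), `k` (rounded), `n`,
#'   `background_freq`, `fractions`.
#' @export
state_enrichment <- function(snp_list, ld_proxies, annotation) {
  if (length(snp_list) == 0L) stop("empty SNP list")
  fr <- active_fraction(snp_list, ld_proxies, annotation)
  k_eff <- sum(fr)
  n <- length(snp_list)
  k <- min(n, floor(k_eff + 0.5))
  p <- binom.test(k, n, p = annotation$background_freq,
                  alternative = "greater")$p.value
  list(p = p, k_eff = k_eff, k = k, n = n,
       background_freq = annotation$background_freq, fractions = fr)
}

#' Binomial enrichment of active-state pairs among interacting SNP pairs
#'
#' For each significant SNP pair, the product of active-proxy fractions
#' (first SNP in epigenome A, second in epigenome B) estimates the
#' active-active pair fraction; the products are summed and tested against
#' the product of the two background frequencies.
#'
#' @param snp_pairs data frame with columns `snp1`, `snp2` (e.g. pairs with
#'   interaction p below a cutoff).
#' @param ld_proxies as in [state_enrichment()].
#' @param annotation_a,annotation_b [state_annotation()] objects for the two
#'   epigenomes (may be identical).
#' @return list with `p`, `k_eff`, `k`, `n`, `background_freq`.
#' @export
pair_state_enrichment <- function(snp_pairs, ld_proxies, annotation_a,
                                  annotation_b) {
  if (nrow(snp_pairs) == 0L) stop("empty pair list")
  fa <- active_fraction(snp_pairs$snp1, ld_proxies, annotation_a)
  fb <- active_fraction(snp_pairs$snp2, ld_proxies, annotation_b)
  k_eff <- sum(fa * fb)
  n <- nrow(snp_pairs)
  k <- min(n, floor(k_eff + 0.5))
  bg <- annotation_a$background_freq * annotation_b$background_freq
  p <- binom.test(k, n, p = bg, alternative = "greater")$p.value
  list(p = p, k_eff = k_eff, k = k, n = n, background_freq = bg)
}

#' Pairwise LD r-squared from phased haplotypes
#'
#' Helper for constructing synthetic LD-proxy tables in tests: squared
#' Pearson correlation between haplotype columns.
#'
#' @param H binary haplotype matrix (haplotypes x variants).
#' @return symmetric matrix of r-squared values.
#' @export
ld_r2_from_haplotypes <- function(H) {
  suppressWarnings(stats::cor(H))^2
}

#' Write SNP-set scores as TSV
#' @param scores list of `dda_setscore` objects.
#' @param path output path.
#' @export
write_setscore_report <- function(scores, path) {
  df <- do.call(rbind, lapply(scores, function(s) {
    data.frame(set = s$set_name, snps = s$snp_count, auc = s$auc,
               ci_low = s$ci[1], ci_high = s$ci[2],
               independent_auc = s$independent_auc,
               best_penalizer = s$best_penalizer,
               p_estimate = s$p_estimate, flagged = s$flagged)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
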