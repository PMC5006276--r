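#' Case-control cohort genotype data
#'
#' Constructor for the cohort container used throughout the package:
#' minor-allele count genotypes (0/1/2, `NA` = missing), binary phenotypes
#' (0 = control, 1 = case), and per-SNP metadata.
#'
#' @param genotypes integer `n x m` matrix of minor-allele counts in
#'   \{0, 1, 2, NA\}.
#' @param phenotypes length-n vector in \{0, 1\} (1 = case).
#' @param snp_meta data frame with columns `snp`, `chrom`, `pos`, `allele1`
#'   (counted allele), `allele2`.
#' @param sample_ids length-n character vector.
#' @return an object of class `dda_cohort`.
#' @export
dda_cohort <- function(genotypes, phenotypes, snp_meta = NULL,
                       sample_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes); m <- ncol(genotypes)
  phenotypes <- as.integer(phenotypes)
  if (length(phenotypes) != n) stop("phenotype length does not match genotypes")
  if (!all(phenotypes %in% c(0L, 1L))) stop("phenotypes must be 0/1")
  if (!all(genotypes %in% c(0L, 1L, 2L) | is.na(genotypes)))
    stop("genotypes must be in {0, 1, 2, NA}")
  n0 <- sum(phenotypes == 0L); n1 <- sum(phenotypes == 1L)
  if (n0 == 0L || n1 == 0L)
    stop("degenerate cohort: both case and control groups must be non-empty")
  if (is.null(snp_meta))
    snp_meta <- data.frame(snp = paste0("snp", seq_len(m)), chrom = "1",
                           pos = seq_len(m), allele1 = "A", allele2 = "B",
                           stringsAsFactors = FALSE)
  if (anyDuplicated(snp_meta$snp)) stop("SNP identifiers must be unique")
  if (is.null(sample_ids)) sample_ids <- paste0("id", seq_len(n))
  colnames(genotypes) <- snp_meta$snp
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 snp_meta = snp_meta, sample_ids = as.character(sample_ids)),
            class = "dda_cohort")
}

#' @export
print.dda_cohort <- function(x, ...) {
  cat("dda_cohort:", length(x$phenotypes), "samples (",
      sum(x$phenotypes == 0), "controls /", sum(x$phenotypes == 1),
      "cases ),", ncol(x$genotypes), "SNPs\n")
  invisible(x)
}

parse_error <- function(file, line_no, why) {
  stop(sprintf("parse error in %s at line %d: %s", file, line_no, why),
       call. = FALSE)
}

map_phenotypes <- function(codes, ids) {
  # PLINK codes: 1 = control, 2 = case; anything else = missing sample
  pheno <- rep(NA_integer_, length(codes))
  pheno[codes == "1"] <- 0L
  pheno[codes == "2"] <- 1L
  drop <- is.na(pheno)
  if (any(drop))
    message(sum(drop), " sample(s) with unknown phenotype code dropped")
  list(pheno = pheno[!drop], keep = !drop)
}

#' Read PLINK genotype files
#'
#' Reads a case-control panel from PLINK text (`.ped`/`.map`) or binary
#' (`.bed`/`.bim`/`.fam`, SNP-major) files. Phenotype codes 1/2 are mapped to
#' control/case; samples with any other phenotype code are dropped. Genotypes
#' are returned as counts of the designated minor allele; for `.ped` input
#' the minor allele is identified from the pooled sample allele frequencies,
#' for `.bed` input the `.bim` A1 allele is counted (re-identification happens
#' in [qc_filter()]).
#'
#' @param prefix path prefix (without extension), or a full path to a `.ped`
#'   or `.bed` file.
#' @param format `"auto"` (default), `"ped"` or `"bed"`.
#' @return a [dda_cohort] object.
#' @export
load_genotypes <- function(prefix, format = c("auto", "ped", "bed")) {
  format <- match.arg(format)
  prefix <- sub("\\.(ped|bed)$", "", prefix)
  if (format == "auto")
    format <- if (file.exists(paste0(prefix, ".bed"))) "bed" else "ped"
  if (format == "ped") read_ped(prefix) else read_bed(prefix)
}

read_ped <- function(prefix) {
  ped_f <- paste0(prefix, ".ped"); map_f <- paste0(prefix, ".map")
  if (!file.exists(ped_f)) stop("file not found: ", ped_f)
  if (!file.exists(map_f)) stop("file not found: ", map_f)
  map <- read.table(map_f, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 4L) stop(".map must have 4 columns")
  m <- nrow(map)
  lines <- readLines(ped_f)
  lines <- lines[nzchar(trimws(lines))]
  n_raw <- length(lines)
  ids <- character(n_raw); codes <- character(n_raw)
  a1 <- matrix("", n_raw, m); a2 <- matrix("", n_raw, m)
  for (k in seq_len(n_raw)) {
    f <- strsplit(trimws(lines[k]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * m)
      parse_error(ped_f, k, sprintf("expected %d fields, found %d",
                                    6L + 2L * m, length(f)))
    ids[k] <- f[2L]; codes[k] <- f[6L]
    al <- f[-(1:6)]
    a1[k, ] <- al[seq(1L, 2L * m, by = 2L)]
    a2[k, ] <- al[seq(2L, 2L * m, by = 2L)]
  }
  ph <- map_phenotypes(codes, ids)
  a1 <- a1[ph$keep, , drop = FALSE]; a2 <- a2[ph$keep, , drop = FALSE]
  ids <- ids[ph$keep]
  n <- nrow(a1)
  G <- matrix(NA_integer_, n, m)
  minor <- character(m); major <- character(m)
  for (j in seq_len(m)) {
    alle <- c(a1[, j], a2[, j])
    obs <- alle[alle != "0"]
    lv <- sort(unique(obs))
    if (length(lv) > 2L)
      parse_error(ped_f, 1L, sprintf("SNP %s has >2 alleles", map[j, 2L]))
    if (length(lv) == 0L) lv <- c("0", "0")
    if (length(lv) == 1L) lv <- c(lv, lv)
    cnt <- c(sum(obs == lv[1L]), sum(obs == lv[2L]))
    mi <- if (cnt[1L] <= cnt[2L]) 1L else 2L
    minor[j] <- lv[mi]; major[j] <- lv[3L - mi]
    miss <- a1[, j] == "0" | a2[, j] == "0"
    G[, j] <- (a1[, j] == minor[j]) + (a2[, j] == minor[j])
    G[miss, j] <- NA_integer_
  }
  meta <- data.frame(snp = as.character(map[, 2L]), chrom = as.character(map[, 1L]),
                     pos = as.integer(map[, 4L]), allele1 = minor,
                     allele2 = major, stringsAsFactors = FALSE)
  dda_cohort(G, ph$pheno, meta, ids)
}

read_bed <- function(prefix) {
  bed_f <- paste0(prefix, ".bed"); bim_f <- paste0(prefix, ".bim")
  fam_f <- paste0(prefix, ".fam")
  for (f in c(bed_f, bim_f, fam_f))
    if (!file.exists(f)) stop("file not found: ", f)
  bim <- read.table(bim_f, header = FALSE, stringsAsFactors = FALSE)
  fam <- read.table(fam_f, header = FALSE, stringsAsFactors = FALSE)
  m <- nrow(bim); n_raw <- nrow(fam)
  raw <- readBin(bed_f, "raw", n = file.size(bed_f))
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes): ", bed_f)
  if (raw[3L] != as.raw(0x01))
    stop("only SNP-major .bed files are supported")
  bps <- ceiling(n_raw / 4)               # bytes per SNP
  if (length(raw) != 3L + bps * m)
    stop("unexpected .bed size for ", n_raw, " samples x ", m, " SNPs")
  body <- raw[-(1:3)]
  # decode 2-bit genotypes: 00 -> 2 (hom A1), 01 -> NA, 10 -> 1, 11 -> 0
  look <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  bits <- matrix(as.integer(body), nrow = bps)
  G <- matrix(NA_integer_, n_raw, m)
  for (shift in 0:3) {
    rows <- shift + 1L + 4L * (seq_len(bps) - 1L)
    vals <- look[1L + (bits %/% 4L^shift) %% 4L]
    keep <- rows <= n_raw
    G[rows[keep], ] <- matrix(vals, nrow = bps)[keep, , drop = FALSE]
  }
  ph <- map_phenotypes(as.character(fam[, 6L]), fam[, 2L])
  G <- G[ph$keep, , drop = FALSE]
  meta <- data.frame(snp = as.character(bim[, 2L]), chrom = as.character(bim[, 1L]),
                     pos = as.integer(bim[, 4L]), allele1 = as.character(bim[, 5L]),
                     allele2 = as.character(bim[, 6L]), stringsAsFactors = FALSE)
  dda_cohort(G, ph$pheno, meta, fam[ph$keep, 2L])
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact two-sided test for deviation from Hardy-Weinberg proportions from
#' genotype counts, summing the probabilities of all heterozygote counts
#' (conditional on the allele counts) no more probable than the observed one.
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (minor homozygote,
#'   heterozygote, major homozygote).
#' @return the exact p-value.
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  if (n == 0L) return(1)
  n_a <- 2L * n_hom1 + n_het            # minor allele count
  hets <- seq.int(n_a %% 2L, min(n_a, 2L * n - n_a), by = 2L)
  # unnormalized log-probabilities of each possible heterozygote count
  lp <- vapply(hets, function(h) {
    ha <- (n_a - h) %/% 2L               # minor homozygotes
    hb <- n - ha - h                     # major homozygotes
    h * log(2) - lgamma(ha + 1) - lgamma(h + 1) - lgamma(hb + 1)
  }, numeric(1))
  pr <- exp(lp - lse(lp))
  obs <- pr[match(n_het, hets)]
  min(1, sum(pr[pr <= obs + 1e-12]))
}

#' Quality-filter a cohort
#'
#' Re-identifies the minor allele from pooled-sample allele frequencies,
#' then removes SNPs failing any of: pooled minor-allele frequency
#' `> maf_min`, exact Hardy-Weinberg p-value (control samples) `> hwe_p_min`,
#' per-SNP missingness `<= miss_max`.
#'
#' @param data a [dda_cohort] object.
#' @param maf_min minimum pooled minor-allele frequency (exclusive).
#' @param hwe_p_min minimum Hardy-Weinberg exact p-value (exclusive),
#'   computed on control samples.
#' @param miss_max maximum per-SNP fraction of missing genotypes (inclusive).
#' @return the filtered [dda_cohort]; a data frame of per-criterion removal
#'   counts is attached as attribute `"qc_report"` and per-SNP allele flips as
#'   `"minor_allele_flipped"`.
#' @export
qc_filter <- function(data, maf_min = 0.01, hwe_p_min = 1e-6,
                      miss_max = 0.05) {
  stopifnot(inherits(data, "dda_cohort"))
  for (v in c(maf_min, hwe_p_min, miss_max))
    if (v < 0 || v > 1) stop("thresholds must lie in [0, 1]")
  G <- data$genotypes
  n <- nrow(G); m <- ncol(G)
  # minor-allele re-identification over the pooled sample
  freq <- colMeans(G, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq > 0.5
  if (any(flip)) {
    G[, flip] <- 2L - G[, flip]
    meta <- data$snp_meta
    tmp <- meta$allele1[flip]
    meta$allele1[flip] <- meta$allele2[flip]
    meta$allele2[flip] <- tmp
    data$snp_meta <- meta
    freq[flip] <- 1 - freq[flip]
  }
  miss <- colMeans(is.na(G))
  ctrl <- data$phenotypes == 0L
  hwe_p <- vapply(seq_len(m), function(j) {
    g <- G[ctrl, j]; g <- g[!is.na(g)]
    hwe_exact_test(sum(g == 2L), sum(g == 1L), sum(g == 0L))
  }, numeric(1))
  fail_maf <- !(freq > maf_min) | is.na(freq)
  fail_hwe <- !(hwe_p > hwe_p_min)
  fail_miss <- !(miss <= miss_max)
  keep <- !(fail_maf | fail_hwe | fail_miss)
  if (!any(keep)) stop("empty panel: all SNPs removed by QC")
  report <- data.frame(criterion = c("maf", "hwe", "missingness"),
                       removed = c(sum(fail_maf), sum(fail_hwe), sum(fail_miss)))
  out <- dda_cohort(G[, keep, drop = FALSE], data$phenotypes,
                    data$snp_meta[keep, , drop = FALSE], data$sample_ids)
  attr(out, "qc_report") <- report
  attr(out, "minor_allele_flipped") <- flip[keep]
  out
}

#' Write a QC report as TSV
#' @param data a QC-filtered [dda_cohort] (output of [qc_filter()]).
#' @param path output path.
#' @export
write_qc_report <- function(data, path) {
  rep <- attr(data, "qc_report")
  if (is.null(rep)) stop("no qc_report attribute; run qc_filter() first")
  write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Encode genotypes under a genetic model
#'
#' Maps minor-allele counts to the dominant (carrier 0/1), recessive
#' (minor homozygote 0/1) or genotypic (identity 0/1/2) encoding. Missing
#' genotypes are imputed beforehand to the per-SNP modal genotype of the
#' pooled sample (ties broken toward the smaller count).
#'
#' @param data a [dda_cohort], normally after [qc_filter()].
#' @param model `"dominant"`, `"recessive"` or `"genotypic"`.
#' @return an object of class `dda_encoded`: list with `values` (n x m
#'   numeric matrix, no missing entries), `model`, `snp` ids, and
#'   `minor_allele_flags`.
#' @export
encode_genotypes <- function(data, model = c("dominant", "recessive", "genotypic")) {
  model <- match.arg(model)
  G <- data$genotypes
  for (j in seq_len(ncol(G))) {
    if (anyNA(G[, j])) {
      tab <- tabulate(G[, j] + 1L, nbins = 3L)
      G[is.na(G[, j]), j] <- which.max(tab) - 1L
    }
  }
  V <- switch(model,
              dominant = (G >= 1L) + 0,
              recessive = (G == 2L) + 0,
              genotypic = G + 0)
  flags <- attr(data, "minor_allele_flipped")
  if (is.null(flags)) flags <- rep(FALSE, ncol(G))
  structure(list(values = V, model = model, snp = data$snp_meta$snp,
                 minor_allele_flags = flags),
            class = "dda_encoded")
}

#' @export
print.dda_encoded <- function(x, ...) {
  cat("dda_encoded:", nrow(x$values), "samples x", ncol(x$values),
      "SNPs,", x$model, "model\n")
  invisible(x)
}

# accept either a dda_encoded object or a plain numeric matrix
enc_values <- function(enc) {
  if (inherits(enc, "dda_encoded")) enc$values else as.matrix(enc)
}
enc_model <- function(enc, default = "dominant") {
  if (inherits(enc, "dda_encoded")) enc$model else default
}

#' Empirical genotype moments of a group
#'
#' Single-SNP level frequencies and SNP-pair co-occurrence frequencies over
#' the selected group, in the expanded level-indicator representation.
#'
#' @param enc a `dda_encoded` object (or encoded matrix).
#' @param labels phenotype vector (0/1); ignored for `group = "pooled"` with
#'   `labels = NULL`.
#' @param group `"control"`, `"case"` or `"pooled"`.
#' @param model encoding label when `enc` is a plain matrix.
#' @return object of class `dda_moments`: `f_single` (length m*L), `f_pair`
#'   (m*L x m*L, diagonal equals `f_single` for binary encodings), `n`,
#'   `group`, `model`.
#' @export
empirical_moments <- function(enc, labels = NULL,
                              group = c("pooled", "control", "case"),
                              model = NULL) {
  group <- match.arg(group)
  V <- enc_values(enc)
  model <- if (is.null(model)) enc_model(enc) else model
  rows <- switch(group,
                 pooled = rep(TRUE, nrow(V)),
                 control = labels == 0,
                 case = labels == 1)
  if (group != "pooled" && is.null(labels)) stop("labels required for group moments")
  if (!any(rows)) stop("degenerate group: no samples in ", group)
  X <- expand_indicators(V[rows, , drop = FALSE], enc_levels(model))
  structure(list(f_single = colMeans(X), f_pair = crossprod(X) / sum(rows),
                 n = sum(rows), group = group, model = model),
            class = "dda_moments")
}

#' Write a cohort as PLINK .ped/.map text files
#'
#' Minor-allele counts are written as allele pairs (0: `A2 A2`, 1: `A1 A2`,
#' 2: `A1 A1`; missing: `0 0`) with phenotypes coded 1/2.
#'
#' @param data a [dda_cohort].
#' @param prefix output path prefix (writes `prefix.ped` and `prefix.map`).
#' @export
write_plink_ped <- function(data, prefix) {
  G <- data$genotypes
  meta <- data$snp_meta
  map <- data.frame(meta$chrom, meta$snp, 0, meta$pos)
  write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  n <- nrow(G); m <- ncol(G)
  al <- matrix("0", n, 2L * m)
  for (j in seq_len(m)) {
    g <- G[, j]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, meta$allele1[j], meta$allele2[j]))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2L, meta$allele1[j], meta$allele2[j]))
    al[, 2L * j - 1L] <- a1; al[, 2L * j] <- a2
  }
  ped <- cbind(data$sample_ids, data$sample_ids, 0, 0, 0,
               data$phenotypes + 1L, al)
  write.table(ped, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
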