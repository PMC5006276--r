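#' Disease-risk model
#'
#' Bayes posterior risk of disease given genotypes:
#' `Pr(y = 1 | a) = 1 / (1 + exp(-alpha - sum beta_i a_i - sum gamma_ij a_i a_j))`,
#' with `beta` and `gamma` given by differences of the case and control
#' genotype-distribution parameters (or fitted directly by logistic
#' regression).
#'
#' @param alpha intercept.
#' @param beta per-SNP effects in the expanded level-indicator layout
#'   (length `m*L`).
#' @param gamma symmetric `m*L x m*L` interaction matrix, zero within-SNP
#'   blocks.
#' @param prevalence disease prevalence `p1` in (0, 1).
#' @param model encoding label.
#' @param source `"DDA"`, `"logistic"` or `"truth"`.
#' @return an object of class `dda_risk`.
#' @export
dda_risk <- function(alpha, beta, gamma = NULL, prevalence = 0.5,
                     model = "dominant", source = "DDA") {
  L <- enc_levels(model)
  d <- length(beta)
  m <- d %/% L
  if (is.null(gamma)) gamma <- matrix(0, d, d)
  gamma <- as.matrix(gamma)
  if (max(abs(gamma - t(gamma))) > 1e-8) stop("gamma must be symmetric")
  snp_of <- rep(seq_len(m), each = L)
  gamma[outer(snp_of, snp_of, "==")] <- 0
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must lie in (0, 1)")
  structure(list(alpha = alpha, beta = as.numeric(beta), gamma = gamma,
                 prevalence = prevalence, model = model, source = source,
                 m = m, L = L),
            class = "dda_risk")
}

#' @export
print.dda_risk <- function(x, ...) {
  cat("dda_risk (", x$source, "): ", x$m, " SNPs, ", x$model,
      " model, prevalence ", signif(x$prevalence, 4), "\n", sep = "")
  cat("  alpha:", signif(x$alpha, 6), " |beta| max:",
      signif(max(abs(x$beta)), 4), " |gamma| max:",
      signif(max(abs(x$gamma)), 4), "\n")
  invisible(x)
}

#' Convert fitted genotype distributions to a disease-risk model
#'
#' Risk effects are element-wise differences between case and control
#' parameters (`beta = h1 - h0`, `gamma = J1 - J0`). The intercept is
#' `ln(p1/p0) + lnZ0 - lnZ1` when exact partition values are available
#' (EE and independent fits); for PL fits it is calibrated by a
#' one-parameter maximum-likelihood fit of the labels given the fixed linear
#' predictor on the training data; for MF fits the mean-field free energies
#' are used.
#'
#' @param fit a `dda_fit` object.
#' @param prevalence disease prevalence `p1`; defaults to the sample case
#'   fraction. Re-specifying it shifts the intercept by the difference of
#'   the logit prevalences.
#' @return a [dda_risk] object.
#' @export
to_risk_model <- function(fit, prevalence = NULL) {
  stopifnot(inherits(fit, "dda_fit"))
  psi0 <- fit$psi0; psi1 <- fit$psi1
  if (psi0$model != psi1$model || psi0$m != psi1$m)
    stop("case and control fits use different models")
  p1_samp <- fit$n1 / (fit$n0 + fit$n1)
  beta <- psi1$H - psi0$H
  gamma <- psi1$Jbig - psi0$Jbig
  if (fit$method %in% c("EE", "independent", "MF")) {
    alpha <- log(p1_samp / (1 - p1_samp)) +
      psi0$log_partition - psi1$log_partition
  } else {
    # PL: calibrate the intercept on the training sample
    X <- expand_indicators(enc_values(fit$enc), psi0$L)
    lay <- theta_layout(psi0$m, psi0$L)
    lp <- drop(feature_matrix(X, lay) %*% pack_theta(beta, gamma, lay))
    cal <- glm(fit$labels ~ 1, family = binomial(), offset = lp)
    alpha <- unname(coef(cal)[1L])
  }
  out <- dda_risk(alpha, beta, gamma, prevalence = p1_samp,
                  model = psi0$model, source = "DDA")
  if (!is.null(prevalence)) out <- set_prevalence(out, prevalence)
  out
}

#' Re-specify the disease prevalence of a risk model
#'
#' Shifts the intercept by the logit difference of the new and old
#' prevalences; all other parameters (and hence AUC) are unchanged.
#'
#' @param model a [dda_risk] object.
#' @param prevalence new prevalence in (0, 1).
#' @return the updated [dda_risk].
#' @export
set_prevalence <- function(model, prevalence) {
  stopifnot(inherits(model, "dda_risk"))
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must lie in (0, 1)")
  model$alpha <- model$alpha + qlogis(prevalence) - qlogis(model$prevalence)
  model$prevalence <- prevalence
  model
}

#' Predict disease risk scores
#'
#' @param model a [dda_risk] object.
#' @param enc encoded genotypes with the same SNP panel and encoding.
#' @return numeric vector of posterior case probabilities in (0, 1).
#' @export
predict_risk <- function(model, enc) {
  V <- enc_values(enc)
  if (ncol(V) != model$m) stop("SNP count mismatch")
  X <- expand_indicators(V, model$L)
  lay <- theta_layout(model$m, model$L)
  lp <- model$alpha +
    drop(feature_matrix(X, lay) %*% pack_theta(model$beta, model$gamma, lay))
  plogis(lp)
}

#' AUC with a 95% confidence interval
#'
#' Mann-Whitney estimator of the area under the receiver operating
#' characteristic curve with midrank tie handling; the confidence interval
#' uses the Hanley-McNeil standard error.
#'
#' @param scores numeric risk scores.
#' @param labels phenotype vector (0/1).
#' @return list with `estimate`, `ci` (length 2), `se`, `n0`, `n1`.
#' @export
auc_mw <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- as.numeric(sum(labels == 1)); n0 <- as.numeric(sum(labels == 0))
  if (n0 == 0L || n1 == 0L) stop("degenerate: both classes must be present")
  r <- rank(scores)                      # midranks
  a <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
               (n0 * n1))
  list(estimate = a, ci = c(max(0, a - 1.96 * se), min(1, a + 1.96 * se)),
       se = se, n0 = n0, n1 = n1)
}

#' Independent-SNP association p-values
#'
#' Per-SNP likelihood-ratio (G) statistic comparing separate case/control
#' level frequencies against pooled frequencies, with chi-square d.f. equal
#' to the number of non-reference levels.
#'
#' @param enc encoded genotypes.
#' @param labels phenotype vector (0/1).
#' @param model encoding label when `enc` is a plain matrix.
#' @return data frame with columns `snp`, `q`, `df`, `p`.
#' @export
independent_snp_pvalues <- function(enc, labels, model = NULL) {
  V <- enc_values(enc)
  model <- if (is.null(model)) enc_model(enc) else model
  L <- enc_levels(model)
  m <- ncol(V)
  counts <- function(rows) {
    sapply(0:L, function(g) colSums(V[rows, , drop = FALSE] == g))
  }
  c0 <- counts(which(labels == 0)); c1 <- counts(which(labels == 1))
  if (m == 1L) { c0 <- matrix(c0, 1L); c1 <- matrix(c1, 1L) }
  cp <- c0 + c1
  gterm <- function(obs, tot) {
    f <- obs / tot
    ifelse(obs > 0, obs * log(f), 0)
  }
  n0 <- sum(labels == 0); n1 <- sum(labels == 1); n <- n0 + n1
  q <- 2 * (rowSums(gterm(c0, n0)) + rowSums(gterm(c1, n1)) -
              rowSums(gterm(cp, n)))
  q <- pmax(q, 0)
  snp <- if (inherits(enc, "dda_encoded")) enc$snp else paste0("snp", seq_len(m))
  data.frame(snp = snp, q = q, df = L, p = pchisq(q, df = L, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Mean square error of a risk model against truth
#'
#' Mean of squared differences over all distinct single-SNP and interaction
#' effects.
#'
#' @param model,true_theta [dda_risk] objects on the same panel.
#' @return scalar mean square error.
#' @export
mse_vs_truth <- function(model, true_theta) {
  if (model$m != true_theta$m || model$L != true_theta$L)
    stop("risk models have different shapes")
  lay <- theta_layout(model$m, model$L)
  db <- model$beta - true_theta$beta
  dg <- (model$gamma - true_theta$gamma)[cbind(lay$r_idx, lay$s_idx)]
  mean(c(db, dg)^2)
}

fit_one_method <- function(enc, labels, method, penalizer, model) {
  if (method == "logistic") {
    fit_logistic(enc, labels, lambda = penalizer, model = model)
  } else {
    f <- dda_fit(enc, labels, method = method, penalizer = penalizer,
                 model = model)
    to_risk_model(f)
  }
}

subset_enc <- function(enc, rows = NULL, cols = NULL) {
  V <- enc_values(enc)
  if (!is.null(rows)) V <- V[rows, , drop = FALSE]
  if (!is.null(cols)) V <- V[, cols, drop = FALSE]
  snp <- if (inherits(enc, "dda_encoded")) enc$snp else colnames(V)
  flags <- if (inherits(enc, "dda_encoded")) enc$minor_allele_flags else rep(FALSE, ncol(V))
  if (!is.null(cols)) { snp <- snp[cols]; flags <- flags[cols] }
  structure(list(values = V, model = enc_model(enc), snp = snp,
                 minor_allele_flags = flags), class = "dda_encoded")
}

stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (y in 0:1) {
    idx <- which(labels == y)
    if (length(idx) < folds)
      stop("re-stratification error: a class has fewer samples than folds")
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

#' Cross-validated AUC over a penalizer grid
#'
#' Stratified k-fold cross-validation of risk prediction. For each penalizer
#' value the model is fitted on each training fold and test-fold scores are
#' pooled before a single AUC is computed. With `p_c` set, independent-SNP
#' p-values are computed on each training fold only and SNPs with `p < p_c`
#' retained (the unbiased pre-selection protocol); preselecting on the full
#' sample instead labels the resulting score a pseudo-AUC (`"pAUC"`).
#'
#' @param data a [dda_cohort] or `dda_encoded` object.
#' @param labels phenotype vector; taken from `data` when it is a cohort.
#' @param method `"EE"`, `"PL"`, `"MF"`, `"logistic"` or `"independent"`.
#' @param model encoding used if `data` is a cohort.
#' @param grid penalizer values (lambda, or epsilon for MF). Defaults: 13
#'   logarithmic points 1e-4..1e2 for lambda methods, 11 linear points 0..1
#'   for MF, a single NA for the independent fit.
#' @param p_c optional independent-SNP p-value cutoff for SNP pre-selection.
#' @param preselection `"fold"` (default; cutoff applied within each training
#'   fold) or `"full"` (applied once on the full sample; biased, reported as
#'   pAUC).
#' @param folds number of folds.
#' @param seed integer seed controlling fold assignment.
#' @return object of class `dda_cv`: data frame `results` (penalizer, auc,
#'   ci_low, ci_high), `best_penalizer` (ties broken toward the stronger
#'   penalizer), `best_auc`, `mean_snp_count`, `fold_assignments`,
#'   `score_label` (`"AUC"` or `"pAUC"`).
#' @export
cross_validate <- function(data, labels = NULL,
                           method = c("EE", "PL", "MF", "logistic", "independent"),
                           model = "dominant", grid = NULL, p_c = NULL,
                           preselection = c("fold", "full"), folds = 5L,
                           seed = 1L) {
  method <- match.arg(method)
  preselection <- match.arg(preselection)
  if (inherits(data, "dda_cohort")) {
    labels <- data$phenotypes
    enc <- encode_genotypes(data, model)
  } else {
    enc <- data
    model <- enc_model(enc)
    if (is.null(labels)) stop("labels required with encoded input")
  }
  if (folds < 2L) stop("folds must be >= 2")
  if (is.null(grid)) {
    grid <- switch(method,
                   MF = seq(0, 1, length.out = 11L),
                   independent = NA_real_,
                   10^seq(-4, 2, length.out = 13L))
  }
  score_label <- "AUC"
  keep_full <- seq_len(ncol(enc_values(enc)))
  if (!is.null(p_c) && preselection == "full") {
    ip <- independent_snp_pvalues(enc, labels)
    keep_full <- which(ip$p < p_c)
    if (length(keep_full) == 0L) stop("p_c removed every SNP")
    score_label <- "pAUC"
  }
  fold <- stratified_folds(labels, folds, seed)
  scores <- matrix(NA_real_, length(labels), length(grid))
  snp_counts <- numeric(folds)
  for (k in seq_len(folds)) {
    tr <- which(fold != k); te <- which(fold == k)
    keep <- keep_full
    if (!is.null(p_c) && preselection == "fold") {
      ip <- independent_snp_pvalues(subset_enc(enc, rows = tr), labels[tr])
      keep <- which(ip$p < p_c)
      if (length(keep) == 0L)
        keep <- which.min(ip$p)   # retain at least the top SNP
    }
    snp_counts[k] <- length(keep)
    enc_tr <- subset_enc(enc, rows = tr, cols = keep)
    enc_te <- subset_enc(enc, rows = te, cols = keep)
    for (gi in seq_along(grid)) {
      rm_ <- fit_one_method(enc_tr, labels[tr], method, grid[gi], model)
      scores[te, gi] <- predict_risk(rm_, enc_te)
    }
  }
  res <- data.frame(penalizer = grid, auc = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_)
  for (gi in seq_along(grid)) {
    a <- auc_mw(scores[, gi], labels)
    res$auc[gi] <- a$estimate
    res$ci_low[gi] <- a$ci[1L]; res$ci_high[gi] <- a$ci[2L]
  }
  best_auc <- max(res$auc)
  cand <- which(res$auc >= best_auc - 1e-12)
  # ties broken toward the more regularized model
  best <- if (method == "MF") min(grid[cand]) else max(grid[cand])
  structure(list(results = res, best_penalizer = best, best_auc = best_auc,
                 mean_snp_count = mean(snp_counts), fold_assignments = fold,
                 score_label = score_label, method = method, model = model,
                 seed = seed),
            class = "dda_cv")
}

#' @export
print.dda_cv <- function(x, ...) {
  cat("dda_cv:", x$method, "method;", x$score_label, "over",
      nrow(x$results), "grid points\n")
  cat("  best penalizer:", signif(x$best_penalizer, 4), " best",
      x$score_label, ":", signif(x$best_auc, 4),
      " mean SNPs/fold:", signif(x$mean_snp_count, 4), "\n")
  invisible(x)
}

#' Write a cross-validation report as TSV
#' @param cv a `dda_cv` object.
#' @param path output path.
#' @export
write_cv_report <- function(cv, path) {
  out <- cv$results
  out$mean_snp_count <- cv$mean_snp_count
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
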