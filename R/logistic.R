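# Penalized multivariate logistic regression with all pairwise interactions
# (the comparison baseline), and per-pair marginal epistasis tests.

logistic_nll <- function(par, Phi1, y, n, lambda, penmask) {
  eta <- drop(Phi1 %*% par)
  # -sum[y*eta - log(1+e^eta)] + n*lambda/2 * sum(penalized^2)
  nll <- -sum(y * eta - log1p(exp(pmin(eta, 30))) - pmax(eta - 30, 0)) +
    n * lambda / 2 * sum(penmask * par^2)
  mu <- plogis(eta)
  gr <- drop(crossprod(Phi1, mu - y)) + n * lambda * (penmask * par)
  list(nll = nll, gr = gr)
}

#' Penalized logistic regression with all pairwise interactions
#'
#' Maximizes the logistic log-likelihood over the intercept, per-SNP effects
#' and all pairwise interaction effects jointly, with an l2 penalty on the
#' interaction terms only (intercept and marginal effects unpenalized).
#'
#' @param enc encoded genotypes (`dda_encoded` or matrix).
#' @param labels phenotype vector (0/1).
#' @param lambda l2 penalizer on interaction coefficients.
#' @param model encoding label when `enc` is a plain matrix.
#' @param maxit optimizer iteration cap.
#' @return a [dda_risk] object with `source = "logistic"`; attributes
#'   `converged` and `loglik` (the penalized objective).
#' @export
fit_logistic <- function(enc, labels, lambda = 0.01, model = NULL,
                         maxit = 1000L) {
  V <- enc_values(enc)
  model <- if (is.null(model)) enc_model(enc) else model
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  L <- enc_levels(model)
  lay <- theta_layout(ncol(V), L)
  X <- expand_indicators(V, L)
  Phi1 <- cbind(1, feature_matrix(X, lay))
  n <- nrow(V)
  penmask <- c(0, rep(0, lay$d), rep(1, lay$p - lay$d))
  start <- c(qlogis(mean(labels)), numeric(lay$p))
  opt <- optim(start,
               function(p) logistic_nll(p, Phi1, labels, n, lambda, penmask)$nll,
               function(p) logistic_nll(p, Phi1, labels, n, lambda, penmask)$gr,
               method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-12))
  if (opt$convergence != 0 && lambda <= 0)
    warning("logistic fit did not converge at lambda = 0 (possible separation)")
  up <- unpack_theta(opt$par[-1L], lay)
  out <- dda_risk(opt$par[1L], up$H, up$Jbig,
                  prevalence = mean(labels), model = model,
                  source = "logistic")
  attr(out, "converged") <- opt$convergence == 0
  attr(out, "loglik") <- -opt$value
  out
}

pair_lr_test <- function(x1, x2, y, genotypic) {
  if (length(unique(x1)) < 2L || length(unique(x2)) < 2L) {
    return(list(estimate = NA_real_, statistic = NA_real_, p = 1,
                marginal = c(NA_real_, NA_real_), df = NA_integer_,
                degenerate = TRUE))
  }
  if (genotypic) {
    f1 <- factor(x1, levels = 0:2); f2 <- factor(x2, levels = 0:2)
    f1 <- droplevels(f1); f2 <- droplevels(f2)
    full <- glm(y ~ f1 * f2, family = binomial())
    red <- glm(y ~ f1 + f2, family = binomial())
    est_names <- grep(":", names(coef(full)), value = TRUE)
    est <- suppressWarnings(max(abs(coef(full)[est_names]), na.rm = TRUE))
    marg <- c(coef(red)[2L], coef(red)[nlevels(f1) + 1L])
  } else {
    full <- glm(y ~ x1 * x2, family = binomial())
    red <- glm(y ~ x1 + x2, family = binomial())
    est <- unname(coef(full)["x1:x2"])
    marg <- unname(coef(full)[c("x1", "x2")])
  }
  stat <- as.numeric(red$deviance - full$deviance)
  df <- red$df.residual - full$df.residual
  if (is.na(stat) || df <= 0)
    return(list(estimate = est, statistic = NA_real_, p = 1, marginal = marg,
                df = df, degenerate = TRUE))
  list(estimate = est, statistic = max(stat, 0),
       p = pchisq(max(stat, 0), df = df, lower.tail = FALSE),
       marginal = marg, df = df, degenerate = FALSE)
}

#' Marginal pairwise epistasis tests
#'
#' For every SNP pair, fits a logistic model with the two marginal terms plus
#' their product (factor interaction under the genotypic encoding) and tests
#' the interaction by a likelihood-ratio test (1 d.f. binary, up to 4 d.f.
#' genotypic). No multiple-testing correction is applied.
#'
#' @param enc encoded genotypes.
#' @param labels phenotype vector (0/1).
#' @param model encoding label when `enc` is a plain matrix.
#' @return data frame of class `dda_pairwise` with columns `snp1`, `snp2`,
#'   `estimate` (interaction log odds ratio), `statistic`, `df`, `p`,
#'   `degenerate`.
#' @export
pairwise_epistasis <- function(enc, labels, model = NULL) {
  V <- enc_values(enc)
  model <- if (is.null(model)) enc_model(enc) else model
  if (ncol(V) < 2L) stop("pairwise tests require m >= 2")
  genotypic <- model == "genotypic"
  y <- as.integer(labels)
  pairs <- t(utils::combn(ncol(V), 2L))
  snp <- if (inherits(enc, "dda_encoded")) enc$snp else paste0("snp", seq_len(ncol(V)))
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    r <- pair_lr_test(V[, i], V[, j], y, genotypic)
    data.frame(snp1 = snp[i], snp2 = snp[j], i = i, j = j,
               estimate = r$estimate, statistic = r$statistic,
               df = if (is.null(r$df) || is.na(r$df)) NA_integer_ else as.integer(r$df),
               p = r$p, degenerate = r$degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dda_pairwise", "data.frame")
  out
}

#' Write pairwise epistasis results as TSV
#' @param pw a `dda_pairwise` data frame.
#' @param path output path.
#' @export
write_pairwise_report <- function(pw, path) {
  write.table(pw[, c("snp1", "snp2", "estimate", "statistic", "p")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Risk-model estimate from marginal tests
#'
#' Assembles the risk parameters the way separate marginal analyses would:
#' per-SNP effects from single-SNP log odds ratios (the analytic
#' independent-SNP solution) and interaction effects from the per-pair
#' product-term log odds ratios of [pairwise_epistasis()].
#'
#' @param enc encoded genotypes (binary encoding).
#' @param labels phenotype vector (0/1).
#' @return a [dda_risk] object with `source = "pairwise"`.
#' @export
pairwise_theta <- function(enc, labels) {
  V <- enc_values(enc)
  model <- enc_model(enc)
  if (enc_levels(model) != 1L)
    stop("pairwise_theta supports binary encodings")
  ind <- fit_independent(enc, labels, model)
  beta <- ind$psi1$H - ind$psi0$H
  pw <- pairwise_epistasis(enc, labels, model)
  d <- ncol(V)
  gamma <- matrix(0, d, d)
  for (k in seq_len(nrow(pw))) {
    if (!is.na(pw$estimate[k])) {
      gamma[pw$i[k], pw$j[k]] <- pw$estimate[k]
      gamma[pw$j[k], pw$i[k]] <- pw$estimate[k]
    }
  }
  p1 <- mean(labels == 1)
  dda_risk(qlogis(p1), beta, gamma, prevalence = p1, model = model,
           source = "pairwise")
}
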