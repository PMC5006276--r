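# Fitting the per-group genotype distributions.
#
# All methods maximize (a surrogate of) the penalized total log-likelihood
#   L_y = sum_k ln Pr(a^k | y) - n_y * (lambda/2) * sum_{i<j} J_ij^2,
# the l2 penalty acting on couplings only, never on fields.

group_rows <- function(labels, group) {
  switch(group,
         control = which(labels == 0),
         case = which(labels == 1),
         pooled = seq_along(labels),
         stop("unknown group: ", group))
}

# sufficient statistics of one group's encoded rows against the cached
# state table: list(tab, counts, t, n)
ee_suffstats <- function(V, model) {
  L <- enc_levels(model)
  tab <- state_table(ncol(V), L)
  idx <- state_index(V, L)
  counts <- tabulate(idx, nbins = nrow(tab$states))
  list(tab = tab, counts = counts,
       t = drop(crossprod(tab$Phi, counts)), n = nrow(V))
}

#' Penalized log-likelihood of a genotype distribution model
#'
#' Evaluates the total penalized log-likelihood of one group's encoded
#' genotype rows under the given model parameters, using exact enumeration
#' for the partition function. The penalty applies to the couplings only.
#'
#' @param psi a [dda_params] object.
#' @param enc encoded rows of one group (matrix or `dda_encoded`).
#' @param lambda l2 penalizer on the couplings.
#' @return scalar total penalized log-likelihood.
#' @export
penalized_loglik <- function(psi, enc, lambda = 0) {
  V <- enc_values(enc)
  if (ncol(V) != psi$m) stop("SNP count mismatch between model and data")
  ss <- ee_suffstats(V, psi$model)
  theta <- as_theta(psi)
  E <- drop(ss$tab$Phi %*% theta)
  sum(ss$t * theta) - ss$n * lse(E) -
    ss$n * lambda / 2 * sum(params_Jfree(psi)^2)
}

# frequencies per expanded coordinate with 0.5 pseudo-count per genotype cell
# applied to SNPs with a boundary frequency; returns list(f, cells, adjusted)
level_freq <- function(V, L, pseudo = TRUE) {
  n <- nrow(V); m <- ncol(V)
  cells <- matrix(0, m, L + 1L)   # counts of levels 0..L per SNP
  for (g in 0:L) cells[, g + 1L] <- colSums(V == g)
  adj <- rep(FALSE, m)
  if (pseudo) {
    adj <- apply(cells, 1L, function(cc) any(cc == 0))
    cells[adj, ] <- cells[adj, , drop = FALSE] + 0.5
  }
  tot <- rowSums(cells)
  fmat <- cells / tot              # m x (L+1) level frequencies
  f <- as.numeric(t(fmat[, -1L, drop = FALSE]))  # expanded coords
  list(f = f, f0 = fmat[, 1L], adjusted = adj, cells = cells)
}

independent_params <- function(V, L, model, group) {
  lf <- level_freq(V, L)
  if (any(lf$adjusted))
    message(sum(lf$adjusted),
            " SNP(s) at a boundary frequency; 0.5 pseudo-count applied")
  H <- log(lf$f / rep(lf$f0, each = L))
  m <- ncol(V)
  # factorized log partition: sum_i ln(1 + sum_g e^{h_ig})
  hm <- matrix(H, m, L, byrow = TRUE)
  lz <- sum(log(1 + rowSums(exp(hm))))
  p <- dda_params(hm, NULL, model = model, group = group, log_partition = lz)
  attr(p, "pseudo_count") <- lf$adjusted
  p
}

independent_loglik <- function(psi, V) {
  # J = 0: the likelihood factorizes over SNPs
  lf <- level_freq(V, psi$L, pseudo = FALSE)
  n <- nrow(V)
  hm <- params_h(psi)
  lz_i <- log(1 + rowSums(exp(hm)))
  sum(n * lf$f * psi$H) - n * sum(lz_i)
}

#' Analytic independent-SNP fit
#'
#' With interactions turned off the maximum-likelihood solution is available
#' in closed form from the group level frequencies: for binary encodings
#' `h_i = ln(f_i / (1 - f_i))`; for the genotypic encoding
#' `h_i(g) = ln(f_i(g) / f_i(0))`. Boundary frequencies receive a 0.5
#' pseudo-count per genotype cell so fields stay finite.
#'
#' @param enc encoded genotypes (`dda_encoded` or matrix).
#' @param labels phenotype vector (0/1).
#' @param model encoding label when `enc` is a plain matrix.
#' @return a `dda_fit` object (see [dda_fit()]) with `method = "independent"`.
#' @export
fit_independent <- function(enc, labels, model = NULL) {
  V <- enc_values(enc)
  model <- if (is.null(model)) enc_model(enc) else model
  L <- enc_levels(model)
  fits <- lapply(c("control", "case", "pooled"), function(g) {
    independent_params(V[group_rows(labels, g), , drop = FALSE], L, model, g)
  })
  logliks <- vapply(seq_along(fits), function(k) {
    g <- c("control", "case", "pooled")[k]
    independent_loglik(fits[[k]], V[group_rows(labels, g), , drop = FALSE])
  }, numeric(1))
  new_dda_fit(fits[[1L]], fits[[2L]], fits[[3L]], logliks, "independent",
              NA_real_, TRUE, 0L, labels = labels, enc = enc, model = model)
}

#' Power of the independent-SNP likelihood-ratio test
#'
#' Asymptotic power for detecting a carrier-frequency difference between
#' case and control groups with a 1-d.f. likelihood-ratio test, using the
#' noncentral chi-square distribution with noncentrality equal to the
#' expected LR statistic at the true frequencies.
#'
#' @param f0,f1 true control and case carrier frequencies (in (0, 1)).
#' @param n total sample size (split equally between groups).
#' @param alpha_level significance level.
#' @return the power (a fraction).
#' @export
power_independent <- function(f0, f1, n, alpha_level = 0.05) {
  stopifnot(f0 > 0, f0 < 1, f1 > 0, f1 < 1)
  if (alpha_level <= 0 || alpha_level >= 1)
    stop("alpha_level must lie in (0, 1)")
  n0 <- n / 2; n1 <- n / 2
  fbar <- (n0 * f0 + n1 * f1) / n
  kl <- function(f, g) f * log(f / g) + (1 - f) * log((1 - f) / (1 - g))
  ncp <- 2 * (n0 * kl(f0, fbar) + n1 * kl(f1, fbar))
  crit <- qchisq(1 - alpha_level, df = 1)
  pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}

#' Exact-enumeration fit of one group
#'
#' Maximizes the penalized log-likelihood exactly by Newton iteration on the
#' enumerated genotype distribution (gradient of the log-partition function
#' equals the model moments). Feasible for small SNP panels only.
#'
#' @param enc encoded genotypes.
#' @param labels phenotype vector (0/1).
#' @param lambda l2 penalizer on couplings.
#' @param group `"control"`, `"case"` or `"pooled"`.
#' @param model encoding label when `enc` is a plain matrix.
#' @param theta0 optional start vector (warm start).
#' @param tol gradient tolerance per individual.
#' @param maxit iteration cap.
#' @return a [dda_params] object; attributes `loglik` (penalized objective),
#'   `converged`, `iterations`.
#' @export
fit_ee <- function(enc, labels = NULL, lambda = 0.01,
                   group = c("pooled", "control", "case"), model = NULL,
                   theta0 = NULL, tol = 1e-6, maxit = 500L) {
  group <- match.arg(group)
  V <- enc_values(enc)
  model <- if (is.null(model)) enc_model(enc) else model
  if (!is.null(labels)) V <- V[group_rows(labels, group), , drop = FALSE]
  ss <- ee_suffstats(V, model)
  lay <- ss$tab$layout
  if (is.null(theta0)) theta0 <- numeric(lay$p)
  res <- ee_newton_cpp(ss$tab$Phi, ss$t, ss$n, lambda, pen_mask(lay),
                       theta0, seq_len(lay$p) - 1L, tol, as.integer(maxit))
  if (!res$converged)
    warning("EE fit did not reach tolerance (max gradient ",
            signif(res$grad_max, 3), "); partial result returned")
  p <- params_from_theta(res$theta, lay, model, group,
                         log_partition = res$logZ)
  attr(p, "loglik") <- -res$nll
  attr(p, "converged") <- res$converged
  attr(p, "iterations") <- res$iterations
  p
}

# ---- pseudo-likelihood ----

# negative conditional log-likelihood + gradient of site i's multinomial
# problem. par = c(h_i (L), J rows: for each level g, coefficients over the
# other sites' expanded coordinates (d_other), level-major).
pl_site_obj <- function(par, yi, Xo, w, L, lambda, n, fixed_idx = NULL,
                        fixed_val = NULL) {
  if (!is.null(fixed_idx)) par[fixed_idx] <- fixed_val
  d_o <- ncol(Xo)
  h <- par[seq_len(L)]
  Jm <- matrix(par[-seq_len(L)], nrow = d_o, ncol = L)  # column g = level g
  Eg <- sweep(Xo %*% Jm, 2L, h, "+")                    # K x L energies
  M <- pmax(apply(Eg, 1L, max), 0)
  lsum <- M + log(exp(-M) + rowSums(exp(Eg - M)))       # log(1 + sum_g e^Eg)
  pick <- numeric(length(yi))
  sel <- yi > 0L
  pick[sel] <- Eg[cbind(which(sel), yi[sel])]
  nll <- -sum(w * (pick - lsum)) + n * lambda / 2 * sum(Jm^2)
  P <- exp(Eg - lsum)                                   # K x L probabilities
  Yind <- matrix(0, length(yi), L)
  if (any(sel)) Yind[cbind(which(sel), yi[sel])] <- 1
  R <- (P - Yind) * w
  gh <- colSums(R)
  gJ <- crossprod(Xo, R) + n * lambda * Jm
  gr <- c(gh, as.numeric(gJ))
  if (!is.null(fixed_idx)) gr[fixed_idx] <- 0
  list(nll = nll, gr = gr)
}

pl_fit_site <- function(i, Vw, w, L, lambda, n, start = NULL,
                        fixed_idx = NULL, fixed_val = NULL, maxit = 500L) {
  m <- ncol(Vw)
  yi <- as.integer(Vw[, i])
  Xo <- expand_indicators(Vw[, -i, drop = FALSE], L)
  npar <- L + ncol(Xo) * L
  if (is.null(start)) start <- numeric(npar)
  opt <- optim(start,
               function(p) pl_site_obj(p, yi, Xo, w, L, lambda, n,
                                       fixed_idx, fixed_val)$nll,
               function(p) pl_site_obj(p, yi, Xo, w, L, lambda, n,
                                       fixed_idx, fixed_val)$gr,
               method = "BFGS", control = list(maxit = maxit, reltol = 1e-12))
  par <- opt$par
  if (!is.null(fixed_idx)) par[fixed_idx] <- fixed_val
  list(par = par, value = opt$value, converged = opt$convergence == 0)
}

# assemble symmetrized params from per-site solutions; site_fits is a list of
# length m with elements $par laid out as in pl_site_obj
pl_assemble <- function(site_fits, m, L, model, group) {
  d <- m * L
  H <- numeric(d)
  Jraw <- matrix(0, d, d)      # row block i = site-i estimate of J_i.
  for (i in seq_len(m)) {
    par <- site_fits[[i]]$par
    H[(i - 1L) * L + seq_len(L)] <- par[seq_len(L)]
    other <- setdiff(seq_len(m), i)
    oc <- as.integer(t(outer((other - 1L) * L, seq_len(L), "+")))  # expanded cols of others
    Jm <- matrix(par[-seq_len(L)], nrow = (m - 1L) * L, ncol = L)
    for (g in seq_len(L)) {
      Jraw[(i - 1L) * L + g, oc] <- Jm[, g]
    }
  }
  Jsym <- (Jraw + t(Jraw)) / 2
  dda_params(matrix(H, m, L, byrow = TRUE), Jsym, model = model, group = group)
}

collapse_rows <- function(V) {
  key <- apply(V, 1L, paste, collapse = ",")
  ux <- !duplicated(key)
  Vw <- V[ux, , drop = FALSE]
  w <- as.numeric(table(factor(key, levels = key[ux])))
  list(V = Vw, w = w)
}

#' Pseudo-likelihood fit of one group
#'
#' Maximizes the penalized sum of per-site conditional log-likelihoods (a
#' logistic problem per SNP for binary encodings, multinomial for genotypic),
#' then symmetrizes the couplings by averaging the two per-site estimates of
#' each pair. Site problems are independent and dispatched through `map_fun`.
#'
#' @inheritParams fit_ee
#' @param map_fun a `lapply`-compatible function used to run the per-site
#'   problems (e.g. `parallel::mclapply`); results are independent of
#'   execution order.
#' @return a [dda_params] object; attributes `loglik` (total penalized
#'   pseudo-log-likelihood), `converged`, `iterations`.
#' @export
fit_pl <- function(enc, labels = NULL, lambda = 0.01,
                   group = c("pooled", "control", "case"), model = NULL,
                   map_fun = lapply, maxit = 500L) {
  group <- match.arg(group)
  V <- enc_values(enc)
  model <- if (is.null(model)) enc_model(enc) else model
  if (ncol(V) < 2L) stop("pseudo-likelihood requires m >= 2")
  if (!is.null(labels)) V <- V[group_rows(labels, group), , drop = FALSE]
  L <- enc_levels(model)
  n <- nrow(V)
  cw <- collapse_rows(V)
  site_fits <- map_fun(seq_len(ncol(V)), function(i) {
    pl_fit_site(i, cw$V, cw$w, L, lambda, n, maxit = maxit)
  })
  conv <- all(vapply(site_fits, `[[`, logical(1), "converged"))
  if (!conv && lambda <= 0)
    warning("a per-site conditional problem did not converge at lambda = 0 ",
            "(possible separation)")
  psi <- pl_assemble(site_fits, ncol(V), L, model, group)
  site_values <- vapply(site_fits, `[[`, numeric(1), "value")
  # penalized pseudo-log-likelihood: sum of the decoupled per-site optima
  attr(psi, "loglik") <- -sum(site_values)
  attr(psi, "site_values") <- site_values
  attr(psi, "converged") <- conv
  attr(psi, "iterations") <- NA_integer_
  attr(psi, "site_fits") <- site_fits
  psi
}

# ---- mean field ----

mf_log_partition <- function(H, Jbig, f, L) {
  m <- length(H) / L
  fm <- matrix(f, m, L, byrow = TRUE)
  f0 <- 1 - rowSums(fm)
  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  entropy <- -sum(xlx(fm)) - sum(xlx(f0))
  entropy + sum(H * f) + sum(Jbig * outer(f, f)) / 2
}

#' Mean-field fit of one group
#'
#' Closed-form coupling estimate by inversion of the regularized connected
#' covariance matrix: between-SNP covariance entries are shrunk linearly by
#' `epsilon` (0 = independent-SNP limit, 1 = full interactions), the
#' couplings are minus the off-diagonal blocks of the inverse, and the fields
#' follow from the mean-field self-consistency relation. The log-partition
#' value is the mean-field (variational) free energy.
#'
#' @inheritParams fit_ee
#' @param epsilon shrinkage of between-SNP covariances, in `[0, 1]`.
#' @return a [dda_params] object; attributes `loglik` (mean-field
#'   log-likelihood), `converged` (always `TRUE`), `iterations` (0).
#' @export
fit_mf <- function(enc, labels = NULL, epsilon = 0.5,
                   group = c("pooled", "control", "case"), model = NULL) {
  group <- match.arg(group)
  if (epsilon < 0 || epsilon > 1) stop("epsilon must lie in [0, 1]")
  V <- enc_values(enc)
  model <- if (is.null(model)) enc_model(enc) else model
  if (!is.null(labels)) V <- V[group_rows(labels, group), , drop = FALSE]
  L <- enc_levels(model)
  m <- ncol(V); d <- m * L; n <- nrow(V)
  lf <- level_freq(V, L)           # pseudo-counted at boundaries
  f <- lf$f
  X <- expand_indicators(V, L)
  C <- crossprod(X) / n - tcrossprod(colMeans(X))
  snp_of <- rep(seq_len(m), each = L)
  between <- outer(snp_of, snp_of, "!=")
  Ce <- C
  Ce[between] <- epsilon * C[between]
  # replace within-SNP blocks by their pseudo-counted multinomial covariance
  for (i in seq_len(m)) {
    idx <- (i - 1L) * L + seq_len(L)
    fi <- f[idx]
    Ce[idx, idx] <- diag(fi, nrow = L) - tcrossprod(fi)
  }
  Cinv <- tryCatch(solve(Ce), error = function(e) NULL)
  if (is.null(Cinv)) {
    message("singular shrunk covariance; adding diagonal jitter 1e-8")
    Cinv <- tryCatch(solve(Ce + diag(1e-8, d)), error = function(e)
      stop("shrunk covariance matrix is numerically singular"))
  }
  Jbig <- -Cinv
  Jbig[!between] <- 0
  fm <- matrix(f, m, L, byrow = TRUE)
  f0 <- 1 - rowSums(fm)
  H <- log(f / rep(f0, each = L)) - drop(Jbig %*% f)
  psi <- dda_params(matrix(H, m, L, byrow = TRUE), Jbig, model = model,
                    group = group)
  lz <- mf_log_partition(psi$H, psi$Jbig, f, L)
  psi$log_partition <- lz
  # mean-field likelihood: sum_k E(x_k) - n * lnZ_mf
  fdat <- colMeans(X)
  F2 <- crossprod(X) / n
  attr(psi, "loglik") <- n * (sum(psi$H * fdat) + sum(psi$Jbig * F2) / 2) - n * lz
  attr(psi, "converged") <- TRUE
  attr(psi, "iterations") <- 0L
  psi
}

# ---- combined fit ----

new_dda_fit <- function(psi0, psi1, psi_pooled, logliks, method, penalizer,
                        converged, iterations, labels, enc, model) {
  structure(list(psi0 = psi0, psi1 = psi1, psi_pooled = psi_pooled,
                 loglik0 = logliks[1L], loglik1 = logliks[2L],
                 loglik_pooled = logliks[3L], method = method,
                 penalizer = penalizer, converged = converged,
                 iterations = iterations,
                 n0 = sum(labels == 0), n1 = sum(labels == 1),
                 labels = labels, enc = enc, model = model),
            class = "dda_fit")
}

#' @export
print.dda_fit <- function(x, ...) {
  cat("dda_fit:", x$method, "method,", x$model, "model,",
      x$psi0$m, "SNPs,", x$n0, "controls /", x$n1, "cases\n")
  cat("  penalizer:", x$penalizer, " logliks (0/1/pooled):",
      signif(c(x$loglik0, x$loglik1, x$loglik_pooled), 6), "\n")
  invisible(x)
}

#' Fit case, control, and pooled genotype distributions
#'
#' Runs the chosen inference method on the control group, the case group,
#' and the concatenated (pooled) sample at a common penalizer, returning
#' everything needed for risk conversion and likelihood-ratio tests.
#'
#' @param enc encoded genotypes (`dda_encoded` or matrix).
#' @param labels phenotype vector (0/1).
#' @param method `"EE"`, `"PL"`, `"MF"` or `"independent"`.
#' @param penalizer `lambda` for EE/PL, `epsilon` for MF; ignored for the
#'   independent fit.
#' @param model encoding label when `enc` is a plain matrix.
#' @param ... passed to the per-group fitting routine.
#' @return an object of class `dda_fit` with fields `psi0`, `psi1`,
#'   `psi_pooled`, the three penalized objective values, `method`,
#'   `penalizer`, `converged`, `iterations`.
#' @export
dda_fit <- function(enc, labels, method = c("EE", "PL", "MF", "independent"),
                    penalizer = 0.01, model = NULL, ...) {
  method <- match.arg(method)
  model <- if (is.null(model)) enc_model(enc) else model
  if (method == "independent") return(fit_independent(enc, labels, model))
  fitter <- switch(method, EE = fit_ee, PL = fit_pl, MF = fit_mf)
  groups <- c("control", "case", "pooled")
  fits <- lapply(groups, function(g) {
    if (method == "MF") fitter(enc, labels, epsilon = penalizer, group = g,
                               model = model, ...)
    else fitter(enc, labels, lambda = penalizer, group = g, model = model, ...)
  })
  logliks <- vapply(fits, function(p) attr(p, "loglik"), numeric(1))
  conv <- all(vapply(fits, function(p) isTRUE(attr(p, "converged")), logical(1)))
  iters <- suppressWarnings(max(vapply(fits, function(p) {
    it <- attr(p, "iterations"); if (is.null(it) || is.na(it)) 0L else it
  }, integer(1))))
  new_dda_fit(fits[[1L]], fits[[2L]], fits[[3L]], logliks, method, penalizer,
              conv, iters, labels = labels, enc = enc, model = model)
}
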