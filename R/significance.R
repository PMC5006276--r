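# Likelihood-ratio statistics with chi-square asymptotics for single-SNP
# terms and permutation-resampled empirical nulls for interactions.
#
# The restricted (null) model pins the tested parameters of case and control
# groups to their pooled-fit values at the same penalizer and re-optimizes
# every remaining free parameter; q = 2 * [(L1 + L0)_full - (L1 + L0)_restricted].

# theta coordinate indices of site i's fields / pair (i,j)'s couplings
site_theta_idx <- function(layout, i) (i - 1L) * layout$L + seq_len(layout$L)
pair_theta_idx <- function(layout, i, j) {
  if (i > j) { tmp <- i; i <- j; j <- tmp }
  pr <- which(layout$pairs[, 1L] == i & layout$pairs[, 2L] == j)
  if (length(pr) != 1L) stop("pair index out of range")
  layout$d + (pr - 1L) * layout$L^2 + seq_len(layout$L^2)
}

# per-site parameter indices of the couplings J_{i, j} inside site i's
# pseudo-likelihood parameter vector
pl_site_J_idx <- function(m, L, i, j) {
  other <- setdiff(seq_len(m), i)
  pos <- match(j, other)
  d_o <- (m - 1L) * L
  idx <- integer(0)
  for (gi in seq_len(L)) for (gj in seq_len(L))
    idx <- c(idx, L + (gi - 1L) * d_o + (pos - 1L) * L + gj)
  idx
}

# pooled-fit values for those coordinates, matching pl_site_J_idx order
pl_pool_J_val <- function(pooled, i, j) {
  L <- pooled$L
  v <- numeric(0)
  for (gi in seq_len(L)) for (gj in seq_len(L))
    v <- c(v, pooled$Jbig[(i - 1L) * L + gi, (j - 1L) * L + gj])
  v
}

ee_group_loglik_restricted <- function(fit, group, pin_idx, pin_val) {
  V <- enc_values(fit$enc)
  rows <- group_rows(fit$labels, group)
  ss <- ee_suffstats(V[rows, , drop = FALSE], fit$model)
  lay <- ss$tab$layout
  psi <- if (group == "control") fit$psi0 else if (group == "case") fit$psi1 else fit$psi_pooled
  theta0 <- as_theta(psi)
  theta0[pin_idx] <- pin_val
  free <- setdiff(seq_len(lay$p), pin_idx)
  if (length(free) == 0L) {
    # fully pinned model: evaluate the penalized objective directly
    E <- drop(ss$tab$Phi %*% theta0)
    pen <- fit$penalizer / 2 * sum((pen_mask(lay) * theta0)^2)
    return(sum(ss$t * theta0) - ss$n * lse(E) - ss$n * pen)
  }
  res <- ee_newton_cpp(ss$tab$Phi, ss$t, ss$n, fit$penalizer, pen_mask(lay),
                       theta0, free - 1L, 1e-6, 500L)
  if (!res$converged)
    warning("restricted EE fit did not reach tolerance")
  -res$nll
}

pl_group_loglik <- function(psi) -sum(attr(psi, "site_values"))

pl_group_loglik_restricted <- function(fit, group, sites, fixed) {
  # sites: integer vector of per-site problems to refit;
  # fixed: list parallel to sites with (idx, val) inside each site's par
  V <- enc_values(fit$enc)
  rows <- group_rows(fit$labels, group)
  Vg <- V[rows, , drop = FALSE]
  L <- enc_levels(fit$model)
  cw <- collapse_rows(Vg)
  psi <- if (group == "control") fit$psi0 else fit$psi1
  sf <- attr(psi, "site_fits")
  vals <- vapply(sf, `[[`, numeric(1), "value")
  for (k in seq_along(sites)) {
    i <- sites[k]
    r <- pl_fit_site(i, cw$V, cw$w, L, fit$penalizer, nrow(Vg),
                     start = sf[[i]]$par, fixed_idx = fixed[[k]]$idx,
                     fixed_val = fixed[[k]]$val)
    vals[i] <- r$value
  }
  -sum(vals)
}

mf_eval_loglik <- function(H, Jbig, fdat, F2, f_model, L, n) {
  lz <- mf_log_partition(H, Jbig, f_model, L)
  n * (sum(H * fdat) + sum(Jbig * F2) / 2) - n * lz
}

mf_group_loglik_restricted <- function(fit, group, pin) {
  V <- enc_values(fit$enc)
  rows <- group_rows(fit$labels, group)
  Vg <- V[rows, , drop = FALSE]
  psi <- if (group == "control") fit$psi0 else fit$psi1
  pooled <- fit$psi_pooled
  L <- psi$L; m <- psi$m
  X <- expand_indicators(Vg, L)
  fdat <- colMeans(X); F2 <- crossprod(X) / nrow(Vg)
  lf <- level_freq(Vg, L)
  H <- psi$H; Jbig <- psi$Jbig
  if (pin$type == "site") {
    idx <- site_theta_idx(theta_layout(m, L), pin$i)
    H[idx] <- pooled$H[idx]
  } else {
    i <- pin$i; j <- pin$j
    ri <- (i - 1L) * L + seq_len(L); rj <- (j - 1L) * L + seq_len(L)
    Jbig[ri, rj] <- pooled$Jbig[ri, rj]
    Jbig[rj, ri] <- pooled$Jbig[rj, ri]
    # re-derive the affected fields from the mean-field self-consistency
    fm <- matrix(lf$f, m, L, byrow = TRUE)
    f0 <- 1 - rowSums(fm)
    for (s in c(i, j)) {
      rs <- (s - 1L) * L + seq_len(L)
      H[rs] <- log(lf$f[rs] / f0[s]) - drop(Jbig[rs, , drop = FALSE] %*% lf$f)
    }
  }
  mf_eval_loglik(H, Jbig, fdat, F2, lf$f, L, nrow(Vg))
}

ind_group_loglik_restricted <- function(fit, group, pin) {
  psi <- if (group == "control") fit$psi0 else fit$psi1
  pooled <- fit$psi_pooled
  V <- enc_values(fit$enc)
  rows <- group_rows(fit$labels, group)
  Vg <- V[rows, , drop = FALSE]
  base <- if (group == "control") fit$loglik0 else fit$loglik1
  if (pin$type == "pair") return(base)   # couplings are identically zero
  L <- psi$L; n <- nrow(Vg)
  idx <- site_theta_idx(theta_layout(psi$m, L), pin$i)
  fi <- colMeans(expand_indicators(Vg[, pin$i, drop = FALSE], L))
  contrib <- function(h) n * (sum(fi * h) - log(1 + sum(exp(h))))
  base - contrib(psi$H[idx]) + contrib(pooled$H[idx])
}

restricted_loglik <- function(fit, group, pin) {
  lay <- theta_layout(fit$psi0$m, fit$psi0$L)
  switch(fit$method,
    EE = {
      idx <- if (pin$type == "site") site_theta_idx(lay, pin$i)
             else pair_theta_idx(lay, pin$i, pin$j)
      ee_group_loglik_restricted(fit, group, idx, as_theta(fit$psi_pooled)[idx])
    },
    PL = {
      if (pin$type == "site") {
        pl_group_loglik_restricted(fit, group, pin$i,
          list(list(idx = seq_len(fit$psi0$L),
                    val = fit$psi_pooled$H[site_theta_idx(lay, pin$i)])))
      } else {
        m <- fit$psi0$m; L <- fit$psi0$L
        pl_group_loglik_restricted(fit, group, c(pin$i, pin$j), list(
          list(idx = pl_site_J_idx(m, L, pin$i, pin$j),
               val = pl_pool_J_val(fit$psi_pooled, pin$i, pin$j)),
          list(idx = pl_site_J_idx(m, L, pin$j, pin$i),
               val = pl_pool_J_val(fit$psi_pooled, pin$j, pin$i))))
      }
    },
    MF = mf_group_loglik_restricted(fit, group, pin),
    independent = ind_group_loglik_restricted(fit, group, pin),
    stop("unsupported method for restricted fits: ", fit$method))
}

full_group_logliks <- function(fit) {
  if (fit$method == "PL")
    c(pl_group_loglik(fit$psi0), pl_group_loglik(fit$psi1))
  else c(fit$loglik0, fit$loglik1)
}

#' Overall likelihood-ratio statistic
#'
#' Twice the difference between the sum of the case and control penalized
#' log-likelihoods and the pooled-sample value, clipped at zero.
#'
#' @param fit a `dda_fit` containing all three group fits at one penalizer.
#' @return scalar statistic `q`.
#' @export
lr_overall <- function(fit) {
  stopifnot(inherits(fit, "dda_fit"))
  if (is.null(fit$psi_pooled)) stop("fit lacks a pooled component")
  ll <- if (fit$method == "PL") {
    c(pl_group_loglik(fit$psi0), pl_group_loglik(fit$psi1),
      pl_group_loglik(fit$psi_pooled))
  } else c(fit$loglik0, fit$loglik1, fit$loglik_pooled)
  max(0, 2 * (ll[1L] + ll[2L] - ll[3L]))
}

#' Single-SNP likelihood-ratio test under collective inference
#'
#' Pins site `i`'s fields in both groups to their pooled-fit values,
#' re-optimizes all remaining parameters, and compares against the full fit.
#' The p-value uses the asymptotic chi-square distribution (1 d.f. binary,
#' 2 d.f. genotypic) and is an upper bound when a non-zero penalizer
#' suppresses the null distribution.
#'
#' @param fit a `dda_fit`.
#' @param site SNP index.
#' @return list with `q`, `df`, `p`.
#' @export
lr_single <- function(fit, site) {
  ll <- full_group_logliks(fit)
  l0r <- restricted_loglik(fit, "control", list(type = "site", i = site))
  l1r <- restricted_loglik(fit, "case", list(type = "site", i = site))
  q <- max(0, 2 * ((ll[1L] + ll[2L]) - (l0r + l1r)))
  df <- fit$psi0$L
  list(q = q, df = df, p = pchisq(q, df = df, lower.tail = FALSE))
}

#' Interaction likelihood-ratio statistic for one SNP pair
#'
#' Pins the pair's couplings in both groups to their pooled-fit values,
#' re-optimizes the rest, and returns the statistic. p-values for
#' interactions should come from the permutation null
#' ([permutation_null()]), not chi-square asymptotics.
#'
#' @param fit a `dda_fit`.
#' @param pair length-2 vector of SNP indices.
#' @return scalar statistic `q_ij`.
#' @export
lr_pair <- function(fit, pair) {
  ll <- full_group_logliks(fit)
  pin <- list(type = "pair", i = pair[1L], j = pair[2L])
  l0r <- restricted_loglik(fit, "control", pin)
  l1r <- restricted_loglik(fit, "case", pin)
  max(0, 2 * ((ll[1L] + ll[2L]) - (l0r + l1r)))
}

# fast exact-enumeration path: all-pair interaction statistics for one label
# assignment, reusing precomputed state structures
ee_all_pair_q <- function(pre, labels, lambda, tol = 1e-6) {
  lay <- pre$tab$layout
  pooled_theta <- pre$pooled_theta
  qs <- numeric(lay$npairs)
  lls <- numeric(2)
  thetas <- list()
  for (y in 0:1) {
    counts <- tabulate(pre$idx[labels == y], nbins = nrow(pre$tab$states))
    tvec <- drop(crossprod(pre$tab$Phi, counts))
    n_y <- sum(counts)
    res <- ee_newton_cpp(pre$tab$Phi, tvec, n_y, lambda, pre$penmask,
                         pre$warm[[y + 1L]], seq_len(lay$p) - 1L, tol, 500L)
    thetas[[y + 1L]] <- res$theta
    lls[y + 1L] <- -res$nll
    for (pr in seq_len(lay$npairs)) {
      pidx <- lay$d + (pr - 1L) * lay$L^2 + seq_len(lay$L^2)
      th0 <- res$theta
      th0[pidx] <- pooled_theta[pidx]
      rr <- ee_newton_cpp(pre$tab$Phi, tvec, n_y, lambda, pre$penmask,
                          th0, setdiff(seq_len(lay$p), pidx) - 1L, tol, 500L)
      qs[pr] <- qs[pr] + (lls[y + 1L] - (-rr$nll))
    }
  }
  list(q = pmax(0, 2 * qs), thetas = thetas, logliks = lls)
}

ee_pre <- function(V, labels, lambda, model) {
  L <- enc_levels(model)
  tab <- state_table(ncol(V), L)
  idx <- state_index(V, L)
  lay <- tab$layout
  counts <- tabulate(idx, nbins = nrow(tab$states))
  tvec <- drop(crossprod(tab$Phi, counts))
  pooled <- ee_newton_cpp(tab$Phi, tvec, length(idx), lambda, pen_mask(lay),
                          numeric(lay$p), seq_len(lay$p) - 1L, 1e-6, 500L)
  list(tab = tab, idx = idx, penmask = pen_mask(lay),
       pooled_theta = pooled$theta,
       warm = list(pooled$theta, pooled$theta))
}

#' Permutation-resampled null distributions of interaction statistics
#'
#' Reshuffles the phenotype labels (preserving group sizes), re-runs the
#' full inference and all-pair interaction statistics at the same penalizer,
#' and accumulates per-pair empirical null draws. The pooled fit is
#' label-invariant and computed once. Each permutation consumes its own
#' child random stream, so draws are independent of execution order and of
#' the total number of permutations requested.
#'
#' @param enc encoded genotypes.
#' @param labels observed phenotype vector (0/1).
#' @param method `"EE"`, `"PL"` or `"MF"`.
#' @param penalizer lambda (EE/PL) or epsilon (MF).
#' @param n_perm number of permutations (>= 19).
#' @param seed master seed.
#' @param model encoding label when `enc` is a plain matrix.
#' @param map_fun `lapply`-compatible dispatcher for the permutations.
#' @return object of class `dda_null`: `draws` (n_perm x npairs matrix),
#'   `pairs`, `n_perm`, `penalizer`, `method`, `failed` (count of skipped
#'   permutations).
#' @export
permutation_null <- function(enc, labels, method = c("EE", "PL", "MF"),
                             penalizer = 0.01, n_perm = 999L, seed = 1L,
                             model = NULL, map_fun = lapply) {
  method <- match.arg(method)
  if (n_perm < 19L) stop("n_perm must be at least 19")
  V <- enc_values(enc)
  model <- if (is.null(model)) enc_model(enc) else model
  lay <- theta_layout(ncol(V), enc_levels(model))
  seeds <- child_seeds(seed, n_perm)
  labels <- as.integer(labels)
  if (method == "EE") {
    pre <- ee_pre(V, labels, penalizer, model)
    run1 <- function(b) {
      set.seed(seeds[b])
      lb <- sample(labels)
      tryCatch(ee_all_pair_q(pre, lb, penalizer)$q,
               error = function(e) NULL)
    }
  } else {
    run1 <- function(b) {
      set.seed(seeds[b])
      lb <- sample(labels)
      tryCatch({
        f <- dda_fit(enc, lb, method = method, penalizer = penalizer,
                     model = model)
        vapply(seq_len(lay$npairs), function(pr)
          lr_pair(f, lay$pairs[pr, ]), numeric(1))
      }, error = function(e) NULL)
    }
  }
  out <- map_fun(seq_len(n_perm), run1)
  ok <- !vapply(out, is.null, logical(1))
  if (any(!ok))
    message(sum(!ok), " permutation(s) failed and were skipped")
  draws <- do.call(rbind, out[ok])
  structure(list(draws = draws, pairs = lay$pairs, n_perm = sum(ok),
                 penalizer = penalizer, method = method,
                 failed = sum(!ok), seed = seed),
            class = "dda_null")
}

#' Empirical p-values from a permutation null
#'
#' Add-one estimator `p = (1 + #\{q_null >= q_obs\}) / (1 + N)`, per pair by
#' default, or against the draws pooled across pairs.
#'
#' @param null_cdfs a `dda_null` object.
#' @param q_obs observed per-pair statistics (in the null's pair order).
#' @param pool if `TRUE`, compare each observation against all pairs' draws.
#' @return numeric vector of empirical p-values in (0, 1].
#' @export
empirical_pvalues <- function(null_cdfs, q_obs, pool = FALSE) {
  stopifnot(inherits(null_cdfs, "dda_null"))
  N <- null_cdfs$n_perm
  if (pool) {
    all_draws <- as.numeric(null_cdfs$draws)
    vapply(q_obs, function(q) (1 + sum(all_draws >= q)) / (1 + length(all_draws)),
           numeric(1))
  } else {
    vapply(seq_along(q_obs), function(k)
      (1 + sum(null_cdfs$draws[, k] >= q_obs[k])) / (1 + N), numeric(1))
  }
}

#' Full interaction significance test
#'
#' Computes observed all-pair interaction statistics and their empirical
#' p-values against a permutation null at the same penalizer, plus
#' single-SNP statistics with asymptotic chi-square p-values.
#'
#' @inheritParams permutation_null
#' @param snp_names optional SNP identifiers.
#' @return object of class `dda_lrt`: data frames `single` (snp, q, df, p)
#'   and `pairs` (snp1, snp2, q, p_emp, n_perm), the overall statistic
#'   `q_overall`, the `dda_null` object, and the penalizer.
#' @export
dda_interaction_test <- function(enc, labels, method = c("EE", "PL", "MF"),
                                 penalizer = 0.01, n_perm = 199L, seed = 1L,
                                 model = NULL, map_fun = lapply,
                                 snp_names = NULL) {
  method <- match.arg(method)
  model <- if (is.null(model)) enc_model(enc) else model
  fit <- dda_fit(enc, labels, method = method, penalizer = penalizer,
                 model = model)
  lay <- theta_layout(fit$psi0$m, fit$psi0$L)
  if (is.null(snp_names))
    snp_names <- if (inherits(enc, "dda_encoded")) enc$snp
                 else paste0("snp", seq_len(fit$psi0$m))
  sing <- lapply(seq_len(fit$psi0$m), function(i) lr_single(fit, i))
  single <- data.frame(snp = snp_names,
                       q = vapply(sing, `[[`, numeric(1), "q"),
                       df = vapply(sing, `[[`, numeric(1), "df"),
                       p = vapply(sing, `[[`, numeric(1), "p"),
                       stringsAsFactors = FALSE)
  q_obs <- vapply(seq_len(lay$npairs), function(pr)
    lr_pair(fit, lay$pairs[pr, ]), numeric(1))
  nulls <- permutation_null(enc, labels, method = method,
                            penalizer = penalizer, n_perm = n_perm,
                            seed = seed, model = model, map_fun = map_fun)
  pairs_df <- data.frame(snp1 = snp_names[lay$pairs[, 1L]],
                         snp2 = snp_names[lay$pairs[, 2L]],
                         q = q_obs,
                         p_emp = empirical_pvalues(nulls, q_obs),
                         n_perm = nulls$n_perm, stringsAsFactors = FALSE)
  structure(list(single = single, pairs = pairs_df,
                 q_overall = lr_overall(fit), null_cdfs = nulls,
                 penalizer = penalizer, method = method, fit = fit),
            class = "dda_lrt")
}

#' @export
print.dda_lrt <- function(x, ...) {
  cat("dda_lrt:", x$method, "at penalizer", x$penalizer, "\n")
  cat("  overall q:", signif(x$q_overall, 5), "\n")
  cat("  top pair:",
      paste(unlist(x$pairs[which.min(x$pairs$p_emp), c("snp1", "snp2")]),
            collapse = " x "),
      " p_emp =", min(x$pairs$p_emp), "\n")
  invisible(x)
}

#' Quantile-quantile points for p-values
#'
#' Sorted observed `-log10 p` against the uniform order-statistic
#' expectations `-log10(i / (n + 1))`.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return data frame with columns `expected` and `observed` (both
#'   `-log10` scale), ascending in significance.
#' @export
qq_points <- function(p_values) {
  if (length(p_values) == 0L) stop("empty p-value vector")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  n <- length(p_values)
  data.frame(expected = -log10(seq_len(n) / (n + 1)),
             observed = -log10(sort(p_values)))
}
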