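#' Specification of a case-control genotype simulation
#'
#' Defines the generative study conditions: per-group genotype distributions
#' whose single-SNP fields and pairwise couplings are drawn from normal
#' distributions, with optional per-entry overrides. Sampling is exact, by
#' exhaustive enumeration of all genotype states.
#'
#' @param m number of SNPs (<= 25 for binary models, <= 15 for genotypic).
#' @param n0,n1 control and case group sizes (default equal).
#' @param hbar length-2 means of the single-SNP fields, `(control, case)`.
#' @param jbar length-2 means of the pairwise couplings, `(control, case)`.
#' @param sigma_h,sigma_j standard deviations of fields and couplings.
#' @param model `"dominant"` or `"genotypic"`.
#' @param overrides optional list with any of `h0`, `h1` (numeric vectors
#'   named by SNP index) and `J0`, `J1` (data frames with columns `i`, `j`,
#'   `value`) applied after random assignment.
#' @param mean_overrides optional list with `h` (data frame `i`, `control`,
#'   `case`) and/or `J` (data frame `i`, `j`, `control`, `case`) replacing
#'   the group means of selected entries before the random deviations are
#'   added (e.g. a single causal pair with a stronger case-group coupling).
#' @param share_deviations if `TRUE`, one random deviation per entry is
#'   drawn and shared by both groups, so case-control parameter differences
#'   equal the group-mean differences exactly; sensitivity/specificity
#'   designs use this so non-causal effects cancel between groups. If
#'   `FALSE` (default) each group draws its own parameters.
#' @param seed integer master seed; parameter draws and genotype draws use
#'   disjoint child streams.
#' @return an object of class `dda_simspec`.
#' @export
simulation_spec <- function(m, n0, n1 = n0, hbar = c(-1, -0.3),
                            jbar = c(0, 0.1), sigma_h = 0.2, sigma_j = 0.2,
                            model = c("dominant", "genotypic"),
                            overrides = NULL, mean_overrides = NULL,
                            share_deviations = FALSE, seed = 1L) {
  model <- match.arg(model)
  stopifnot(m >= 1, n0 >= 1, n1 >= 1, sigma_h >= 0, sigma_j >= 0,
            length(hbar) == 2, length(jbar) == 2)
  L <- enc_levels(model)
  if ((L == 1L && m > 25L) || (L == 2L && m > 15L))
    stop("m too large for exhaustive enumeration (25 binary / 15 genotypic)")
  structure(list(m = as.integer(m), n0 = as.integer(n0), n1 = as.integer(n1),
                 hbar = hbar, jbar = jbar, sigma_h = sigma_h,
                 sigma_j = sigma_j, model = model, overrides = overrides,
                 mean_overrides = mean_overrides,
                 share_deviations = isTRUE(share_deviations),
                 seed = as.integer(seed)),
            class = "dda_simspec")
}

apply_overrides <- function(H, Jbig, ov_h, ov_J, m, L) {
  if (!is.null(ov_h)) {
    idx <- as.integer(names(ov_h))
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > m))
      stop("override site index out of range")
    for (k in seq_along(idx))
      H[(idx[k] - 1L) * L + seq_len(L)] <- ov_h[[k]]
  }
  if (!is.null(ov_J)) {
    for (k in seq_len(nrow(ov_J))) {
      i <- ov_J$i[k]; j <- ov_J$j[k]
      if (i < 1 || j < 1 || i > m || j > m || i == j)
        stop("override pair index out of range")
      ri <- (i - 1L) * L + seq_len(L); rj <- (j - 1L) * L + seq_len(L)
      Jbig[ri, rj] <- ov_J$value[k]
      Jbig[rj, ri] <- ov_J$value[k]
    }
  }
  list(H = H, Jbig = Jbig)
}

#' Draw the group model parameters of a simulation
#'
#' Each field is drawn from `N(hbar[y], sigma_h^2)` and each coupling from
#' `N(jbar[y], sigma_j^2)` for control (y = 0) and case (y = 1) groups;
#' overrides are applied last. Reproducible under the spec's seed.
#'
#' @param spec a [simulation_spec()] object.
#' @return list with [dda_params] elements `psi0` and `psi1`.
#' @export
sample_parameters <- function(spec) {
  stopifnot(inherits(spec, "dda_simspec"))
  seeds <- child_seeds(spec$seed, 2L)
  set.seed(seeds[1L])
  m <- spec$m; L <- enc_levels(spec$model)
  lay <- theta_layout(m, L)
  nfree <- lay$p - lay$d
  # group mean surfaces, with optional per-entry mean overrides
  Hbar <- lapply(spec$hbar, rep, m * L)
  Jbar <- lapply(spec$jbar, rep, nfree)
  mo <- spec$mean_overrides
  if (!is.null(mo$h)) {
    for (k in seq_len(nrow(mo$h))) {
      idx <- (mo$h$i[k] - 1L) * L + seq_len(L)
      if (mo$h$i[k] < 1 || mo$h$i[k] > m) stop("mean override site out of range")
      Hbar[[1L]][idx] <- mo$h$control[k]
      Hbar[[2L]][idx] <- mo$h$case[k]
    }
  }
  if (!is.null(mo$J)) {
    for (k in seq_len(nrow(mo$J))) {
      i <- min(mo$J$i[k], mo$J$j[k]); j <- max(mo$J$i[k], mo$J$j[k])
      pr <- which(lay$pairs[, 1L] == i & lay$pairs[, 2L] == j)
      if (length(pr) != 1L) stop("mean override pair out of range")
      idx <- (pr - 1L) * L^2 + seq_len(L^2)
      Jbar[[1L]][idx] <- mo$J$control[k]
      Jbar[[2L]][idx] <- mo$J$case[k]
    }
  }
  if (spec$share_deviations) {
    dH <- rnorm(m * L, 0, spec$sigma_h)
    dJ <- if (nfree > 0L) rnorm(nfree, 0, spec$sigma_j) else numeric(0)
  }
  out <- list()
  for (y in 0:1) {
    if (spec$share_deviations) {
      H <- Hbar[[y + 1L]] + dH
      Jv <- Jbar[[y + 1L]] + dJ
    } else {
      H <- rnorm(m * L, Hbar[[y + 1L]], spec$sigma_h)
      Jv <- if (nfree > 0L) rnorm(nfree, Jbar[[y + 1L]], spec$sigma_j) else numeric(0)
    }
    Jbig <- unpack_theta(c(H, Jv), lay)$Jbig
    ov <- apply_overrides(H, Jbig, spec$overrides[[paste0("h", y)]],
                          spec$overrides[[paste0("J", y)]], m, L)
    out[[paste0("psi", y)]] <-
      dda_params(matrix(ov$H, m, L, byrow = TRUE), ov$Jbig, model = spec$model,
                 group = if (y == 0) "control" else "case")
  }
  out
}

#' Exhaustively enumerate a genotype distribution
#'
#' Evaluates the normalized probability of every genotype state under the
#' exponential-family distribution with the given fields and couplings.
#'
#' @param psi a [dda_params] object.
#' @return object of class `dda_dist`: `states` (K x m), `prob` (length K,
#'   sums to 1), `log_partition`.
#' @export
enumerate_distribution <- function(psi) {
  stopifnot(inherits(psi, "dda_params"))
  tab <- state_table(psi$m, psi$L)
  E <- drop(tab$Phi %*% as_theta(psi))
  lz <- lse(E)
  structure(list(states = tab$states, prob = exp(E - lz), log_partition = lz,
                 model = psi$model),
            class = "dda_dist")
}

#' Sample case-control genotypes from enumerated distributions
#'
#' Rows of each group are drawn i.i.d. from the exhaustively enumerated
#' genotype distribution of its parameters.
#'
#' @param psi0,psi1 control and case [dda_params].
#' @param n0,n1 group sizes.
#' @param seed integer seed.
#' @return list with `enc` (a `dda_encoded` object; controls first) and
#'   `labels` (0/1 vector).
#' @export
sample_genotypes <- function(psi0, psi1, n0, n1, seed = 1L) {
  stopifnot(psi0$m == psi1$m, psi0$model == psi1$model)
  set.seed(seed)
  d0 <- enumerate_distribution(psi0)
  d1 <- enumerate_distribution(psi1)
  i0 <- sample.int(length(d0$prob), n0, replace = TRUE, prob = d0$prob)
  i1 <- sample.int(length(d1$prob), n1, replace = TRUE, prob = d1$prob)
  V <- rbind(d0$states[i0, , drop = FALSE], d1$states[i1, , drop = FALSE])
  enc <- structure(list(values = V + 0, model = psi0$model,
                        snp = paste0("snp", seq_len(psi0$m)),
                        minor_allele_flags = rep(FALSE, psi0$m)),
                   class = "dda_encoded")
  list(enc = enc, labels = c(rep(0L, n0), rep(1L, n1)))
}

#' Simulate a full case-control cohort
#'
#' Draws model parameters, samples genotypes, and records the true
#' disease-risk parameters implied by the parameter differences.
#'
#' @param spec a [simulation_spec()] object.
#' @return list with `enc`, `labels`, `psi0`, `psi1`, `theta_true`
#'   (a [dda_risk] model), and `spec`.
#' @export
simulate_cohort <- function(spec) {
  seeds <- child_seeds(spec$seed, 2L)
  psis <- sample_parameters(spec)
  samp <- sample_genotypes(psis$psi0, psis$psi1, spec$n0, spec$n1,
                           seed = seeds[2L])
  p1 <- spec$n1 / (spec$n0 + spec$n1)
  theta <- dda_risk(alpha = log(p1 / (1 - p1)) +
                      enumerate_distribution(psis$psi0)$log_partition -
                      enumerate_distribution(psis$psi1)$log_partition,
                    beta = psis$psi1$H - psis$psi0$H,
                    gamma = psis$psi1$Jbig - psis$psi0$Jbig,
                    prevalence = p1, model = spec$model, source = "truth")
  c(samp, list(psi0 = psis$psi0, psi1 = psis$psi1, theta_true = theta,
               spec = spec))
}

#' Write a simulated panel as PLINK text plus a truth sidecar
#'
#' The encoded genotypes are written as `.ped`/`.map` (binary encodings write
#' carriers as heterozygotes) and the true group parameters and risk model as
#' a JSON sidecar for downstream accuracy scoring.
#'
#' @param sim output of [simulate_cohort()].
#' @param prefix output path prefix.
#' @export
write_sim_plink <- function(sim, prefix) {
  V <- sim$enc$values
  storage.mode(V) <- "integer"
  cohort <- dda_cohort(V, sim$labels)
  write_plink_ped(cohort, prefix)
  truth <- list(model = sim$spec$model,
                h0 = params_h(sim$psi0), h1 = params_h(sim$psi1),
                J0 = sim$psi0$Jbig, J1 = sim$psi1$Jbig,
                alpha = sim$theta_true$alpha, beta = sim$theta_true$beta,
                gamma = sim$theta_true$gamma,
                prevalence = sim$theta_true$prevalence,
                seed = sim$spec$seed)
  writeLines(jsonlite::toJSON(truth, digits = NA, auto_unbox = TRUE),
             paste0(prefix, "_truth.json"))
  invisible(prefix)
}
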