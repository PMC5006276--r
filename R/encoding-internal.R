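# Internal machinery shared by all fitting routines.
#
# Binary encodings (dominant/recessive) and the genotypic encoding are handled
# uniformly through a level-indicator expansion: each SNP i with encoded
# levels {0, ..., L} contributes L indicator columns x_{i,g} = 1(a_i = g),
# g = 1..L (level 0 is the reference and carries zero energy). A model is then
# always a "binary-with-constraints" exponential family with fields H over the
# m*L indicator coordinates and couplings Jbig over between-SNP coordinate
# pairs; within-SNP blocks of Jbig are identically zero.

enc_levels <- function(model) {
  switch(model,
         dominant = 1L, recessive = 1L, genotypic = 2L,
         stop("unknown encoding model: ", model))
}

# expand an encoded n x m matrix (values 0..L) into n x (m*L) indicators,
# columns interleaved as (snp1 lev1, snp1 lev2, snp2 lev1, ...)
expand_indicators <- function(A, L) {
  A <- as.matrix(A)
  if (L == 1L) {
    storage.mode(A) <- "double"
    return(A)
  }
  m <- ncol(A)
  X <- matrix(0, nrow(A), m * L)
  for (g in seq_len(L)) {
    X[, seq(g, m * L, by = L)] <- (A == g) + 0
  }
  X
}

# coordinate layout for the packed parameter vector theta = c(H, Jfree):
# H has d = m*L entries; Jfree holds, for each SNP pair (i<j) in column-major
# pair order, the L*L block entries in column-major (g', g) order.
theta_layout <- function(m, L) {
  d <- m * L
  pairs <- if (m >= 2L) t(utils::combn(m, 2L)) else matrix(integer(), 0L, 2L)
  np <- nrow(pairs)
  # expanded coordinate indices (r, s) for every free J entry
  if (np > 0L) {
    r_idx <- integer(np * L * L)
    s_idx <- integer(np * L * L)
    k <- 0L
    for (pr in seq_len(np)) {
      i <- pairs[pr, 1L]; j <- pairs[pr, 2L]
      for (gj in seq_len(L)) for (gi in seq_len(L)) {
        k <- k + 1L
        r_idx[k] <- (i - 1L) * L + gi
        s_idx[k] <- (j - 1L) * L + gj
      }
    }
  } else {
    r_idx <- s_idx <- integer(0)
  }
  list(m = m, L = L, d = d, pairs = pairs, npairs = np,
       r_idx = r_idx, s_idx = s_idx, p = d + length(r_idx))
}

# feature matrix for rows of expanded indicators X (n x d):
# cbind(X, X[, r] * X[, s]) following the layout's J entry order
feature_matrix <- function(X, layout) {
  if (layout$npairs == 0L) return(X)
  cbind(X, X[, layout$r_idx, drop = FALSE] * X[, layout$s_idx, drop = FALSE])
}

# pack/unpack between (H, Jbig) and theta
pack_theta <- function(H, Jbig, layout) {
  c(H, Jbig[cbind(layout$r_idx, layout$s_idx)])
}

unpack_theta <- function(theta, layout) {
  H <- theta[seq_len(layout$d)]
  Jbig <- matrix(0, layout$d, layout$d)
  if (layout$p > layout$d) {
    v <- theta[(layout$d + 1L):layout$p]
    Jbig[cbind(layout$r_idx, layout$s_idx)] <- v
    Jbig[cbind(layout$s_idx, layout$r_idx)] <- v
  }
  list(H = H, Jbig = Jbig)
}

# penalty mask over theta (couplings only)
pen_mask <- function(layout) {
  c(rep(0, layout$d), rep(1, layout$p - layout$d))
}

# enumerated state table for m SNPs with levels 0..L, cached per (m, L);
# returns list(states = K x m integer matrix, X = K x d indicators,
#              Phi = K x p features, layout)
state_table <- function(m, L) {
  key <- paste0("st_", m, "_", L)
  if (!is.null(.dda_cache[[key]])) return(.dda_cache[[key]])
  K <- (L + 1L)^m
  if ((L == 1L && m > 25L) || (L == 2L && m > 15L))
    stop("exhaustive enumeration limited to m <= 25 (binary) or 15 (genotypic)")
  states <- as.matrix(expand.grid(rep(list(0L:L), m), KEEP.OUT.ATTRS = FALSE))
  dimnames(states) <- NULL
  layout <- theta_layout(m, L)
  X <- expand_indicators(states, L)
  tab <- list(states = states, X = X, Phi = feature_matrix(X, layout),
              layout = layout)
  .dda_cache[[key]] <- tab
  tab
}

# map encoded rows to 1-based state indices of state_table()$states
state_index <- function(A, L) {
  m <- ncol(A)
  pow <- (L + 1)^(seq_len(m) - 1)
  as.integer(round(A %*% pow)) + 1L
}

# log-sum-exp
lse <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

# derive k child seeds (< 2^31) from a master seed without disturbing the
# caller's RNG state
child_seeds <- function(seed, k) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max, k)
}
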