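#' Genotype-distribution model parameters
#'
#' Container for the exponential-family genotype distribution of one group:
#' single-SNP fields `h` and symmetric pairwise couplings `J`. For binary
#' encodings (dominant/recessive) `h` is one value per SNP and `J` one value
#' per SNP pair; for the genotypic encoding each SNP carries one field per
#' non-reference level (1, 2) and each pair a 2x2 coupling block. Internally
#' both cases are stored in the expanded level-indicator representation.
#'
#' @param h numeric vector of length `m` (binary models) or `m x L` matrix
#'   with rows = SNPs, columns = levels (genotypic, L = 2), or an
#'   already-expanded vector of length `m*L`.
#' @param J symmetric `m*L x m*L` matrix of couplings in the expanded
#'   representation with zero within-SNP blocks, or (binary) a plain `m x m`
#'   symmetric zero-diagonal matrix. `NULL` means no interactions.
#' @param model encoding label: `"dominant"`, `"recessive"` or `"genotypic"`.
#' @param group which sample the parameters describe: `"control"`, `"case"`,
#'   or `"pooled"`.
#' @param log_partition log normalizing constant if known (`NA` otherwise).
#' @return an object of class `dda_params`.
#' @export
dda_params <- function(h, J = NULL, model = "dominant",
                       group = c("control", "case", "pooled"),
                       log_partition = NA_real_) {
  group <- match.arg(group)
  L <- enc_levels(model)
  if (is.matrix(h)) {
    stopifnot(ncol(h) == L)
    m <- nrow(h)
    H <- as.numeric(t(h))           # interleaved (snp1 lev1, snp1 lev2, ...)
  } else {
    if (L == 1L) {
      m <- length(h); H <- as.numeric(h)
    } else {
      stopifnot(length(h) %% L == 0L)
      m <- length(h) %/% L; H <- as.numeric(h)
    }
  }
  d <- m * L
  if (is.null(J)) J <- matrix(0, d, d)
  J <- as.matrix(J)
  if (L == 1L && nrow(J) != d) stop("J dimension does not match h")
  if (nrow(J) != d || ncol(J) != d) stop("J must be ", d, " x ", d)
  if (max(abs(J - t(J))) > 1e-8) stop("J must be symmetric")
  # zero out within-SNP blocks (including the diagonal)
  snp_of <- rep(seq_len(m), each = L)
  J[outer(snp_of, snp_of, "==")] <- 0
  if (!all(is.finite(H)) || !all(is.finite(J))) stop("non-finite parameters")
  structure(list(H = H, Jbig = J, m = m, L = L, model = model, group = group,
                 log_partition = log_partition),
            class = "dda_params")
}

#' @export
print.dda_params <- function(x, ...) {
  cat("dda_params:", x$model, "model,", x$group, "group,", x$m, "SNPs\n")
  cat("  |h| range:", signif(range(x$H), 3), "\n")
  if (x$m > 1L)
    cat("  |J| max:", signif(max(abs(x$Jbig)), 3),
        " log Z:", signif(x$log_partition, 6), "\n")
  invisible(x)
}

#' Single-SNP fields as an m x L matrix
#' @param params a [dda_params] object.
#' @return numeric matrix, rows = SNPs, columns = encoded levels.
#' @export
params_h <- function(params) {
  matrix(params$H, nrow = params$m, ncol = params$L, byrow = TRUE)
}

#' Coupling block for one SNP pair
#' @param params a [dda_params] object.
#' @param i,j SNP indices.
#' @return `L x L` numeric matrix (a scalar-like 1x1 matrix for binary models).
#' @export
params_J <- function(params, i, j) {
  L <- params$L
  ri <- (i - 1L) * L + seq_len(L)
  rj <- (j - 1L) * L + seq_len(L)
  params$Jbig[ri, rj, drop = FALSE]
}

# flat vector of the distinct couplings (upper between-SNP entries),
# in theta_layout order
params_Jfree <- function(params) {
  lay <- theta_layout(params$m, params$L)
  params$Jbig[cbind(lay$r_idx, lay$s_idx)]
}

as_theta <- function(params) {
  lay <- theta_layout(params$m, params$L)
  pack_theta(params$H, params$Jbig, lay)
}

params_from_theta <- function(theta, layout, model, group, log_partition = NA_real_) {
  up <- unpack_theta(theta, layout)
  dda_params(matrix(up$H, layout$m, layout$L, byrow = TRUE), up$Jbig,
             model = model, group = group, log_partition = log_partition)
}

#' Serialize fitted model parameters to JSON
#'
#' @param params a [dda_params] object.
#' @param path output file; if `NULL` the JSON string is returned.
#' @param ... further fields stored alongside (e.g. penalizer, method).
#' @return invisibly, the JSON string.
#' @export
write_params_json <- function(params, path = NULL, ...) {
  obj <- list(model = params$model, group = params$group,
              m = params$m, levels = params$L,
              h = params_h(params), J = params$Jbig,
              log_partition = params$log_partition, ...)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}
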