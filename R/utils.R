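# Internal numerical helpers shared across modules.

# Force exact symmetry after floating-point updates.
symmetrize <- function(M) (M + t(M)) / 2

# Relative jitter used before inverting near-singular covariance matrices.
default_jitter <- function(M) 1e-9 * sum(diag(M)) / nrow(M)

#' Invert a symmetric positive (semi)definite matrix with jitter regularisation
#'
#' Inverts via Cholesky. When the smallest eigenvalue is below
#' `1e-12 * largest`, a ridge `lambda * I` with `lambda = 1e-9 * trace/n`
#' is added first, so that information matrices obtained from nearly
#' degenerate residue covariances remain finite.
#'
#' @param M symmetric matrix.
#' @param label name used in error messages.
#' @return the inverse, exactly symmetric.
#' @keywords internal
#' @noRd
inv_psd <- function(M, label = "matrix") {
  M <- symmetrize(as.matrix(M))
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) {
    stop(label, " is not positive definite; add jitter regularization ",
         "(e.g. M + 1e-9 * mean(diag(M)) * I) or supply more data.",
         call. = FALSE)
  }
  if (min(ev) < 1e-12 * max(ev)) {
    M <- M + diag(default_jitter(M), nrow(M))
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      stop(label, " is rank deficient even after jitter regularization; ",
           "inspect the residues for constant dimensions.", call. = FALSE)
    }
  }
  symmetrize(chol2inv(chol(M)))
}

# Upper-triangular Cholesky factor S with t(S) %*% S == M. Adds escalating
# jitter for matrices that are PSD up to rounding (e.g. prior information
# after a near-total-uncertainty initialisation), errors otherwise.
chol_factor <- function(M, label = "matrix") {
  M <- symmetrize(as.matrix(M))
  base <- max(mean(diag(M)), .Machine$double.eps)
  for (lambda in c(0, 1e-12, 1e-10, 1e-8) * base) {
    S <- tryCatch(chol(M + diag(lambda, nrow(M))), error = function(e) NULL)
    if (!is.null(S)) return(S)
  }
  stop(label, " block is not positive definite.", call. = FALSE)
}

# Extract a numeric matrix of the given columns from a data frame or matrix.
# `prefix` columns are auto-detected when `cols` is NULL.
as_state_matrix <- function(x, cols = NULL, prefix = "x") {
  if (is.matrix(x)) return(unname(as.matrix(x)))
  stopifnot(is.data.frame(x))
  if (is.null(cols)) {
    cols <- grep(paste0("^", prefix, "[0-9]+$"), names(x), value = TRUE)
    if (length(cols) == 0) {
      cols <- setdiff(names(x), c("t", "time", "trial", "lever", "phase", "outlier"))
    }
  }
  unname(as.matrix(x[cols]))
}

l2 <- function(v) sqrt(sum(v^2))
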