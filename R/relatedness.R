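#' Centered genetic relatedness matrix
#'
#' G = W W' / p, where W is the genotype matrix with each marker column
#' centered on its mean and p is the number of markers. Missing genotypes
#' are mean-imputed per marker for GRM construction only (association
#' tests drop them instead).
#'
#' @param geno Genotype matrix (individuals x markers, 0/1/2/NA).
#' @return A `grm`: symmetric matrix with individual dimnames and a
#'   `provenance` attribute ("raw").
#' @export
centered_grm <- function(geno) {
  stopifnot(is.matrix(geno))
  if (nrow(geno) < 2 || ncol(geno) < 1) {
    stop("need at least 2 individuals and 1 marker")
  }
  mu <- colMeans(geno, na.rm = TRUE)
  W <- sweep(geno, 2, mu)
  W[is.na(W)] <- 0
  keep <- apply(W, 2, function(x) any(x != 0))
  if (!any(keep)) stop("all markers have zero variance")
  W <- W[, keep, drop = FALSE]
  G <- tcrossprod(W) / ncol(W)
  dimnames(G) <- list(rownames(geno), rownames(geno))
  attr(G, "provenance") <- "raw"
  class(G) <- c("grm", class(G))
  G
}

#' Override the F2 block of a GRM
#'
#' F2 individuals are effectively full siblings: their pairwise relatedness
#' is fixed at 0.5 and their diagonal at 1, leaving every other entry
#' (F2-AIC and AIC-AIC) untouched.
#'
#' @param grm A `grm` with individual dimnames.
#' @param f2_ids Ids of the F2 individuals.
#' @return The overridden `grm` (provenance "f2-overridden").
#' @export
override_f2_block <- function(grm, f2_ids) {
  ids <- rownames(grm)
  if (!all(f2_ids %in% ids)) {
    stop("unknown ids: ", paste(setdiff(f2_ids, ids), collapse = ", "))
  }
  i <- match(f2_ids, ids)
  grm[i, i] <- 0.5
  diag(grm)[i] <- 1
  attr(grm, "provenance") <- "f2-overridden"
  grm
}

#' Nearest positive-definite adjustment
#'
#' Projects a symmetric matrix to the nearest positive semi-definite
#' matrix in Frobenius norm (Higham alternating projections without a
#' diagonal constraint, which reduces to clipping negative eigenvalues),
#' then floors the spectrum at `eig_floor` for strict definiteness. The
#' adjustment adds only the small perturbation needed to remove negative
#' eigenvalues, which mixed-model fitting requires. Already-PD input is
#' returned essentially unchanged.
#'
#' @param m Symmetric matrix (checked to `sym_tol`).
#' @param eig_floor Eigenvalue floor (default 1e-8).
#' @param sym_tol Symmetry tolerance.
#' @return The adjusted `grm` (provenance extended with "pd-adjusted"),
#'   with the pre/post eigenvalue ranges in attribute `eig_report`.
#' @export
near_pd <- function(m, eig_floor = 1e-8, sym_tol = 1e-9) {
  if (!is.matrix(m) || nrow(m) != ncol(m) ||
      max(abs(m - t(m))) > sym_tol * max(1, max(abs(m)))) {
    stop("`m` must be a symmetric square matrix")
  }
  m_sym <- (m + t(m)) / 2
  e <- eigen(m_sym, symmetric = TRUE)
  vals <- pmax(e$values, eig_floor)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(m)
  attr(out, "provenance") <- c(attr(m, "provenance"), "pd-adjusted")
  attr(out, "eig_report") <- list(before = range(e$values),
                                  after = range(vals))
  class(out) <- c("grm", class(out)[class(out) != "grm"])
  out
}

#' Mantel similarity between two relatedness matrices
#'
#' Pearson correlation of the lower-triangle off-diagonal entries, with an
#' optional permutation p-value from simultaneous row/column shuffles (the
#' Mantel test). Used to verify that the positive-definite adjustment
#' perturbs the GRM only slightly.
#'
#' @param m1,m2 Square matrices of identical dimension (>= 3).
#' @param n_perm Number of permutations (0 = no test).
#' @param seed Seed for the permutation test.
#' @return List with `correlation` (also as `similarity_pct`) and, when
#'   permuted, `p_value`.
#' @export
mantel_similarity <- function(m1, m2, n_perm = 0, seed = 1) {
  if (!all(dim(m1) == dim(m2)) || nrow(m1) < 3) {
    stop("matrices must have identical shape with >= 3 individuals")
  }
  lt <- lower.tri(m1)
  x <- m1[lt]; y <- m2[lt]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant off-diagonal entries")
  }
  r_obs <- stats::cor(x, y)
  out <- list(correlation = r_obs, similarity_pct = 100 * r_obs)
  if (n_perm > 0) {
    set.seed(seed)
    n <- nrow(m1)
    r_perm <- vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      stats::cor(x, m2[p, p][lt])
    }, 0)
    out$p_value <- (1 + sum(r_perm >= r_obs)) / (n_perm + 1)
  }
  out
}
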