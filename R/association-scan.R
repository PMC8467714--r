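# Case/control x genotype-class counts for every marker at once.
# Returns list of 3-column matrices (markers x genotype classes):
# case counts, control counts.
.scan_counts <- function(geno, pheno) {
  use <- !is.na(pheno)
  g <- geno[use, , drop = FALSE]
  y <- pheno[use]
  case <- matrix(0, ncol(g), 3, dimnames = list(colnames(g), 0:2))
  tot <- case
  for (k in 0:2) {
    ind <- (!is.na(g)) & g == k
    tot[, k + 1] <- colSums(ind)
    case[, k + 1] <- colSums(ind * y)
  }
  list(case = case, control = tot - case)
}

# 2-df G statistic of the 2x3 case/control-by-genotype table per marker,
# with the 0 * log 0 = 0 convention for empty cells.
.g_stat <- function(case, control) {
  if (is.null(dim(case))) {
    case <- matrix(case, ncol = 3)
    control <- matrix(control, ncol = 3)
  }
  tot <- case + control
  n <- rowSums(tot)
  pr_case <- rowSums(case) / n
  xlogx <- function(o, e) ifelse(o > 0, o * log(o / e), 0)
  e_case <- tot * pr_case
  e_ctrl <- tot * (1 - pr_case)
  g <- 2 * (rowSums(xlogx(case, e_case)) + rowSums(xlogx(control, e_ctrl)))
  g[!is.finite(g)] <- 0
  pmax(g, 0)
}

#' Binary-trait QTL scan for an F2 intercross
#'
#' Per marker, compares the saturated three-genotype-class binomial model
#' with the null of a common case probability by a 2-df likelihood-ratio
#' test (the G statistic of the 2x3 case/control-by-genotype table),
#' reported as LOD = LRT / (2 ln 10). An additive-coded logistic
#' regression supplies the per-allele effect and odds ratio. Individuals
#' missing the marker (or with NA phenotype) are dropped marker-wise.
#'
#' @param geno Genotype matrix.
#' @param pheno Binary vector (0 = control, 1 = defect; NA dropped).
#' @param map Optional [marker_map()] to annotate positions.
#' @return A `scan_result` data frame: marker, (chromosome, position), n,
#'   LRT, LOD, nominal p (chi-square 2 df), additive beta, se, OR, and a
#'   `monomorphic` flag (such markers get LOD 0, p 1).
#' @export
binary_scan_f2 <- function(geno, pheno, map = NULL) {
  stopifnot(is.matrix(geno), length(pheno) == nrow(geno))
  if (!all(pheno %in% c(0, 1, NA))) stop("`pheno` must be binary 0/1")
  cc <- .scan_counts(geno, pheno)
  lrt <- .g_stat(cc$case, cc$control)
  mono <- rowSums((cc$case + cc$control) > 0) < 2
  lrt[mono] <- 0
  lod <- lrt / (2 * log(10))
  p <- stats::pchisq(lrt, df = 2, lower.tail = FALSE)
  p[mono] <- 1

  beta <- se <- rep(NA_real_, ncol(geno))
  use0 <- !is.na(pheno)
  for (j in seq_len(ncol(geno))) {
    if (mono[j]) next
    use <- use0 & !is.na(geno[, j])
    fit <- tryCatch(
      stats::glm(pheno[use] ~ geno[use, j], family = stats::binomial()),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(stats::glm(pheno[use] ~ geno[use, j],
                                    family = stats::binomial()))
      })
    if (!is.null(fit) && length(stats::coef(fit)) == 2) {
      sm <- summary(fit)$coefficients
      beta[j] <- sm[2, 1]; se[j] <- sm[2, 2]
    }
  }
  out <- data.frame(
    marker = colnames(geno),
    n = rowSums(cc$case + cc$control),
    LRT = lrt, LOD = lod, p = p,
    beta = beta, se = se, OR = exp(beta),
    monomorphic = mono,
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (!is.null(map)) {
    i <- match(out$marker, map$id)
    out$chromosome <- map$chromosome[i]
    out$position_bp <- map$position_bp[i]
    out <- out[, c("marker", "chromosome", "position_bp",
                   setdiff(names(out), c("marker", "chromosome", "position_bp")))]
  }
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Permutation significance thresholds for a binary scan
#'
#' Shuffles the phenotype labels, records the genome-wide maximum LOD of
#' the 2-df binary scan in each permutation, and returns the empirical
#' (1 - alpha) quantiles as genome-wide LOD thresholds.
#'
#' @param geno Genotype matrix.
#' @param pheno Binary phenotype (NA dropped before permuting).
#' @param n_perm Number of permutations (>= 100).
#' @param alphas Genome-wide error rates.
#' @param seed Integer seed.
#' @return List with `thresholds` (named by alpha) and `max_lod` (the
#'   permutation distribution).
#' @export
permutation_thresholds <- function(geno, pheno, n_perm = 1000,
                                   alphas = c(0.05, 0.2), seed = 1) {
  if (n_perm < 100) stop("`n_perm` must be at least 100")
  set.seed(seed)
  use <- !is.na(pheno)
  g <- geno[use, , drop = FALSE]
  y <- pheno[use]
  n <- length(y)
  # Precompute per-marker genotype-class indicators once; each permutation
  # is then a single matrix product.
  ind <- lapply(0:2, function(k) {
    M <- (!is.na(g)) & g == k
    storage.mode(M) <- "double"
    M
  })
  tot <- vapply(ind, colSums, numeric(ncol(g)))
  max_lod <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    yp <- y[sample.int(n)]
    case <- vapply(ind, function(M) as.numeric(crossprod(M, yp)),
                   numeric(ncol(g)))
    lrt <- .g_stat(case, tot - case)
    max_lod[b] <- max(lrt) / (2 * log(10))
  }
  th <- stats::quantile(max_lod, probs = 1 - alphas, names = FALSE, type = 7)
  list(thresholds = stats::setNames(th, paste0("alpha_", alphas)),
       max_lod = max_lod)
}

#' Effective number of independent tests
#'
#' Li-Ji style estimate from the eigenvalues of the marker correlation
#' matrix: M_eff = sum over eigenvalues of I(lambda >= 1) +
#' (lambda - floor(lambda)). Markers with no variation (or no data) are
#' excluded with a warning. Returns Bonferroni-style thresholds
#' 0.05 / M_eff (significant) and 1 / M_eff (suggestive).
#'
#' @param geno Genotype matrix (>= 2 markers).
#' @return List with `m_eff`, `threshold_significant`,
#'   `threshold_suggestive`.
#' @export
effective_tests <- function(geno) {
  stopifnot(is.matrix(geno))
  if (ncol(geno) < 2) stop("need at least 2 markers")
  v <- apply(geno, 2, stats::var, na.rm = TRUE)
  bad <- is.na(v) | v == 0
  if (any(bad)) {
    warning(sum(bad), " marker(s) without variation excluded from M_eff")
    geno <- geno[, !bad, drop = FALSE]
  }
  R <- suppressWarnings(stats::cor(geno, use = "pairwise.complete.obs"))
  R[is.na(R)] <- 0; diag(R) <- 1
  lam <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  # rounding guards the floor() against eigenvalues like 6 - 1e-15
  lam <- pmax(round(lam, 8), 0)
  m_eff <- sum(as.numeric(lam >= 1) + (lam - floor(lam)))
  list(m_eff = m_eff,
       threshold_significant = 0.05 / m_eff,
       threshold_suggestive = 1 / m_eff)
}

#' Liability-scale transformation of a variance-explained estimate
#'
#' Corrects an observed-scale PVE for case-control ascertainment and
#' transforms it to the liability scale:
#' PVE_l = PVE * P^2 (1-P)^2 / (A (1-A) z^2), where P is the population
#' incidence, A the incidence in the ascertained cohort, and z the
#' standard normal density at the population liability threshold.
#'
#' @param PVE Observed-scale proportion of variance explained (>= 0).
#' @param P Population incidence in (0, 1).
#' @param A Ascertained-cohort incidence in (0, 1).
#' @return Liability-scale PVE.
#' @export
liability_transform <- function(PVE, P, A) {
  if (P <= 0 || P >= 1 || A <= 0 || A >= 1) {
    stop("`P` and `A` must lie strictly inside (0, 1)")
  }
  if (any(PVE < 0)) stop("`PVE` must be non-negative")
  z <- stats::dnorm(stats::qnorm(1 - P))
  PVE * P^2 * (1 - P)^2 / (A * (1 - A) * z^2)
}

#' Variance explained by a single marker
#'
#' PVE_SNP = MAF (1 - MAF) beta^2 / PV. The conventional additive genetic
#' variance of a biallelic locus carries an extra factor 2
#' (2 MAF (1-MAF) beta^2); set `conventional = TRUE` to include it. The
#' default follows the one-factor form.
#'
#' @param maf Minor allele frequency in (0, 0.5].
#' @param beta Per-allele marker effect.
#' @param pv Phenotypic variance (> 0).
#' @param conventional Include the factor 2 of the standard additive
#'   variance formula.
#' @return Proportion of phenotypic variance explained by the marker.
#' @export
pve_snp <- function(maf, beta, pv, conventional = FALSE) {
  if (any(maf <= 0 | maf > 0.5)) stop("`maf` must lie in (0, 0.5]")
  if (any(pv <= 0)) stop("`pv` must be positive")
  fac <- if (conventional) 2 else 1
  fac * maf * (1 - maf) * beta^2 / pv
}
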