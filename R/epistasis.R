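#' Two-locus case/control incidence table
#'
#' Tabulates cases and controls of one defect over the nine genotype
#' combinations at a locus pair. Individuals missing either genotype are
#' excluded; empty cells are kept with an undefined (NA) incidence and
#' flagged. The table carries the unweighted average incidence (UWA) over
#' the nine cells — the scaling denominator that makes interaction
#' effects comparable between defects of different incidence.
#'
#' @param geno Genotype matrix.
#' @param pheno Binary defect indicator (1 = case, 0 = control, NA
#'   excluded).
#' @param pair Character vector of two distinct marker ids.
#' @param defect Defect label carried in the result.
#' @return A `two_locus_table`: list with `n_case`, `n_control`,
#'   `incidence` (3x3 matrices, locus 1 in rows), `uwa`,
#'   `population_incidence`, `empty_cells`, `pair`, `defect`.
#' @export
incidence_table <- function(geno, pheno, pair, defect = "defect") {
  if (length(pair) != 2 || pair[1] == pair[2]) {
    stop("`pair` must name two distinct markers")
  }
  if (!all(pair %in% colnames(geno))) {
    stop("markers absent from genotype table: ",
         paste(setdiff(pair, colnames(geno)), collapse = ", "))
  }
  g1 <- geno[, pair[1]]; g2 <- geno[, pair[2]]
  use <- !is.na(pheno) & !is.na(g1) & !is.na(g2)
  g1 <- g1[use]; g2 <- g2[use]; y <- pheno[use]
  dn <- list(g1 = 0:2, g2 = 0:2)
  n_case <- n_ctrl <- matrix(0L, 3, 3, dimnames = dn)
  for (a in 0:2) for (b in 0:2) {
    cell <- g1 == a & g2 == b
    n_case[a + 1, b + 1] <- sum(y[cell] == 1)
    n_ctrl[a + 1, b + 1] <- sum(y[cell] == 0)
  }
  tot <- n_case + n_ctrl
  inc <- ifelse(tot > 0, n_case / tot, NA_real_)
  structure(list(
    defect = defect, pair = pair,
    n_case = n_case, n_control = n_ctrl,
    incidence = inc,
    uwa = mean(inc),
    population_incidence = mean(y == 1),
    empty_cells = which(tot == 0, arr.ind = TRUE)
  ), class = "two_locus_table")
}

#' Decompose a two-locus incidence table into main effects and interaction
#'
#' The expected incidence at each cell is the unweighted main-effects fit
#' expected_ij = rowmean_i + colmean_j - grandmean (equivalently, the
#' unweighted least-squares regression of the nine cell incidences onto
#' the two single-locus margins, all cells weighted equally regardless of
#' counts). The higher-order interaction effect is
#' observed - expected; its rows, columns, and total each sum to zero, so
#' interaction at one genotype is always balanced by opposite deviations
#' elsewhere.
#'
#' @param table A [incidence_table()] result, or a plain 3x3 incidence
#'   matrix.
#' @return List with `expected` and `effects` (3x3 matrices).
#' @export
epistasis_decompose <- function(table) {
  inc <- if (inherits(table, "two_locus_table")) table$incidence else table
  if (!is.matrix(inc) || !all(dim(inc) == c(3, 3))) {
    stop("need a 3x3 incidence table")
  }
  if (anyNA(inc)) {
    pr <- if (inherits(table, "two_locus_table")) {
      paste(table$pair, collapse = "-")
    } else "table"
    stop("empty cell(s) in ", pr,
         ": decomposition requires all nine incidences")
  }
  resid <- .main_effects_residual(inc)
  list(expected = inc - resid, effects = resid)
}

# Contrast coefficients of the interaction effect at cell (i, j): 4/9 at
# the cell, -2/9 sharing its row or column, +1/9 elsewhere. These are the
# weights the unweighted main-effects residual applies to the nine cells.
.effect_contrast <- function(i, j) {
  lam <- matrix(1 / 9, 3, 3)
  lam[i, ] <- -2 / 9
  lam[, j] <- -2 / 9
  lam[i, j] <- 4 / 9
  lam
}

#' Test higher-order interaction effects at every two-locus genotype
#'
#' Each cell incidence is arcsine-square-root transformed
#' (theta = asin(sqrt(p)), variance 1/(4n) — the variance-stabilized
#' scale), and the interaction at cell (i, j) is tested as the linear
#' contrast of the nine transformed incidences with the decomposition
#' weights (+4/9 at the cell, -2/9 sharing a row or column, +1/9
#' elsewhere). Two-tailed tests use the normal reference; the
#' significance threshold is Bonferroni-corrected over all two-locus
#' genotypes examined for the defect, 0.05 / (9 x) for x locus pairs.
#' Reported effect magnitudes stay on the incidence scale, scaled by the
#' UWA for cross-defect comparison.
#'
#' @param table A [incidence_table()] with all nine cells populated.
#' @param n_pairs_for_defect x, the number of locus pairs analyzed for
#'   this defect (sets the Bonferroni threshold 0.05 / (9 x)).
#' @return A `data.frame` (class `epistasis_effects`) with one row per
#'   cell: genotypes, observed, expected, effect (observed - expected),
#'   scaled effect (effect / UWA), direction, arcsine-scale contrast, se,
#'   t, p, significance flag, testable flag, and the syn/anti genotype
#'   class from [classify_two_locus()].
#' @export
test_effects <- function(table, n_pairs_for_defect = 1) {
  stopifnot(inherits(table, "two_locus_table"))
  dec <- epistasis_decompose(table)
  n <- table$n_case + table$n_control
  if (any(n == 0)) stop("zero-count cell: pair not testable")
  theta <- asin(sqrt(table$incidence))
  v <- 1 / (4 * n)
  thr <- 0.05 / (9 * n_pairs_for_defect)
  rows <- vector("list", 9)
  k <- 0
  for (i in 1:3) for (j in 1:3) {
    lam <- .effect_contrast(i, j)
    est <- sum(lam * theta)
    se <- sqrt(sum(lam^2 * v))
    tstat <- est / se
    p <- 2 * stats::pnorm(-abs(tstat))
    k <- k + 1
    rows[[k]] <- data.frame(
      defect = table$defect,
      locus1 = table$pair[1], locus2 = table$pair[2],
      g1 = i - 1L, g2 = j - 1L,
      n = n[i, j],
      observed = table$incidence[i, j],
      expected = dec$expected[i, j],
      effect = dec$effects[i, j],
      scaled_effect = if (table$uwa > 0) dec$effects[i, j] / table$uwa else NA_real_,
      direction = ifelse(dec$effects[i, j] >= 0, "+", "-"),
      contrast_asin = est, se_asin = se, t = tstat, p = p,
      significant = p < thr,
      class = classify_two_locus(i - 1L, j - 1L),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "uwa") <- table$uwa
  attr(out, "threshold") <- thr
  class(out) <- c("epistasis_effects", "data.frame")
  out
}

#' Scale interaction effects by the unweighted average incidence
#'
#' Dividing effects by the UWA expresses each deviation relative to the
#' defect's typical incidence, making magnitudes comparable between
#' defects with different incidences. Signs are preserved (+ raises
#' risk, - lowers risk); absolute values are used for cross-defect
#' magnitude comparisons.
#'
#' @param effects 3x3 matrix of raw effects (or vector).
#' @param uwa Unweighted average incidence (> 0).
#' @return Scaled effects of the same shape.
#' @export
scale_effects <- function(effects, uwa) {
  if (!is.numeric(uwa) || length(uwa) != 1 || is.na(uwa) || uwa <= 0) {
    stop("`uwa` must be a single positive number")
  }
  effects / uwa
}

#' Pick a partner marker for pairwise interaction analysis
#'
#' When a defect has only one mapped locus, pairwise interaction analysis
#' proceeds with the next most significant marker from the scan that is
#' neither among the existing loci nor linked to any of them (within
#' 10 Mb on the same chromosome).
#'
#' @param scan Data frame with columns marker and p (e.g. from
#'   [lmm_scan()]), plus chromosome/position_bp or a `map` to supply them.
#' @param existing_loci Markers already selected.
#' @param map Optional [marker_map()] for positions.
#' @param exclusion_bp Linkage exclusion window (default 10 Mb).
#' @return The chosen marker id.
#' @export
partner_snp <- function(scan, existing_loci, map = NULL,
                        exclusion_bp = 10e6) {
  if (!nrow(scan)) stop("empty scan")
  sc <- scan
  if (!is.null(map)) {
    i <- match(sc$marker, map$id)
    sc$chromosome <- map$chromosome[i]
    sc$position_bp <- map$position_bp[i]
  }
  if (is.null(sc$chromosome) || is.null(sc$position_bp)) {
    stop("scan lacks positions; supply `map`")
  }
  ex <- sc[sc$marker %in% existing_loci, , drop = FALSE]
  cand <- sc[!(sc$marker %in% existing_loci), , drop = FALSE]
  if (nrow(ex)) {
    linked <- vapply(seq_len(nrow(cand)), function(r) {
      any(ex$chromosome == cand$chromosome[r] &
            abs(ex$position_bp - cand$position_bp[r]) < exclusion_bp)
    }, TRUE)
    cand <- cand[!linked, , drop = FALSE]
  }
  cand <- cand[!is.na(cand$p), , drop = FALSE]
  if (!nrow(cand)) stop("no eligible partner marker")
  cand$marker[which.min(cand$p)]
}
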