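# Shared fixtures, built in code at test time.

# Tiny single-chromosome map with regular spacing.
tiny_map <- function(n = 5, spacing_cM = 4, chr = 1) {
  marker_map(
    id = sprintf("t%02d_%02d", chr, seq_len(n)),
    chromosome = rep(chr, n),
    position_bp = seq_len(n) * spacing_cM * 2e6,
    position_cM = seq_len(n) * spacing_cM
  )
}

# Quick F2 cohort with a flat (architecture-free) penetrance.
quick_f2 <- function(n = 500, map = make_marker_panel(20), baseline = 0.1,
                     seed = 1, mutant_fraction = 1) {
  simulate_cohort(
    cross_design(generations = c(F2 = n), mutant_fraction = mutant_fraction),
    map,
    penetrance_spec(list(defect = list(baseline = baseline))),
    seed = seed
  )
}

# Brute-force posterior of the three-state genotype HMM by enumerating all
# hidden-state paths (chains of <= 6 markers).
enumerate_posterior <- function(obs, pos_cM, error_rate, target_idx,
                                expansion = 1) {
  k <- length(pos_cM)
  P <- lapply(haldane_recomb(diff(pos_cM) * expansion), function(r) {
    matrix(c((1 - r)^2, 2 * r * (1 - r), r^2,
             r * (1 - r), (1 - r)^2 + r^2, r * (1 - r),
             r^2, 2 * r * (1 - r), (1 - r)^2), 3, 3, byrow = TRUE)
  })
  prior <- c(0.25, 0.5, 0.25)
  states <- as.matrix(expand.grid(rep(list(0:2), k)))
  w <- apply(states, 1, function(s) {
    p <- prior[s[1] + 1]
    if (k > 1) {
      for (j in 2:k) p <- p * P[[j - 1]][s[j - 1] + 1, s[j] + 1]
    }
    for (j in seq_len(k)) {
      if (!is.na(obs[j])) {
        p <- p * ifelse(s[j] == obs[j], 1 - error_rate, error_rate / 2)
      }
    }
    p
  })
  vapply(0:2, function(v) sum(w[states[, target_idx] == v]), 0) / sum(w)
}

# Unweighted least-squares main-effects fit of a 3x3 table (independent
# oracle for the epistasis decomposition).
ls_residual <- function(tab) {
  row_f <- factor(rep(1:3, 3))
  col_f <- factor(rep(1:3, each = 3))
  X <- stats::model.matrix(~ row_f + col_f)
  matrix(stats::lm.fit(X, as.vector(tab))$residuals, 3, 3)
}
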