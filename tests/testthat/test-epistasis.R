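test_that("incidence tables count exactly and conserve individuals", {
  set.seed(24)
  n <- 400
  g <- cbind(a = sample(0:2, n, TRUE), b = sample(0:2, n, TRUE))
  g[1:10, 1] <- NA
  y <- rbinom(n, 1, 0.25)
  y[11:15] <- NA
  tab <- incidence_table(g, y, c("a", "b"), defect = "ASD")
  analyzed <- sum(!is.na(y) & !is.na(g[, "a"]) & !is.na(g[, "b"]))
  expect_equal(sum(tab$n_case + tab$n_control), analyzed)
  expect_equal(tab$incidence[2, 3],
               tab$n_case[2, 3] / (tab$n_case[2, 3] + tab$n_control[2, 3]))
  expect_equal(tab$uwa, mean(tab$incidence))
  expect_error(incidence_table(g, y, c("a", "a")), "distinct")

  # degenerate: no cases anywhere
  tab0 <- incidence_table(g, rep(0, n), c("a", "b"))
  expect_equal(tab0$uwa, 0)
  expect_true(all(tab0$incidence == 0, na.rm = TRUE))
})

test_that("decomposition equals brute-force unweighted least squares", {
  set.seed(25)
  for (i in 1:1000) {
    tab <- matrix(runif(9), 3, 3)
    d <- epistasis_decompose(tab)
    expect_lt(max(abs(d$effects - ls_residual(tab))), 1e-10)
  }
})

test_that("decomposition has the documented algebraic structure", {
  # additive construction: zero interaction
  r <- c(0.1, 0.2, 0.3); cc <- c(0.05, 0, 0.1)
  tab_add <- outer(r, cc, `+`)
  expect_lt(max(abs(epistasis_decompose(tab_add)$effects)), 1e-12)

  # single perturbed cell: 4/9, -2/9, 1/9 pattern
  tab <- matrix(0.10, 3, 3); tab[1, 1] <- 0.19
  eff <- epistasis_decompose(tab)$effects
  expect_equal(eff[1, 1], 0.04, tolerance = 1e-12)
  expect_equal(eff[1, 2], -0.02, tolerance = 1e-12)
  expect_equal(eff[2, 1], -0.02, tolerance = 1e-12)
  expect_equal(eff[2, 2], 0.01, tolerance = 1e-12)

  # location invariance
  tab2 <- matrix(runif(9), 3, 3)
  expect_equal(epistasis_decompose(tab2)$effects,
               epistasis_decompose(tab2 + 0.17)$effects, tolerance = 1e-12)

  # conservation to machine precision
  expect_equal(rowSums(eff), rep(0, 3), tolerance = 1e-12)
  expect_equal(colSums(eff), rep(0, 3), tolerance = 1e-12)
  expect_equal(sum(eff), 0, tolerance = 1e-12)
})

test_that("effect testing nulls out additive tables and uses the 0.05/9x threshold", {
  set.seed(26)
  n <- 300
  # construct counts whose incidences are exactly additive
  inc <- outer(c(0.1, 0.15, 0.2), c(0, 0.05, 0.1), `+`)
  n_case <- round(inc * n)
  g1 <- rep(rep(0:2, each = 3), times = n)[1:(9 * n)]
  tab <- structure(list(
    defect = "d", pair = c("a", "b"),
    n_case = n_case, n_control = n - n_case,
    incidence = n_case / n, uwa = mean(n_case / n),
    population_incidence = mean(n_case / n),
    empty_cells = matrix(0, 0, 2)
  ), class = "two_locus_table")
  eff <- test_effects(tab, n_pairs_for_defect = 1)
  expect_equal(attr(eff, "threshold"), 0.05 / 9, tolerance = 1e-12)
  expect_false(any(eff$significant & abs(eff$effect) < 1e-3))
  # conservation on the data frame
  expect_equal(sum(eff$effect), 0, tolerance = 1e-12)
  m <- matrix(eff$effect, 3, 3, byrow = TRUE)
  expect_equal(rowSums(m), rep(0, 3), tolerance = 1e-12)
  expect_equal(colSums(m), rep(0, 3), tolerance = 1e-12)
  expect_equal(attr(test_effects(tab, 4), "threshold"), 0.05 / 36)
})

test_that("the arcsine contrast test holds its type-I error under the null", {
  set.seed(27)
  n_cell <- 200
  n_sim <- 10000
  p_add <- as.vector(outer(c(0.10, 0.14, 0.18), c(0, 0.04, 0.08), `+`))
  cases <- matrix(stats::rbinom(n_sim * 9, n_cell, rep(p_add, each = n_sim)),
                  n_sim, 9)
  theta <- asin(sqrt(cases / n_cell))
  lam <- as.vector(t(epicross:::.effect_contrast(1, 1)))
  est <- theta %*% lam
  se <- sqrt(sum(lam^2) / (4 * n_cell))
  pvals <- 2 * stats::pnorm(-abs(est / se))
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_sim) + 0.01)
})

test_that("simulated pair deviations are recovered within sampling error", {
  map <- tiny_map(2, spacing_cM = 1000)  # effectively unlinked loci
  prev_t <- 0
  for (delta in c(0.05, 0.10, 0.15)) {
    dev <- matrix(0, 3, 3)
    dev[1, 1] <- dev[3, 3] <- -delta / 2
    dev[1, 3] <- dev[3, 1] <- delta
    pen <- penetrance_spec(list(
      d = list(baseline = 0.2,
               pair_deviations = stats::setNames(
                 list(dev), paste(map$id, collapse = ":")))
    ))
    truth <- true_epistasis_effects(pen, "d", map$id)
    co <- simulate_cohort(
      cross_design(generations = c(F2 = 4800), mutant_fraction = 1),
      map, pen, seed = round(delta * 1000))
    y <- as.integer(co$individuals$phenotype == "d")
    tab <- incidence_table(co$geno, y, map$id, defect = "d")
    eff <- test_effects(tab, 1)
    # anti-homozygous corner (0,2): compare estimate to matched ground truth
    cell <- eff[eff$g1 == 0 & eff$g2 == 2, ]
    se_inc <- cell$se_asin * 2 * sqrt(cell$observed * (1 - cell$observed))
    expect_lt(abs(cell$effect - truth[1, 3]), 2 * se_inc)
    expect_gt(abs(cell$t), prev_t)   # power grows with delta
    prev_t <- abs(cell$t)
  }
})

test_that("scaled effects preserve sign, sum to zero and reject UWA = 0", {
  eff <- matrix(c(0.04, -0.02, -0.02, -0.02, 0.01, 0.01,
                  -0.02, 0.01, 0.01), 3, 3, byrow = TRUE)
  sc <- scale_effects(eff, 0.11)
  expect_equal(sc[1, 1], 0.04 / 0.11, tolerance = 1e-12)
  expect_equal(round(sc[1, 1], 4), 0.3636)
  expect_equal(sum(sc), 0, tolerance = 1e-12)
  expect_equal(sc * 0.11, eff, tolerance = 1e-12)
  expect_error(scale_effects(eff, 0), "positive")
})

test_that("partner markers are the best eligible runner-up outside 10 Mb", {
  scan <- data.frame(
    marker = c("top", "shoulder", "runner", "third"),
    chromosome = c(5, 5, 6, 13),
    position_bp = c(50e6, 55e6, 80e6, 10e6),
    p = c(1e-8, 1e-6, 1.94e-3, 2.39e-3),
    stringsAsFactors = FALSE
  )
  expect_equal(partner_snp(scan, "top"), "runner")   # shoulder excluded (5 Mb)
  expect_equal(partner_snp(scan, c("top", "runner")), "third")
  expect_error(partner_snp(scan, scan$marker), "no eligible")
  expect_error(partner_snp(scan[0, ], "x"), "empty scan")
})

test_that("zero-count cells abort testing with a report", {
  tab <- structure(list(
    defect = "d", pair = c("a", "b"),
    n_case = matrix(c(0L, rep(5L, 8)), 3, 3),
    n_control = matrix(c(0L, rep(15L, 8)), 3, 3),
    incidence = matrix(c(NA, rep(0.25, 8)), 3, 3),
    uwa = NA_real_, population_incidence = 0.25,
    empty_cells = matrix(c(1L, 1L), 1, 2)
  ), class = "two_locus_table")
  expect_error(test_effects(tab, 1), "empty cell|zero-count")
})
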