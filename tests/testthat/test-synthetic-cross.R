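test_that("Haldane map function matches its closed form and limits", {
  expect_identical(haldane_recomb(0), 0)
  expect_equal(haldane_recomb(50), 0.31606, tolerance = 1e-5)
  expect_equal(haldane_recomb(10000), 0.5, tolerance = 1e-12)
  d <- seq(0, 200, by = 5)
  expect_true(all(diff(haldane_recomb(d)) > 0))
  expect_true(all(haldane_recomb(d) < 0.5))
  expect_error(haldane_recomb(-1), "non-negative")
})

test_that("F2 genotype frequencies are Mendelian and cohorts deterministic", {
  co <- quick_f2(n = 3000, seed = 42)
  for (j in c(5, 60, 120)) {
    freq <- tabulate(co$geno[, j] + 1L, 3) / nrow(co$geno)
    se <- sqrt(c(.25 * .75, .5 * .5, .25 * .75) / nrow(co$geno))
    expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 3 * se))
  }
  co2 <- quick_f2(n = 3000, seed = 42)
  expect_identical(co$geno, co2$geno)
  expect_identical(co$individuals, co2$individuals)
})

test_that("baseline penetrance is recovered binomially among mutants", {
  map <- make_marker_panel(20)
  co <- simulate_cohort(
    cross_design(generations = c(F2 = 10000)),
    map,
    penetrance_spec(list(ASD = list(baseline = 0.137))),
    seed = 7
  )
  mut <- co$individuals$mutant
  n_mut <- sum(mut)
  frac <- mean(co$individuals$phenotype[mut] == "ASD")
  expect_lt(abs(frac - 0.137), 3 * sqrt(0.137 * 0.863 / n_mut))
  # non-mutants never receive a defect; mutant fraction is Mendelian
  expect_true(all(co$individuals$phenotype[!mut] == "normal"))
  expect_lt(abs(mean(mut) - 0.5), 3 * sqrt(0.25 / nrow(co$geno)))
})

test_that("defects are mutually exclusive and keep their incidence ordering", {
  co <- simulate_cohort(
    cross_design(generations = c(F2 = 8000)), make_marker_panel(20),
    default_penetrance(), seed = 3
  )
  mut <- co$individuals[co$individuals$mutant, ]
  expect_true(all(mut$phenotype %in%
                    c("normal", "ASD", "membranous_VSD", "muscular_VSD", "AVSD")))
  inc <- table(factor(mut$phenotype,
                      c("ASD", "membranous_VSD", "muscular_VSD", "AVSD")))
  expect_true(all(diff(as.numeric(inc)) < 0))  # ASD most common ... AVSD rarest
  affected <- mean(mut$phenotype != "normal")
  expect_lt(abs(affected - 0.30), 0.03)
})

test_that("invalid realized penetrances are rejected with the genotype reported", {
  map <- tiny_map(3)
  pen <- penetrance_spec(list(
    bad = list(baseline = 0.9,
               locus_effects = stats::setNames(list(c(0, 0, 0.2)), map$id[1]))
  ))
  expect_error(
    simulate_cohort(cross_design(generations = c(F2 = 200)), map, pen, seed = 1),
    "outside \\[0,1\\]"
  )
})

test_that("advanced intercross expands the map without losing heterozygosity", {
  map <- make_marker_panel(10)
  co <- simulate_cohort(
    cross_design(strains = c("B", "F"),
                 generations = c(F2 = 400, F10 = 400)),
    map, penetrance_spec(list(defect = list(baseline = 0.1))), seed = 5
  )
  gen <- co$individuals$generation
  chr1 <- co$geno[, map$chromosome == 1]
  # empirical recombinant (adjacent-genotype-change) fraction grows F2 -> F10
  rf <- function(rows) mean(abs(diff(t(chr1[rows, ]))) > 0)
  expect_gt(rf(gen == "F10"), rf(gen == "F2"))
  # random mating keeps heterozygosity near 1/2 (no inbreeding collapse)
  het_f10 <- mean(co$geno[gen == "F10", ] == 1)
  expect_gt(het_f10, 0.40)
  expect_lt(het_f10, 0.60)
})

test_that("ground-truth interaction effects equal the decomposition of the exact table", {
  map <- tiny_map(4)
  dev <- matrix(c(0.05, 0, -0.02, 0, 0, 0, -0.02, 0, 0.03), 3, 3)
  pen <- penetrance_spec(list(
    AVSD = list(
      baseline = 0.1,
      locus_effects = stats::setNames(
        list(c(-0.02, 0, 0.02), c(0.01, 0, -0.01)), map$id[c(1, 3)]),
      pair_deviations = stats::setNames(list(dev),
                                        paste(map$id[1], map$id[3], sep = ":"))
    )
  ))
  eff <- true_epistasis_effects(pen, "AVSD", map$id[c(1, 3)])
  expect_equal(rowSums(eff), rep(0, 3), tolerance = 1e-12)
  expect_equal(colSums(eff), rep(0, 3), tolerance = 1e-12)
  # additive architecture: no interaction
  eff0 <- true_epistasis_effects(pen, "AVSD", map$id[c(1, 2)])
  expect_equal(max(abs(eff0)), 0, tolerance = 1e-12)
  # closure with the estimator-side decomposition on the exact table
  tab <- matrix(0.1, 3, 3) +
    matrix(c(-0.02, 0, 0.02), 3, 3) +
    matrix(c(0.01, 0, -0.01), 3, 3, byrow = TRUE) + dev
  expect_equal(epistasis_decompose(tab)$effects, eff, tolerance = 1e-12)
  expect_error(true_epistasis_effects(pen, "nope", map$id[c(1, 3)]), "unknown defect")
})

test_that("single-cell penetrance offset decomposes to the 4/9, -2/9, 1/9 pattern", {
  delta <- 0.06
  map <- tiny_map(3)
  pen <- penetrance_spec(list(
    d = list(baseline = 0.2,
             pair_deviations = stats::setNames(
               list(matrix(c(delta, rep(0, 8)), 3, 3)),
               paste(map$id[1], map$id[2], sep = ":")))
  ))
  eff <- true_epistasis_effects(pen, "d", map$id[1:2])
  expect_equal(eff[1, 1], 4 * delta / 9, tolerance = 1e-12)
  expect_equal(eff[1, 2], -2 * delta / 9, tolerance = 1e-12)
  expect_equal(eff[2, 1], -2 * delta / 9, tolerance = 1e-12)
  expect_equal(eff[2, 2], delta / 9, tolerance = 1e-12)
})

test_that("genotype masking hits the requested rate and keeps the truth", {
  co <- quick_f2(n = 800, seed = 2)
  expect_identical(mask_genotypes(co, 0, seed = 1)$cohort$geno, co$geno)
  m <- mask_genotypes(co, 0.05, seed = 9)
  n_calls <- length(co$geno)
  frac <- nrow(m$mask) / n_calls
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n_calls))
  expect_true(all(is.na(m$cohort$geno[cbind(m$mask$row,
                                            match(m$mask$marker,
                                                  colnames(co$geno)))])))
  # truth recoverable for every masked entry
  expect_identical(m$mask$truth,
                   co$geno[cbind(m$mask$row,
                                 match(m$mask$marker, colnames(co$geno)))])
  expect_error(mask_genotypes(co, 1, seed = 1), "rate")
})

test_that("marker maps reject disordered or sex-chromosome input", {
  expect_error(marker_map("a", 20, 1e6, 1), "autosomes")
  expect_error(marker_map(c("a", "b"), c(1, 1), c(2e6, 1e6), c(2, 1)),
               NA)  # constructor sorts by position
  expect_error(marker_map(c("a", "b"), c(1, 1), c(1e6, 1e6), c(1, 2)),
               "strictly increasing")
  expect_error(marker_map(c("a", "a"), c(1, 1), c(1e6, 2e6), c(1, 2)),
               "unique")
})
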