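test_that("two-locus genotype classes partition the Punnett square 2/2/1/4", {
  expect_equal(classify_two_locus(0, 0), "syn_homozygous")
  expect_equal(classify_two_locus(2, 2), "syn_homozygous")
  expect_equal(classify_two_locus(0, 2), "anti_homozygous")
  expect_equal(classify_two_locus(2, 0), "anti_homozygous")
  expect_equal(classify_two_locus(1, 1), "double_heterozygous")
  expect_equal(classify_two_locus(1, 0), "mixed")
  expect_equal(classify_two_locus(0, 1), "mixed")

  grid <- expand.grid(g1 = 0:2, g2 = 0:2)
  cls <- classify_two_locus(grid$g1, grid$g2)
  expect_equal(sort(as.numeric(table(cls)), decreasing = TRUE), c(4, 2, 2, 1))
  # symmetric under locus exchange
  expect_equal(cls, classify_two_locus(grid$g2, grid$g1))
  # flipping one locus's strain coding swaps syn and anti only
  flipped <- classify_two_locus(2 - grid$g1, grid$g2)
  swap <- c(syn_homozygous = "anti_homozygous",
            anti_homozygous = "syn_homozygous",
            double_heterozygous = "double_heterozygous",
            mixed = "mixed")
  expect_equal(flipped, unname(swap[cls]))
  expect_error(classify_two_locus(NA, 1), "missing|0, 1 or 2")
})

test_that("protective fractions and their z-tests follow the closed form", {
  mk_eff <- function(class, effect, sig = TRUE) {
    data.frame(defect = "d", locus1 = "a", locus2 = "b",
               g1 = 0, g2 = 0, effect = effect, significant = sig,
               class = class, stringsAsFactors = FALSE)
  }
  eff <- do.call(rbind, c(
    lapply(1:12, function(i) mk_eff("syn_homozygous", -0.1)),
    lapply(1:4, function(i) mk_eff("syn_homozygous", 0.1)),
    lapply(1:8, function(i) mk_eff("anti_homozygous", 0.1)),
    lapply(1:8, function(i) mk_eff("anti_homozygous", -0.1))
  ))
  res <- protective_fractions(eff)
  syn <- res$by_class[res$by_class$class == "syn_homozygous", ]
  expect_equal(syn$fraction_protective, 0.75)
  expect_equal(syn$z, 2, tolerance = 1e-12)
  expect_equal(syn$p, 0.0455, tolerance = 1e-3)
  anti <- res$by_class[res$by_class$class == "anti_homozygous", ]
  expect_equal(anti$z, 0)
  expect_equal(anti$p, 1)
  dh <- res$by_class[res$by_class$class == "double_heterozygous", ]
  expect_equal(dh$n, 0L)
  expect_true(is.na(dh$fraction_protective))
  expect_equal(res$syn_anti_ratio, 0.75 / 0.5)
})

test_that("syn-protective architectures are recovered directionally", {
  map <- tiny_map(2, spacing_cM = 1000)
  dev <- matrix(0, 3, 3)
  dev[1, 1] <- dev[3, 3] <- -0.10
  dev[1, 3] <- dev[3, 1] <- 0.12
  pen <- penetrance_spec(list(
    d = list(baseline = 0.2,
             pair_deviations = stats::setNames(
               list(dev), paste(map$id, collapse = ":")))
  ))
  co <- simulate_cohort(
    cross_design(generations = c(F2 = 6000), mutant_fraction = 1),
    map, pen, seed = 31)
  y <- as.integer(co$individuals$phenotype == "d")
  eff <- test_effects(incidence_table(co$geno, y, map$id, "d"), 1)
  res <- protective_fractions(eff)
  syn <- res$by_class[res$by_class$class == "syn_homozygous", ]
  anti <- res$by_class[res$by_class$class == "anti_homozygous", ]
  expect_gt(syn$n, 0)
  expect_gt(anti$n, 0)
  expect_gt(syn$fraction_protective, 0.5)
  expect_lt(anti$fraction_protective, 0.5)
})

test_that("congruence tallies count pairs and respect the significance filter", {
  mk_pair <- function(pair_id, syn_eff, anti_eff, sig_all = TRUE) {
    grid <- expand.grid(g1 = 0:2, g2 = 0:2)
    cls <- classify_two_locus(grid$g1, grid$g2)
    eff <- ifelse(cls == "syn_homozygous", syn_eff,
                  ifelse(cls == "anti_homozygous", anti_eff, 0.01))
    data.frame(defect = "d", locus1 = paste0("a", pair_id),
               locus2 = paste0("b", pair_id),
               g1 = grid$g1, g2 = grid$g2, effect = eff,
               significant = sig_all | cls %in%
                 c("syn_homozygous", "anti_homozygous"),
               class = cls, stringsAsFactors = FALSE)
  }
  # perfectly congruent: protective syn everywhere, deleterious anti
  eff <- do.call(rbind, lapply(1:6, function(i) mk_pair(i, -0.05, 0.08)))
  res <- congruence_tests(eff)
  syn_row <- res[res$anchor == "protective_syn" & res$companion == "other_syn", ]
  expect_equal(syn_row$n_pairs, 6L)
  expect_equal(syn_row$proportion, 1)

  # anchor not significant -> pair leaves the denominator
  eff2 <- eff
  eff2$significant[eff2$class == "syn_homozygous" &
                     eff2$locus1 == "a1"] <- FALSE
  res2 <- congruence_tests(eff2)
  syn_row2 <- res2[res2$anchor == "protective_syn" &
                     res2$companion == "other_syn", ]
  expect_equal(syn_row2$n_pairs, 5L)

  # random signs across many pairs: proportions near 1/2
  set.seed(32)
  eff3 <- do.call(rbind, lapply(1:400, function(i) {
    mk_pair(i, sample(c(-0.05, 0.05), 1), sample(c(-0.08, 0.08), 1))
  }))
  res3 <- congruence_tests(eff3)
  anti_row <- res3[res3$anchor == "protective_syn" & res3$companion == "anti", ]
  expect_gt(anti_row$n_pairs, 50)
  # companion = both anti cells share one sign here, so congruence is a
  # fair coin over pairs
  expect_lt(abs(anti_row$proportion - 0.5),
            3 * sqrt(0.25 / anti_row$n_pairs))

  # no anchors at all
  eff4 <- mk_pair(1, 0.05, -0.08)   # syn deleterious, anti protective
  res4 <- congruence_tests(eff4)
  expect_equal(nrow(res4), 0L)
})
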