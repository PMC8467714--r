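#' Classify a two-locus genotype by strain-origin configuration
#'
#' The nine genotype combinations fall into four classes: syn-homozygous
#' (both loci homozygous for alleles of the same parental strain, 2
#' cells), anti-homozygous (homozygous for opposite strains, 2 cells),
#' double-heterozygous (1 cell), and mixed (exactly one locus
#' heterozygous, 4 cells).
#'
#' @param g1,g2 Genotype codes in 0/1/2 (vectorized).
#' @return Character vector: "syn_homozygous", "anti_homozygous",
#'   "double_heterozygous" or "mixed".
#' @export
classify_two_locus <- function(g1, g2) {
  if (anyNA(g1) || anyNA(g2) || !all(g1 %in% 0:2) || !all(g2 %in% 0:2)) {
    stop("genotype codes must be 0, 1 or 2 (no missing)")
  }
  out <- rep("mixed", length(g1))
  out[g1 == 1 & g2 == 1] <- "double_heterozygous"
  both_hom <- g1 != 1 & g2 != 1
  out[both_hom & g1 == g2] <- "syn_homozygous"
  out[both_hom & g1 != g2] <- "anti_homozygous"
  out
}

#' Protective fractions of significant interaction effects by class
#'
#' Among significant higher-order interaction effects, computes per
#' genotype class the fraction that is protective (negative effect,
#' lowering risk), tests it against 0.5 by a two-sided one-sample z-test,
#' and compares classes pairwise by two-sample z-tests. Detects whether
#' same-strain homozygosity is disproportionately protective.
#'
#' @param effects An `epistasis_effects` data frame (or rbind of several),
#'   typically filtered downstream; only rows with `significant = TRUE`
#'   enter the summary.
#' @return List with `by_class` (class, n significant, n protective,
#'   fraction, z, p; empty classes flagged with NA), `pairwise` (z-tests
#'   between classes), and `syn_anti_ratio` (syn / anti protective
#'   fraction, NA when undefined).
#' @export
protective_fractions <- function(effects) {
  sig <- effects[effects$significant, , drop = FALSE]
  classes <- c("syn_homozygous", "anti_homozygous",
               "double_heterozygous", "mixed")
  by_class <- do.call(rbind, lapply(classes, function(cl) {
    e <- sig[sig$class == cl, , drop = FALSE]
    n <- nrow(e)
    k <- sum(e$effect < 0)
    if (n == 0) {
      return(data.frame(class = cl, n = 0L, n_protective = 0L,
                        fraction_protective = NA_real_,
                        z = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    zt <- prop_ztest(k, n, p0 = 0.5)
    data.frame(class = cl, n = n, n_protective = k,
               fraction_protective = k / n, z = zt$z, p = zt$p,
               stringsAsFactors = FALSE)
  }))
  combs <- utils::combn(classes, 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
    a <- by_class[by_class$class == combs[1, i], ]
    b <- by_class[by_class$class == combs[2, i], ]
    if (a$n == 0 || b$n == 0) {
      return(data.frame(class1 = combs[1, i], class2 = combs[2, i],
                        z = NA_real_, p = NA_real_))
    }
    zt <- prop_ztest(a$n_protective, a$n, b$n_protective, b$n)
    data.frame(class1 = combs[1, i], class2 = combs[2, i],
               z = zt$z, p = zt$p)
  }))
  syn <- by_class$fraction_protective[by_class$class == "syn_homozygous"]
  anti <- by_class$fraction_protective[by_class$class == "anti_homozygous"]
  ratio <- if (!is.na(syn) && !is.na(anti) && anti > 0) syn / anti else NA_real_
  list(by_class = by_class, pairwise = pairwise, syn_anti_ratio = ratio)
}

#' Congruence of syn-/anti-homozygous effects within locus pairs
#'
#' For each locus pair, anchors on (a) a significant protective
#' syn-homozygous cell and (b) a significant deleterious anti-homozygous
#' cell, and asks whether the companion cells behave congruently: a
#' protective syn cell predicting a protective effect at the other syn
#' cell and deleterious effects at the two anti cells, and vice versa.
#' Denominators count locus pairs (each pair contributes once per
#' anchor), and companion cells are only scored where they are themselves
#' significant.
#'
#' @param effects An `epistasis_effects` data frame covering one or more
#'   locus pairs (all 9 cells each).
#' @return Data frame: anchor, companion, n_pairs, n_congruent,
#'   proportion, z and p against 0.5; zero rows when no anchors exist.
#' @export
congruence_tests <- function(effects) {
  key <- paste(effects$defect, effects$locus1, effects$locus2)
  out <- list()
  tally <- function(anchor, companion) {
    n <- 0L; congr <- 0L
    for (k in unique(key)) {
      e <- effects[key == k, , drop = FALSE]
      syn <- e[e$class == "syn_homozygous", ]
      anti <- e[e$class == "anti_homozygous", ]
      anch <- switch(anchor,
        protective_syn = syn[syn$significant & syn$effect < 0, ],
        deleterious_anti = anti[anti$significant & anti$effect > 0, ])
      if (!nrow(anch)) next
      comp <- switch(companion,
        other_syn = {
          a <- anch[1, ]
          syn[!(syn$g1 == a$g1 & syn$g2 == a$g2) & syn$significant, ]
        },
        anti = anti[anti$significant, ],
        other_anti = {
          a <- anch[1, ]
          anti[!(anti$g1 == a$g1 & anti$g2 == a$g2) & anti$significant, ]
        })
      if (!nrow(comp)) next
      n <- n + 1L
      expected_sign <- switch(paste(anchor, companion),
        "protective_syn other_syn" = -1,
        "protective_syn anti" = 1,
        "deleterious_anti other_anti" = 1,
        "deleterious_anti anti" = 1)
      if (all(sign(comp$effect) == expected_sign)) congr <- congr + 1L
    }
    if (n == 0) return(NULL)
    zt <- prop_ztest(congr, n, p0 = 0.5)
    data.frame(anchor = anchor, companion = companion,
               n_pairs = n, n_congruent = congr,
               proportion = congr / n, z = zt$z, p = zt$p,
               stringsAsFactors = FALSE)
  }
  out <- rbind(tally("protective_syn", "other_syn"),
               tally("protective_syn", "anti"),
               tally("deleterious_anti", "other_anti"))
  if (is.null(out)) {
    out <- data.frame(anchor = character(0), companion = character(0),
                      n_pairs = integer(0), n_congruent = integer(0),
                      proportion = numeric(0), z = numeric(0),
                      p = numeric(0))
  }
  out
}
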