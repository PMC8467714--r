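#' Haldane map function
#'
#' Converts a genetic map distance to a recombination fraction under the
#' Haldane (no-interference) model, r = (1 - exp(-2d))/2 with d in Morgans.
#'
#' @param distance_cM Numeric vector of non-negative map distances in
#'   centimorgans.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' haldane_recomb(c(0, 10, 50))
#' @export
haldane_recomb <- function(distance_cM) {
  if (!is.numeric(distance_cM) || any(!is.finite(distance_cM)) ||
      any(distance_cM < 0)) {
    stop("`distance_cM` must be finite and non-negative")
  }
  (1 - exp(-2 * distance_cM / 100)) / 2
}

#' Approximate mouse autosome lengths
#'
#' Physical lengths (Mb) of the 19 mouse autosomes, used by the default
#' marker panels. Sex chromosomes are excluded throughout.
#'
#' @return Named numeric vector of lengths in Mb for chromosomes 1-19.
#' @export
mouse_autosome_lengths <- function() {
  stats::setNames(
    c(195, 182, 160, 157, 152, 150, 145, 129, 124, 131,
      122, 120, 120, 125, 104, 98, 95, 91, 61),
    paste0("chr", 1:19)
  )
}

#' Construct a marker map
#'
#' @param id Character vector of unique marker names.
#' @param chromosome Integer vector in 1-19 (autosomes only).
#' @param position_bp Integer physical positions (1-based bp).
#' @param position_cM Numeric genetic positions (cM, >= 0).
#' @return A `marker_map` data frame sorted by chromosome and position.
#' @export
marker_map <- function(id, chromosome, position_bp, position_cM) {
  if (anyDuplicated(id)) stop("marker ids must be unique")
  if (any(!(chromosome %in% 1:19))) {
    stop("chromosomes must be autosomes 1-19 (sex chromosomes unsupported)")
  }
  if (any(position_cM < 0)) stop("cM positions must be non-negative")
  map <- data.frame(
    id = as.character(id), chromosome = as.integer(chromosome),
    position_bp = round(as.numeric(position_bp)),
    position_cM = as.numeric(position_cM),
    stringsAsFactors = FALSE
  )
  map <- map[order(map$chromosome, map$position_bp), , drop = FALSE]
  rownames(map) <- NULL
  for (ch in unique(map$chromosome)) {
    sub <- map[map$chromosome == ch, ]
    if (any(diff(sub$position_bp) <= 0)) {
      stop("bp positions must be strictly increasing within chromosome ", ch)
    }
    if (any(diff(sub$position_cM) <= 0)) {
      stop("cM positions must be strictly increasing within chromosome ", ch)
    }
  }
  class(map) <- c("marker_map", "data.frame")
  map
}

#' Build an evenly spaced autosomal marker panel
#'
#' Generates a panel with markers every `spacing_mb` megabases along each
#' autosome, converting physical to genetic distance at a constant rate
#' (default 0.5 cM/Mb, the genome-wide mouse average). A spacing of ~20 Mb
#' mimics a sparse custom genotyping panel; ~3 Mb mimics a dense linkage
#' panel.
#'
#' @param spacing_mb Marker spacing in Mb.
#' @param cm_per_mb Genetic-to-physical rate in cM/Mb.
#' @param prefix Marker name prefix.
#' @return A [marker_map()].
#' @export
make_marker_panel <- function(spacing_mb = 20, cm_per_mb = 0.5, prefix = "m") {
  lens <- mouse_autosome_lengths()
  rows <- lapply(seq_along(lens), function(ch) {
    pos_mb <- seq(spacing_mb / 2, lens[ch], by = spacing_mb)
    data.frame(chromosome = ch, position_mb = pos_mb)
  })
  d <- do.call(rbind, rows)
  idx_within <- stats::ave(seq_len(nrow(d)), d$chromosome, FUN = seq_along)
  marker_map(
    id = sprintf("%s%02d.%03d", prefix, d$chromosome, idx_within),
    chromosome = d$chromosome,
    position_bp = round(d$position_mb * 1e6),
    position_cM = d$position_mb * cm_per_mb
  )
}

#' Define a two-strain cross design
#'
#' @param strains Two single-letter strain codes; the first is the reference
#'   strain (genotype code 0 counts alleles of the second strain).
#' @param generations Named integer vector of output cohort sizes, names
#'   from "F2", "F10", "F14" (e.g. `c(F2 = 3000)`).
#' @param mutant_fraction Fraction of offspring carrying the heterozygous
#'   mutation (Mendelian default 0.5).
#' @param n_breeding_pairs Census size (breeding pairs) maintained per
#'   advanced-intercross generation.
#' @return A `cross_design` list.
#' @export
cross_design <- function(strains = c("B", "A"),
                         generations = c(F2 = 3000),
                         mutant_fraction = 0.5,
                         n_breeding_pairs = 100) {
  if (length(strains) != 2 || anyDuplicated(strains)) {
    stop("`strains` must be two distinct codes")
  }
  labs <- names(generations)
  if (is.null(labs) || !all(labs %in% c("F2", "F10", "F14")) ||
      anyDuplicated(labs)) {
    stop("`generations` must be uniquely named from F2, F10, F14")
  }
  if (any(generations <= 0)) stop("generation sizes must be positive")
  if (mutant_fraction < 0 || mutant_fraction > 1) {
    stop("`mutant_fraction` must lie in [0, 1]")
  }
  structure(
    list(strains = as.character(strains),
         generations = generations,
         mutant_fraction = mutant_fraction,
         n_breeding_pairs = as.integer(n_breeding_pairs)),
    class = "cross_design"
  )
}

#' Specify defect penetrances with a known genetic architecture
#'
#' Penetrance acts on the probability scale: the probability that a mutant
#' individual develops defect `d` is
#' `baseline + sum(locus effects at its genotypes) + sum(pair deviations)`.
#' Because deviations add on the probability scale, the ground-truth
#' higher-order interaction at a locus pair is exactly the main-effects
#' residual of the implied 3x3 penetrance table (see
#' [true_epistasis_effects()]).
#'
#' @param defects Named list; one element per defect type, each a list with
#'   `baseline` (probability), optional `locus_effects` (named list of
#'   3-vectors of probability offsets indexed by genotype 0/1/2), and
#'   optional `pair_deviations` (named list; names "id1:id2", each a 3x3
#'   matrix of probability offsets, rows = genotype at id1).
#' @return A `penetrance_spec` object. Defect order is the assignment
#'   order: at most one defect per individual, drawn by partitioning a
#'   single uniform draw so each defect keeps its exact marginal
#'   penetrance.
#' @export
penetrance_spec <- function(defects) {
  if (is.null(names(defects)) || anyDuplicated(names(defects))) {
    stop("`defects` must be a uniquely named list")
  }
  for (nm in names(defects)) {
    d <- defects[[nm]]
    if (is.null(d$baseline) || d$baseline < 0 || d$baseline > 1) {
      stop("defect ", nm, ": baseline must be a probability")
    }
    for (le in d$locus_effects) {
      if (length(le) != 3) stop("defect ", nm, ": locus effects must be 3-vectors")
    }
    for (pd in d$pair_deviations) {
      if (!is.matrix(pd) || !all(dim(pd) == c(3, 3))) {
        stop("defect ", nm, ": pair deviations must be 3x3 matrices")
      }
    }
  }
  structure(list(defects = defects), class = "penetrance_spec")
}

#' Default defect penetrances
#'
#' Baseline penetrances chosen so defect incidences among mutants follow
#' the observed ordering ASD > membranous VSD > muscular VSD > AVSD with
#' roughly 30% of mutants affected overall.
#'
#' @param locus_effects,pair_deviations Optional architecture, passed per
#'   defect as in [penetrance_spec()].
#' @return A `penetrance_spec`.
#' @export
default_penetrance <- function(locus_effects = NULL, pair_deviations = NULL) {
  base <- list(
    ASD = list(baseline = 0.13),
    membranous_VSD = list(baseline = 0.08),
    muscular_VSD = list(baseline = 0.055),
    AVSD = list(baseline = 0.035)
  )
  for (nm in names(locus_effects)) base[[nm]]$locus_effects <- locus_effects[[nm]]
  for (nm in names(pair_deviations)) base[[nm]]$pair_deviations <- pair_deviations[[nm]]
  penetrance_spec(base)
}

# Recombination fractions between consecutive panel markers; 0.5 across
# chromosome boundaries. `expansion` scales cM distances (map expansion in
# advanced-intercross generations).
.adjacent_recomb <- function(map, expansion = 1) {
  m <- nrow(map)
  if (m < 2) return(numeric(0))
  d <- diff(map$position_cM) * expansion
  r <- haldane_recomb(pmax(d, 0))
  r[diff(map$chromosome) != 0] <- 0.5
  r
}

# One meiosis per row of the haplotype pair (h1, h2): origin chains start
# at random and switch between adjacent markers with the given
# recombination fractions.
.meiosis <- function(h1, h2, r) {
  n <- nrow(h1); m <- ncol(h1)
  o <- matrix(0L, n, m)
  o[, 1] <- sample(0:1, n, replace = TRUE)
  if (m > 1) {
    sw <- matrix(stats::rbinom(n * (m - 1), 1L, rep(r, each = n)), n, m - 1)
    o[, -1] <- sw
    o <- matrix(as.integer(.rowcum_mod2(o)), n, m)
  }
  ifelse(o == 0L, h1, h2)
}

# Row-wise cumulative XOR (mod-2 cumsum) across columns.
.rowcum_mod2 <- function(x) {
  for (j in seq_len(ncol(x))[-1]) x[, j] <- (x[, j - 1] + x[, j]) %% 2L
  x
}

# F1 gametes: the F1 is heterozygous everywhere, so a gamete is the origin
# chain itself.
.f1_gametes <- function(n, m, r) {
  .meiosis(matrix(0L, n, m), matrix(1L, n, m), r)
}

# Random non-sib pairing of individuals 1..n with sibship labels.
.pair_non_sibs <- function(sibship) {
  n <- length(sibship)
  for (attempt in 1:200) {
    perm <- sample.int(n)
    a <- perm[seq(1, n, by = 2)]
    b <- perm[seq(2, n, by = 2)]
    ok <- sibship[a] != sibship[b]
    if (all(ok)) return(cbind(a, b))
    # retry only the clashing pairs by reshuffling everything
  }
  stop("could not form non-sib breeding pairs")
}

#' Simulate a cohort of mutant-cross offspring
#'
#' Simulates F2 (and optionally advanced-intercross F10/F14) offspring of a
#' two-strain cross, assigns the heterozygous mutation at the Mendelian
#' ratio, and draws at most one binary defect per mutant from its
#' genotype-determined penetrances. F2 individuals are unions of two
#' independent F1 gametes; advanced-intercross generations arise by random
#' non-sib mating from the F2 onward at a fixed census size, with meiosis
#' under the Haldane model throughout.
#'
#' @param design A [cross_design()].
#' @param map A [marker_map()].
#' @param penetrance A [penetrance_spec()]; all referenced markers must be
#'   on the map.
#' @param seed Integer seed; the simulation is deterministic given it.
#' @return A `cohort`: list with `individuals` (data frame of id,
#'   generation, cross, mutant flag, phenotype), `geno` (individuals x
#'   markers integer matrix, 0 = homozygous reference strain, 1 =
#'   heterozygous, 2 = homozygous other strain, NA = missing), and `map`.
#' @export
simulate_cohort <- function(design, map, penetrance, seed) {
  stopifnot(inherits(design, "cross_design"), inherits(map, "marker_map"),
            inherits(penetrance, "penetrance_spec"))
  ref <- unlist(lapply(penetrance$defects, function(d) {
    c(names(d$locus_effects),
      if (length(d$pair_deviations)) {
        unlist(strsplit(names(d$pair_deviations), ":", fixed = TRUE))
      })
  }))
  if (!all(ref %in% map$id)) {
    stop("penetrance references markers absent from the map: ",
         paste(setdiff(ref, map$id), collapse = ", "))
  }
  set.seed(seed)
  m <- nrow(map)
  r <- .adjacent_recomb(map)
  cross_label <- paste0(design$strains[2], "x", design$strains[1])

  want <- design$generations
  out_geno <- list(); out_gen <- character(0)

  n_f2 <- if ("F2" %in% names(want)) want[["F2"]] else 0L
  if (n_f2 > 0) {
    g_f2 <- .f1_gametes(n_f2, m, r) + .f1_gametes(n_f2, m, r)
    out_geno$F2 <- g_f2
    out_gen <- c(out_gen, rep("F2", n_f2))
  }

  aic_gens <- sort(as.integer(sub("F", "", setdiff(names(want), "F2"))))
  if (length(aic_gens)) {
    n_census <- 2L * design$n_breeding_pairs
    # breeding population at F2
    h1 <- .f1_gametes(n_census, m, r)
    h2 <- .f1_gametes(n_census, m, r)
    sib <- seq_len(n_census)  # F2 from distinct random F1 gametes: no sibships tracked
    gen <- 2L
    for (target in aic_gens) {
      while (gen < target) {
        pairs <- .pair_non_sibs(sib)
        n_pairs <- nrow(pairs)
        next_t <- gen + 1L
        produce <- if (next_t == target) want[[paste0("F", target)]] else 0L
        # census offspring (2 per pair) continue the line; sampled offspring
        # form the output cohort for the target generation
        idx_census <- rep(seq_len(n_pairs), each = 2L)
        nh1 <- .meiosis(h1[pairs[idx_census, 1], , drop = FALSE],
                        h2[pairs[idx_census, 1], , drop = FALSE],
                        r)
        nh2 <- .meiosis(h1[pairs[idx_census, 2], , drop = FALSE],
                        h2[pairs[idx_census, 2], , drop = FALSE],
                        r)
        nsib <- idx_census
        if (produce > 0) {
          idx_out <- sample.int(n_pairs, produce, replace = TRUE)
          oh1 <- .meiosis(h1[pairs[idx_out, 1], , drop = FALSE],
                          h2[pairs[idx_out, 1], , drop = FALSE], r)
          oh2 <- .meiosis(h1[pairs[idx_out, 2], , drop = FALSE],
                          h2[pairs[idx_out, 2], , drop = FALSE], r)
          out_geno[[paste0("F", target)]] <- oh1 + oh2
          out_gen <- c(out_gen, rep(paste0("F", target), produce))
        }
        h1 <- nh1; h2 <- nh2; sib <- nsib
        gen <- next_t
      }
    }
  }

  geno <- do.call(rbind, out_geno)
  colnames(geno) <- map$id
  n <- nrow(geno)
  ids <- sprintf("%s_%s_%05d", cross_label, out_gen, stats::ave(seq_len(n), out_gen, FUN = seq_along))
  mutant <- stats::rbinom(n, 1L, design$mutant_fraction) == 1L

  pheno <- .assign_defects(geno, mutant, penetrance, map)

  individuals <- data.frame(
    id = ids, generation = out_gen, cross = cross_label,
    mutant = mutant, phenotype = pheno, stringsAsFactors = FALSE
  )
  rownames(geno) <- ids
  structure(list(individuals = individuals, geno = geno, map = map),
            class = "cohort")
}

# Draw phenotypes: a single uniform per mutant is partitioned into
# consecutive intervals, one per defect, so each defect keeps its exact
# genotype-conditional penetrance and defects stay mutually exclusive.
.assign_defects <- function(geno, mutant, penetrance, map) {
  n <- nrow(geno)
  pheno <- rep("normal", n)
  defs <- penetrance$defects
  p <- matrix(0, n, length(defs), dimnames = list(NULL, names(defs)))
  for (k in seq_along(defs)) {
    d <- defs[[k]]
    pk <- rep(d$baseline, n)
    for (mk in names(d$locus_effects)) {
      g <- geno[, mk]
      pk <- pk + d$locus_effects[[mk]][g + 1L]
    }
    for (pr in names(d$pair_deviations)) {
      ids <- strsplit(pr, ":", fixed = TRUE)[[1]]
      g1 <- geno[, ids[1]]; g2 <- geno[, ids[2]]
      pk <- pk + d$pair_deviations[[pr]][cbind(g1 + 1L, g2 + 1L)]
    }
    if (any(pk < 0 | pk > 1, na.rm = TRUE)) {
      bad <- which(pk < 0 | pk > 1)[1]
      stop("realized penetrance for ", names(defs)[k], " outside [0,1] at ",
           "individual ", bad, " (value ", signif(pk[bad], 4), ")")
    }
    p[, k] <- pk
  }
  tot <- rowSums(p)
  if (any(tot > 1, na.rm = TRUE)) {
    stop("total defect probability exceeds 1 for some genotype")
  }
  u <- stats::runif(n)
  upper <- p
  for (k in seq_len(ncol(p))[-1]) upper[, k] <- upper[, k - 1] + p[, k]
  lower <- cbind(0, upper[, -ncol(upper), drop = FALSE])
  for (k in seq_along(defs)) {
    hit <- mutant & u >= lower[, k] & u < upper[, k]
    pheno[hit] <- names(defs)[k]
  }
  pheno
}

#' Ground-truth higher-order interaction effects implied by a penetrance spec
#'
#' Builds the 3x3 penetrance table for a defect at a locus pair (baseline +
#' single-locus offsets + pair deviation) and returns its unweighted
#' main-effects residual — the same decomposition [epistasis_decompose()]
#' applies to observed incidence tables, so estimates can be compared to
#' this exact ground truth.
#'
#' @param penetrance A [penetrance_spec()].
#' @param defect Defect name in the spec.
#' @param pair Character vector of two marker ids.
#' @return 3x3 matrix of deviations; each row and column sums to zero.
#' @export
true_epistasis_effects <- function(penetrance, defect, pair) {
  stopifnot(inherits(penetrance, "penetrance_spec"), length(pair) == 2)
  d <- penetrance$defects[[defect]]
  if (is.null(d)) stop("unknown defect: ", defect)
  tab <- matrix(d$baseline, 3, 3)
  le1 <- d$locus_effects[[pair[1]]]
  le2 <- d$locus_effects[[pair[2]]]
  if (!is.null(le1)) tab <- tab + matrix(le1, 3, 3)
  if (!is.null(le2)) tab <- tab + matrix(le2, 3, 3, byrow = TRUE)
  key <- paste(pair, collapse = ":")
  key_rev <- paste(rev(pair), collapse = ":")
  if (!is.null(d$pair_deviations[[key]])) {
    tab <- tab + d$pair_deviations[[key]]
  } else if (!is.null(d$pair_deviations[[key_rev]])) {
    tab <- tab + t(d$pair_deviations[[key_rev]])
  }
  .main_effects_residual(tab)
}

# Unweighted two-way main-effects residual of a 3x3 table:
# residual_ij = x_ij - (rowmean_i + colmean_j - grandmean).
.main_effects_residual <- function(x) {
  rm <- rowMeans(x); cm <- colMeans(x); gm <- mean(x)
  x - outer(rm, cm, function(a, b) a + b) + gm
}

#' Mask genotypes at random
#'
#' Sets each observed genotype to missing independently with probability
#' `rate`, recording the masked truth for later imputation scoring.
#'
#' @param cohort A `cohort`.
#' @param rate Missingness probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with the masked `cohort` and `mask`, a data frame of
#'   (individual row, marker id, true genotype) for every masked entry.
#' @export
mask_genotypes <- function(cohort, rate, seed) {
  stopifnot(inherits(cohort, "cohort"))
  if (rate < 0 || rate >= 1) stop("`rate` must lie in [0, 1)")
  set.seed(seed)
  g <- cohort$geno
  obs <- which(!is.na(g))
  hit <- obs[stats::runif(length(obs)) < rate]
  mask <- data.frame(
    row = ((hit - 1) %% nrow(g)) + 1L,
    marker = colnames(g)[((hit - 1) %/% nrow(g)) + 1L],
    truth = g[hit],
    stringsAsFactors = FALSE
  )
  g[hit] <- NA_integer_
  cohort$geno <- g
  list(cohort = cohort, mask = mask)
}
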