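#' Default end-to-end run configuration
#'
#' Two crosses emulating the study design — an A-strain F2 (sparse ~20 Mb
#' panel) and an F-strain combined F2 + F10 + F14 cohort (dense ~3 Mb
#' panel) — with four defect types at baseline penetrances giving ~30%
#' affected mutants, configurable single-locus effects and two-locus
#' deviations, light random genotype missingness, and desk-scale scan
#' settings. Severity ranks are configuration, not inference: ASD mildest
#' (1), the two VSD types intermediate (2), AVSD most severe (3).
#'
#' @param seed Master seed.
#' @param outdir Output directory for stage artifacts.
#' @return Nested configuration list accepted by [run_end_to_end()].
#' @export
default_run_config <- function(seed = 1, outdir = tempfile("epicross_run_")) {
  list(
    seed = seed,
    outdir = outdir,
    crosses = list(
      AxB = list(strains = c("B", "A"),
                 generations = c(F2 = 1200),
                 panel = list(spacing_mb = 20)),
      FxB = list(strains = c("B", "F"),
                 generations = c(F2 = 600, F10 = 400, F14 = 400),
                 panel = list(spacing_mb = 6))
    ),
    penetrance = NULL,      # NULL = default_penetrance() with demo architecture
    missing_rate = 0.03,
    qc = list(max_missing = 0.10),
    imputation = list(error_rate = 0.005),
    scan = list(n_perm = 200, alphas = c(0.05, 0.2)),
    epistasis = list(n_loci = 2, exclusion_bp = 80e6),
    architecture = NULL,
    severity = c(ASD = 1, membranous_VSD = 2, muscular_VSD = 2, AVSD = 3)
  )
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with the fields of [default_run_config()];
#'   missing fields fall back to the defaults. A `seed` is mandatory.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must specify a seed")
  base <- default_run_config(seed = cfg$seed)
  out <- utils::modifyList(base, cfg)
  for (nm in names(out$crosses)) {
    out$crosses[[nm]]$generations <- unlist(out$crosses[[nm]]$generations)
  }
  out$severity <- unlist(out$severity)
  out
}

#' Demonstration genetic architecture for a marker panel
#'
#' Assigns each defect two risk loci (the mid-panel markers of successive
#' chromosome pairs), both with additive single-locus effects, plus a
#' two-locus penetrance deviation between them: protective at the
#' syn-homozygous cells and deleterious at the anti-homozygous cells.
#' Deviations grow with defect severity (AVSD largest), so the
#' architecture reproduces the qualitative study pattern while staying
#' inside valid penetrance bounds.
#'
#' @param map A [marker_map()] naming the available loci.
#' @param arch Optional list overriding the per-defect `locus_effect`,
#'   `syn_dev`, `anti_dev` named vectors.
#' @return A `penetrance_spec`; marker choices are recoverable from its
#'   `locus_effects`/`pair_deviations` names.
#' @export
demo_penetrance <- function(map, arch = NULL) {
  if (is.null(arch)) {
    arch <- list(
      locus_effect = c(ASD = 0.04, membranous_VSD = 0.03,
                       muscular_VSD = 0.022, AVSD = 0.012),
      syn_dev = c(ASD = -0.01, membranous_VSD = -0.015,
                  muscular_VSD = -0.01, AVSD = -0.01),
      anti_dev = c(ASD = 0.02, membranous_VSD = 0.05,
                   muscular_VSD = 0.05, AVSD = 0.10)
    )
  }
  mid_marker <- function(ch) {
    ids <- map$id[map$chromosome == ch]
    ids[ceiling(length(ids) / 2)]
  }
  defect_chr <- list(ASD = c(1, 2), membranous_VSD = c(3, 4),
                     muscular_VSD = c(5, 6), AVSD = c(7, 8))
  le <- list(); pd <- list()
  for (d in names(defect_chr)) {
    loci <- vapply(defect_chr[[d]], mid_marker, "")
    e <- arch$locus_effect[[d]]
    le[[d]] <- stats::setNames(list(c(-e, 0, e), c(-e, 0, e)), loci)
    dev <- matrix(0, 3, 3)
    dev[1, 1] <- dev[3, 3] <- arch$syn_dev[[d]]
    dev[1, 3] <- dev[3, 1] <- arch$anti_dev[[d]]
    pd[[d]] <- stats::setNames(list(dev), paste(loci, collapse = ":"))
  }
  default_penetrance(locus_effects = le, pair_deviations = pd)
}

.log_stage <- function(...) {
  message(format(Sys.time(), "%H:%M:%S"), " [epicross] ", ...)
}

#' Run the full simulate-to-report pipeline
#'
#' Orchestrates every stage on one configuration: cohort simulation with
#' a known architecture, genotype masking and marker QC, HMM imputation
#' of missing genotypes, GRM construction (with F2 override and
#' positive-definite adjustment for the combined cohort), per-defect QTL
#' scans (binary-trait permutation scan for the F2 cross, mixed-model
#' scan for the combined cross), two-locus interaction analysis with the
#' coadaptation summary, and the severity-correlation report. Each
#' defect is analyzed case-versus-shared-normal-controls. All stage
#' tables are written as TSV under `config$outdir` with a JSON manifest;
#' reruns with the same configuration reproduce them exactly.
#'
#' @param config List from [default_run_config()] or [read_run_config()].
#' @return List with per-stage results and the `severity_report`.
#' @export
run_end_to_end <- function(config = default_run_config()) {
  if (is.null(config$seed)) stop("config must specify a seed")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1, 10)

  results <- list(crosses = list())
  defects <- names(default_penetrance()$defects)

  ci <- 0
  for (cross_name in names(config$crosses)) {
    ci <- ci + 1
    cc <- config$crosses[[cross_name]]
    .log_stage("simulate: ", cross_name)
    map <- make_marker_panel(spacing_mb = cc$panel$spacing_mb,
                             prefix = paste0(tolower(cross_name), "_"))
    pen <- if (is.null(config$penetrance)) {
      demo_penetrance(map, config$architecture)
    } else {
      config$penetrance
    }
    cohort <- simulate_cohort(
      cross_design(strains = cc$strains, generations = cc$generations),
      map, pen, seed = seeds[ci])
    masked <- mask_genotypes(cohort, config$missing_rate, seed = seeds[ci] %% 1e6 + 1)
    cohort <- masked$cohort

    .log_stage("qc: ", cross_name)
    qc <- qc_filter_markers(cohort$geno, config$qc$max_missing)
    geno <- qc$geno
    map_qc <- map[map$id %in% colnames(geno), , drop = FALSE]

    .log_stage("impute: ", cross_name)
    params <- hmm_params(config$imputation$error_rate)
    geno_imp <- geno
    for (gen in unique(cohort$individuals$generation)) {
      rows <- cohort$individuals$generation == gen
      imp <- impute_cohort(geno[rows, , drop = FALSE], map_qc, gen, params)
      typed_cols <- imp$positions$typed
      calls <- imp$call[, typed_cols, drop = FALSE]
      gsub_ <- geno[rows, , drop = FALSE]
      gsub_[is.na(gsub_)] <- calls[is.na(gsub_)]
      geno_imp[rows, ] <- gsub_
    }

    grm_info <- NULL
    combined <- length(unique(cohort$individuals$generation)) > 1
    if (combined) {
      .log_stage("grm: ", cross_name)
      G <- centered_grm(geno_imp)
      G <- override_f2_block(
        G, cohort$individuals$id[cohort$individuals$generation == "F2"])
      G_pd <- near_pd(G)
      grm_info <- list(grm = G_pd,
                       mantel = mantel_similarity(unclass(G), unclass(G_pd)))
    }

    .log_stage("scan: ", cross_name)
    pheno_tab <- cohort_phenotypes(cohort, defects)
    scans <- list(); pairs <- list(); effects <- list()
    for (d in defects) {
      y <- pheno_tab[[d]]
      if (combined) {
        sc <- lmm_scan(geno_imp, y, grm_info$grm)
        sc$LOD <- sc$LRT / (2 * log(10))
      } else {
        sc <- binary_scan_f2(geno_imp, y, map_qc)
        th <- permutation_thresholds(geno_imp, y,
                                     n_perm = config$scan$n_perm,
                                     alphas = config$scan$alphas,
                                     seed = seeds[ci] %% 1e6 + 7)
        attr(sc, "thresholds") <- th$thresholds
      }
      scans[[d]] <- sc

      sc2 <- sc
      i <- match(sc2$marker, map_qc$id)
      sc2$chromosome <- map_qc$chromosome[i]
      sc2$position_bp <- map_qc$position_bp[i]
      loci <- character(0)
      for (r in seq_len(config$epistasis$n_loci)) {
        loci <- c(loci, tryCatch(
          partner_snp(sc2, loci,
                      exclusion_bp = config$epistasis$exclusion_bp),
          error = function(e) NULL))
      }
      if (length(loci) >= 2) {
        prs <- utils::combn(loci, 2)
        eff_d <- list()
        for (pp in seq_len(ncol(prs))) {
          tab <- incidence_table(geno_imp, y, prs[, pp], defect = d)
          if (nrow(tab$empty_cells) == 0) {
            eff_d[[pp]] <- test_effects(tab, n_pairs_for_defect = ncol(prs))
          }
        }
        if (length(eff_d)) effects[[d]] <- do.call(rbind, eff_d)
        pairs[[d]] <- prs
      }
    }
    all_eff <- if (length(effects)) do.call(rbind, effects) else NULL

    .log_stage("coadaptation: ", cross_name)
    coad <- if (!is.null(all_eff)) {
      list(fractions = protective_fractions(all_eff),
           congruence = congruence_tests(all_eff))
    }

    inc <- vapply(defects, function(d) {
      y <- pheno_tab[[d]]; mean(y == 1, na.rm = TRUE)
    }, 0)

    res <- list(name = cross_name, cohort = cohort, map = map_qc,
                penetrance = pen, qc_report = qc$report, geno = geno_imp,
                grm = grm_info, scans = scans, effects = all_eff,
                coadaptation = coad, incidence = inc)
    results$crosses[[cross_name]] <- res

    # stage artifacts
    od <- file.path(config$outdir, cross_name)
    dir.create(od, showWarnings = FALSE)
    write_genotypes(geno_imp, file.path(od, "genotypes_imputed.tsv"))
    write_phenotypes(pheno_tab, file.path(od, "phenotypes.tsv"))
    utils::write.table(qc$report, file.path(od, "qc_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (d in defects) {
      utils::write.table(as.data.frame(scans[[d]]),
                         file.path(od, paste0("scan_", d, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(all_eff)) {
      utils::write.table(as.data.frame(all_eff),
                         file.path(od, "epistasis_effects.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$stages[[cross_name]] <- list(
      n_individuals = nrow(cohort$geno),
      n_markers_post_qc = ncol(geno),
      incidence = as.list(inc),
      mantel_similarity_pct = if (!is.null(grm_info)) grm_info$mantel$similarity_pct
    )
  }

  .log_stage("severity report")
  report <- severity_correlation(results$crosses, config$severity)
  results$severity_report <- report
  manifest$severity <- list(
    incidence_vs_severity_tau = report$incidence_vs_severity$tau,
    effect_vs_severity_tau = if (!is.null(report$effect_vs_severity))
      report$effect_vs_severity$tau
  )
  jsonlite_ok <- requireNamespace("jsonlite", quietly = TRUE)
  if (jsonlite_ok) {
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  results$manifest <- manifest
  results
}

#' Severity correlations of incidences and interaction effects
#'
#' Kendall partial rank correlations across defects: (a) defect incidence
#' versus severity rank, controlling for the cross; (b) significant
#' scaled interaction-effect magnitude versus severity rank, controlling
#' for the cross and the observed two-locus incidence (the latter to
#' avoid bias from an underlying incidence-effect correlation). VSD
#' subtypes share one severity rank, so they pool at report level while
#' remaining separate analyses upstream.
#'
#' @param crosses List of per-cross results as built by
#'   [run_end_to_end()] (each with `incidence` and `effects`).
#' @param severity Named severity ranks per defect.
#' @return List with `incidence_vs_severity` and (when enough significant
#'   effects exist) `effect_vs_severity`, each a [kendall_partial()]
#'   result, plus the underlying tables.
#' @export
severity_correlation <- function(crosses, severity) {
  inc_rows <- do.call(rbind, lapply(crosses, function(cr) {
    data.frame(cross = cr$name, defect = names(cr$incidence),
               incidence = as.numeric(cr$incidence),
               severity = as.numeric(severity[names(cr$incidence)]),
               stringsAsFactors = FALSE)
  }))
  if (length(unique(inc_rows$defect)) < 3) {
    stop("severity correlation needs at least 3 defects")
  }
  cross_code <- as.numeric(factor(inc_rows$cross))
  inc_covs <- if (length(unique(cross_code)) > 1) list(cross_code)
  inc_cor <- if (nrow(inc_rows) >= 4) {
    kendall_partial(inc_rows$incidence, inc_rows$severity,
                    covariates = inc_covs)
  } else {
    list(tau = NA_real_, p = NA_real_, n = nrow(inc_rows),
         note = "fewer than 4 defect-by-cross points")
  }
  out <- list(incidence_table = inc_rows, incidence_vs_severity = inc_cor)

  eff_rows <- do.call(rbind, lapply(crosses, function(cr) {
    if (is.null(cr$effects)) return(NULL)
    e <- cr$effects[cr$effects$significant, , drop = FALSE]
    if (!nrow(e)) return(NULL)
    data.frame(cross = cr$name, defect = e$defect,
               magnitude = abs(e$scaled_effect),
               observed = e$observed,
               severity = as.numeric(severity[e$defect]),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(eff_rows) && nrow(eff_rows) >= 4 &&
      length(unique(eff_rows$severity)) > 1) {
    code <- as.numeric(factor(eff_rows$cross))
    covs <- list(code, eff_rows$observed)
    if (length(unique(code)) == 1) covs <- list(eff_rows$observed)
    out$effect_table <- eff_rows
    out$effect_vs_severity <- kendall_partial(eff_rows$magnitude,
                                              eff_rows$severity,
                                              covariates = covs)
  }
  out
}
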