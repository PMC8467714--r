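#' Write a genotype table
#'
#' Genotypes are an individuals x markers integer matrix coded 0/1/2
#' (copies of the non-reference strain allele) with NA for missing.
#'
#' @param geno Genotype matrix with individual rownames and marker
#'   colnames.
#' @param path Output path (TSV) or, for `dialect = "ped-map"`, the stem
#'   to which `.ped` and `.map` are appended.
#' @param dialect `"tsv"` (default) or `"ped-map"` (PLINK-style text).
#' @param map Required for ped-map export: a [marker_map()] covering the
#'   columns of `geno`.
#' @param strains Two allele letters for ped-map export; code 0 is
#'   homozygous for `strains[1]`.
#' @return Invisibly, the path(s) written.
#' @export
write_genotypes <- function(geno, path, dialect = c("tsv", "ped-map"),
                            map = NULL, strains = c("B", "A")) {
  dialect <- match.arg(dialect)
  stopifnot(is.matrix(geno), !is.null(rownames(geno)), !is.null(colnames(geno)))
  if (dialect == "tsv") {
    d <- data.frame(id = rownames(geno), geno, check.names = FALSE,
                    stringsAsFactors = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    return(invisible(path))
  }
  if (is.null(map)) stop("ped-map export requires `map`")
  map <- map[match(colnames(geno), map$id), , drop = FALSE]
  if (anyNA(map$id)) stop("map does not cover all genotyped markers")
  a1 <- strains[1]; a2 <- strains[2]
  allele1 <- matrix(a1, nrow(geno), ncol(geno))
  allele2 <- matrix(a1, nrow(geno), ncol(geno))
  allele1[geno == 2] <- a2
  allele2[geno >= 1] <- a2
  allele1[is.na(geno)] <- "0"; allele2[is.na(geno)] <- "0"
  inter <- matrix("", nrow(geno), 2 * ncol(geno))
  inter[, seq(1, 2 * ncol(geno), by = 2)] <- allele1
  inter[, seq(2, 2 * ncol(geno), by = 2)] <- allele2
  ped <- cbind("FAM", rownames(geno), "0", "0", "0", "-9", inter)
  ped_path <- paste0(path, ".ped"); map_path <- paste0(path, ".map")
  utils::write.table(ped, ped_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(map$chromosome, map$id, map$position_cM, map$position_bp),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(ped_path, map_path))
}

#' Read a genotype table
#'
#' @param path TSV path, or the stem of a `.ped`/`.map` pair.
#' @param dialect `"tsv"` or `"ped-map"`.
#' @param strains For ped-map, the two allele letters (code 0 = homozygous
#'   `strains[1]`).
#' @return Genotype matrix (see [write_genotypes()]); a lossless
#'   round-trip of codes including missing.
#' @export
read_genotypes <- function(path, dialect = c("tsv", "ped-map"),
                           strains = c("B", "A")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    lines <- readLines(path)
    if (!length(lines)) stop("empty genotype file: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != nf[1])) {
      stop("ragged genotype file ", path, ": line ",
           which(nf != nf[1])[1], " has ", nf[which(nf != nf[1])[1]],
           " fields, expected ", nf[1])
    }
    header <- fields[[1]]
    body <- fields[-1]
    ids <- vapply(body, `[`, "", 1)
    if (anyDuplicated(ids)) {
      stop("duplicate individual id at line ",
           which(duplicated(ids))[1] + 1L, ": ", ids[duplicated(ids)][1])
    }
    vals <- unlist(lapply(body, `[`, -1))
    bad <- !(vals %in% c("0", "1", "2", "NA"))
    if (any(bad)) {
      line <- ((which(bad)[1] - 1) %/% (nf[1] - 1)) + 2L
      stop("unknown genotype code '", vals[bad][1], "' at line ", line)
    }
    g <- matrix(suppressWarnings(as.integer(vals)), nrow = length(body),
                byrow = TRUE, dimnames = list(ids, header[-1]))
    return(g)
  }
  ped <- utils::read.table(paste0(path, ".ped"), sep = "\t",
                           stringsAsFactors = FALSE)
  mp <- utils::read.table(paste0(path, ".map"), sep = "\t",
                          stringsAsFactors = FALSE)
  ids <- as.character(ped[[2]])
  if (anyDuplicated(ids)) stop("duplicate individual ids in ped file")
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  a1 <- al[, seq(1, ncol(al), by = 2), drop = FALSE]
  a2 <- al[, seq(2, ncol(al), by = 2), drop = FALSE]
  g <- (a1 == strains[2]) + (a2 == strains[2])
  g[a1 == "0" | a2 == "0"] <- NA
  g <- matrix(as.integer(g), nrow(g), ncol(g),
              dimnames = list(ids, as.character(mp[[2]])))
  g
}

#' Write / read a phenotype table
#'
#' One row per individual: id, cross, generation, mutant flag, and one
#' binary column per defect type (1 = defect, 0 = normal control, NA = not
#' applicable).
#'
#' @param pheno Data frame as above.
#' @param path TSV path.
#' @return `read_phenotypes` returns the data frame.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Binary phenotype table of a simulated cohort
#'
#' Builds the case/control coding used by every association analysis: each
#' defect is analyzed separately, cases are mutants with that defect and
#' controls are the shared normal mutants; mutants with a different defect
#' and non-mutants are marked not-applicable.
#'
#' @param cohort A `cohort`.
#' @param defects Defect types to tabulate (default: all present).
#' @return Data frame with id, cross, generation, mutant, and one 0/1/NA
#'   column per defect.
#' @export
cohort_phenotypes <- function(cohort, defects = NULL) {
  ind <- cohort$individuals
  if (is.null(defects)) {
    defects <- setdiff(unique(ind$phenotype), "normal")
  }
  out <- ind[, c("id", "cross", "generation", "mutant")]
  for (d in defects) {
    y <- rep(NA_integer_, nrow(ind))
    y[ind$mutant & ind$phenotype == "normal"] <- 0L
    y[ind$mutant & ind$phenotype == d] <- 1L
    out[[d]] <- y
  }
  out
}

#' Filter markers by missingness
#'
#' Drops markers whose missing-genotype fraction exceeds 10% (strictly;
#' a marker at exactly 0.10 is retained). The report also carries each
#' marker's minor allele frequency as a summary statistic — MAF is
#' reported, not filtered on, since both alleles are common by design in
#' an inbred strain cross.
#'
#' @param geno Genotype matrix.
#' @param max_missing Missingness threshold (default 0.10).
#' @return List with `geno` (retained markers) and `report` (data frame:
#'   marker, missing fraction, MAF, dropped flag).
#' @export
qc_filter_markers <- function(geno, max_missing = 0.10) {
  stopifnot(is.matrix(geno))
  if (ncol(geno) == 0) {
    return(list(geno = geno,
                report = data.frame(marker = character(0),
                                    missing_frac = numeric(0),
                                    maf = numeric(0),
                                    dropped = logical(0))))
  }
  miss <- colMeans(is.na(geno))
  af <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  drop <- miss > max_missing
  report <- data.frame(marker = colnames(geno), missing_frac = miss,
                       maf = maf, dropped = drop, row.names = NULL,
                       stringsAsFactors = FALSE)
  list(geno = geno[, !drop, drop = FALSE], report = report)
}
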