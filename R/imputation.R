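#' HMM parameters for genotype imputation
#'
#' @param error_rate Genotyping error probability; an observed genotype is
#'   correct with probability `1 - error_rate`, each wrong state getting
#'   `error_rate / 2`.
#' @return An `hmm_params` list.
#' @export
hmm_params <- function(error_rate = 0.005) {
  if (error_rate < 0 || error_rate > 0.1) {
    stop("`error_rate` must lie in [0, 0.1]")
  }
  structure(list(error_rate = error_rate), class = "hmm_params")
}

#' Map expansion factor of a cross generation
#'
#' Transition distances are scaled by the expected map expansion of the
#' generation: 1 for the F2 and t/2 for advanced-intercross generation t
#' (e.g. F10 -> 5, F14 -> 7), reflecting the extra recombination
#' accumulated by repeated intercrossing. Each generation is imputed with
#' its own factor.
#'
#' @param generation "F2", "F10" or "F14" (any "F<t>" accepted).
#' @return Multiplier applied to cM distances (>= 1).
#' @export
map_expansion <- function(generation) {
  t <- suppressWarnings(as.integer(sub("^F", "", generation)))
  if (is.na(t) || t < 2) stop("unrecognized generation label: ", generation)
  if (t == 2) 1 else t / 2
}

# Genotype-chain transition matrix across a recombination fraction r: the
# two gametes switch parental origin independently, giving the standard
# two-gamete kernel with stationary distribution (1/4, 1/2, 1/4).
.trans_genotype <- function(r) {
  matrix(c((1 - r)^2, 2 * r * (1 - r), r^2,
           r * (1 - r), (1 - r)^2 + r^2, r * (1 - r),
           r^2, 2 * r * (1 - r), (1 - r)^2),
         3, 3, byrow = TRUE)
}

# Forward-backward over one chromosome for all individuals at once.
# obs: n x m matrix (0/1/2/NA) at the m typed positions pos_cM;
# merged chain = typed positions plus target positions. Returns posterior
# array n x length(chain) x 3 plus the chain description.
.forward_backward <- function(obs, pos_cM, target_cM, expansion, error_rate) {
  n <- nrow(obs); m <- ncol(obs)
  chain_pos <- sort(unique(c(pos_cM, target_cM)))
  k <- length(chain_pos)
  typed_idx <- match(pos_cM, chain_pos)
  P <- lapply(haldane_recomb(diff(chain_pos) * expansion), .trans_genotype)
  prior <- c(0.25, 0.5, 0.25)

  emis <- function(j) {
    t_j <- match(chain_pos[j], pos_cM)
    E <- matrix(1, n, 3)
    if (!is.na(t_j)) {
      g <- obs[, t_j]
      ok <- !is.na(g)
      if (any(ok)) {
        E[ok, ] <- error_rate / 2
        E[cbind(which(ok), g[ok] + 1L)] <- 1 - error_rate
      }
    }
    E
  }

  alpha <- vector("list", k)
  A <- matrix(prior, n, 3, byrow = TRUE) * emis(1)
  A <- A / pmax(rowSums(A), .Machine$double.xmin)
  alpha[[1]] <- A
  for (j in seq_len(k)[-1]) {
    A <- (A %*% P[[j - 1]]) * emis(j)
    A <- A / pmax(rowSums(A), .Machine$double.xmin)
    alpha[[j]] <- A
  }
  post <- array(NA_real_, c(n, k, 3))
  B <- matrix(1, n, 3)
  post[, k, ] <- alpha[[k]]
  for (j in rev(seq_len(k - 1))) {
    B <- (B * emis(j + 1)) %*% t(P[[j]])
    B <- B / pmax(rowSums(B), .Machine$double.xmin)
    pj <- alpha[[j]] * B
    post[, j, ] <- pj / pmax(rowSums(pj), .Machine$double.xmin)
  }
  list(posterior = post, chain_pos = chain_pos,
       typed = chain_pos %in% pos_cM)
}

#' Impute one individual's genotypes along a chromosome
#'
#' Exact forward-backward posteriors of a three-state hidden genotype
#' chain: stationary distribution (1/4, 1/2, 1/4), transitions from the
#' Haldane map function on expansion-scaled distances, and emissions
#' correct with probability `1 - error_rate`. Posteriors are returned at
#' every marker position (typed or missing) and at any supplied untyped
#' target positions.
#'
#' @param observed Genotype vector (0/1/2/NA) over the chromosome's
#'   markers, in map order.
#' @param map A [marker_map()] restricted to a single chromosome.
#' @param generation Generation label; sets the map-expansion factor via
#'   [map_expansion()].
#' @param params [hmm_params()].
#' @param targets_cM Optional untyped positions (cM) to impute; must lie
#'   within the chromosome's marker span.
#' @return Data frame with position_cM, typed flag, posterior p0/p1/p2,
#'   hard call (argmax) and confidence (maximum posterior).
#' @export
impute_individual <- function(observed, map, generation = "F2",
                              params = hmm_params(), targets_cM = NULL) {
  if (length(unique(map$chromosome)) != 1) {
    stop("`map` must cover exactly one chromosome")
  }
  if (length(observed) != nrow(map)) {
    stop("genotype vector and map disagree in length")
  }
  if (all(is.na(observed))) {
    stop("at least one observed marker is required on the chromosome")
  }
  span <- range(map$position_cM)
  if (!is.null(targets_cM) &&
      any(targets_cM < span[1] | targets_cM > span[2])) {
    stop("target positions fall off the chromosome's marker span")
  }
  fb <- .forward_backward(matrix(observed, 1), map$position_cM,
                          targets_cM, map_expansion(generation),
                          params$error_rate)
  p <- fb$posterior[1, , , drop = TRUE]
  if (is.null(dim(p))) p <- matrix(p, 1, 3)
  data.frame(
    position_cM = fb$chain_pos,
    typed = fb$typed,
    p0 = p[, 1], p1 = p[, 2], p2 = p[, 3],
    call = max.col(p) - 1L,
    confidence = apply(p, 1, max)
  )
}

#' Impute a cohort's missing and untyped genotypes
#'
#' Runs the forward-backward HMM chromosome by chromosome, vectorized over
#' individuals. Each generation present in the cohort is imputed
#' separately with its own map-expansion factor.
#'
#' @param geno Genotype matrix (individuals x markers).
#' @param map [marker_map()] matching the columns of `geno`.
#' @param generation Generation label of the rows of `geno`.
#' @param params [hmm_params()].
#' @param targets Optional data frame (chromosome, position_cM) of untyped
#'   grid positions to impute in addition to missing typed markers.
#' @return List with `positions` (data frame: chromosome, position_cM,
#'   typed flag), `confidence` and `call` (individuals x positions
#'   matrices), and `posterior` (list of per-chromosome arrays).
#' @export
impute_cohort <- function(geno, map, generation = "F2",
                          params = hmm_params(), targets = NULL) {
  stopifnot(is.matrix(geno), nrow(map) == ncol(geno))
  chrs <- unique(map$chromosome)
  pos_list <- list(); conf_list <- list(); call_list <- list()
  post_list <- list()
  for (ch in chrs) {
    sel <- map$chromosome == ch
    t_cm <- if (!is.null(targets)) {
      targets$position_cM[targets$chromosome == ch]
    }
    fb <- .forward_backward(geno[, sel, drop = FALSE],
                            map$position_cM[sel], t_cm,
                            map_expansion(generation), params$error_rate)
    k <- length(fb$chain_pos)
    conf <- apply(fb$posterior, c(1, 2), max)
    call <- apply(fb$posterior, c(1, 2), which.max) - 1L
    pos_list[[as.character(ch)]] <- data.frame(
      chromosome = ch, position_cM = fb$chain_pos, typed = fb$typed)
    conf_list[[as.character(ch)]] <- conf
    call_list[[as.character(ch)]] <- call
    post_list[[as.character(ch)]] <- fb$posterior
  }
  list(positions = do.call(rbind, pos_list),
       confidence = do.call(cbind, conf_list),
       call = do.call(cbind, call_list),
       posterior = post_list)
}

#' Untyped-position grid between panel markers
#'
#' Builds a dense grid of untyped target positions (default every 3 Mb,
#' converted at the panel's cM/Mb rate) strictly inside each chromosome's
#' marker span, excluding positions already on the panel.
#'
#' @param map Sparse-panel [marker_map()].
#' @param spacing_mb Grid spacing in Mb.
#' @param cm_per_mb Conversion rate used by the panel.
#' @return Data frame (chromosome, position_cM).
#' @export
untyped_grid <- function(map, spacing_mb = 3, cm_per_mb = 0.5) {
  out <- lapply(unique(map$chromosome), function(ch) {
    pos <- map$position_cM[map$chromosome == ch]
    grid <- seq(min(pos), max(pos), by = spacing_mb * cm_per_mb)
    grid <- setdiff(round(grid, 9), round(pos, 9))
    if (!length(grid)) return(NULL)
    data.frame(chromosome = ch, position_cM = grid)
  })
  do.call(rbind, out)
}

#' Summarize imputation confidence
#'
#' @param confidence Numeric vector (or matrix) of per-call maximum
#'   posterior probabilities.
#' @param above Thresholds for which the strictly-greater fraction is
#'   reported.
#' @param below Thresholds for which the strictly-smaller fraction is
#'   reported.
#' @param calls Optional hard calls aligned with `confidence`.
#' @param truth Optional true genotypes aligned with `calls`; when given,
#'   imputation accuracy is reported.
#' @return List with `fraction_above`, `fraction_below`, and optionally
#'   `accuracy`.
#' @export
confidence_summary <- function(confidence, above = 0.70, below = 0.50,
                               calls = NULL, truth = NULL) {
  conf <- as.numeric(confidence)
  if (!length(conf)) stop("empty confidence input")
  fa <- vapply(above, function(t) mean(conf > t), 0)
  fb <- vapply(below, function(t) mean(conf < t), 0)
  out <- list(fraction_above = stats::setNames(fa, paste0(">", above)),
              fraction_below = stats::setNames(fb, paste0("<", below)))
  if (!is.null(calls) && !is.null(truth)) {
    out$accuracy <- mean(as.integer(calls) == as.integer(truth), na.rm = TRUE)
  }
  out
}
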