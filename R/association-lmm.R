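# Profiled ML log-likelihood of y = X b + u + e with cov(u) = vg K,
# cov(e) = ve I, in the eigenbasis of K. `d` = eigenvalues, `ys`, `Xs`
# rotated response/design; delta = ve/vg. Returns the maximized loglik
# and the implied variance components.
.lmm_profile_ml <- function(log_delta, d, ys, Xs) {
  delta <- exp(log_delta)
  w <- 1 / (d + delta)
  XtWX <- crossprod(Xs, Xs * w)
  XtWy <- crossprod(Xs, ys * w)
  b <- tryCatch(solve(XtWX, XtWy), error = function(e) NULL)
  if (is.null(b)) return(list(loglik = -Inf))
  r <- ys - Xs %*% b
  n <- length(ys)
  rss <- sum(w * r^2)
  vg <- rss / n
  ll <- -0.5 * (n * log(2 * pi * vg) + sum(log(d + delta)) + n)
  list(loglik = ll, beta = b, vg = vg, ve = delta * vg, w = w, XtWX = XtWX)
}

.lmm_fit_ml <- function(d, ys, Xs, interval = c(-15, 15)) {
  opt <- stats::optimize(function(ld) .lmm_profile_ml(ld, d, ys, Xs)$loglik,
                         interval = interval, maximum = TRUE, tol = 1e-6)
  fit <- .lmm_profile_ml(opt$maximum, d, ys, Xs)
  fit$log_delta <- opt$maximum
  fit$boundary <- abs(opt$maximum - interval[1]) < 0.01 ||
    abs(opt$maximum - interval[2]) < 0.01
  fit
}

#' Linear mixed model association scan
#'
#' Fits y = mu + x beta + u + e per marker, with cov(u) = v_g * GRM and
#' cov(e) = v_e * I. One eigendecomposition of the GRM is reused across
#' markers; variance components are estimated by maximum likelihood
#' (profiled over the variance ratio) under both hypotheses, and each
#' marker is tested by a 1-df likelihood-ratio test. Binary phenotypes
#' are handled on the observed (linear) scale, as in mixed-model
#' case-control GWAS.
#'
#' @param geno Genotype matrix; markers with missing genotypes have those
#'   individuals dropped (with a per-marker refit of the null).
#' @param pheno Phenotype vector (0/1 for case-control).
#' @param grm Positive-definite relatedness matrix over the individuals.
#' @return Data frame: marker, n, beta, se, LRT, p; constant markers are
#'   flagged with p = 1.
#' @export
lmm_scan <- function(geno, pheno, grm) {
  stopifnot(is.matrix(geno), nrow(geno) == length(pheno),
            all(dim(grm) == nrow(geno)))
  use_all <- !is.na(pheno)
  K <- unclass(grm)[use_all, use_all]
  y <- pheno[use_all]
  g <- geno[use_all, , drop = FALSE]
  n <- length(y)
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(eg$values)) {
    stop("`grm` must be positive definite; apply near_pd() first")
  }
  ys <- crossprod(eg$vectors, y)
  ones_s <- crossprod(eg$vectors, rep(1, n))
  null_fit <- .lmm_fit_ml(eg$values, ys, ones_s)

  m <- ncol(g)
  beta <- se <- rep(NA_real_, m)
  lrt <- rep(0, m); p <- rep(1, m); nn <- rep(n, m)
  flagged <- logical(m)
  for (j in seq_len(m)) {
    x <- g[, j]
    miss <- is.na(x)
    if (stats::var(x, na.rm = TRUE) %in% c(0, NA)) { flagged[j] <- TRUE; next }
    if (any(miss)) {
      keep <- !miss
      Kj <- K[keep, keep]
      egj <- eigen((Kj + t(Kj)) / 2, symmetric = TRUE)
      ysj <- crossprod(egj$vectors, y[keep])
      Xs0 <- crossprod(egj$vectors, rep(1, sum(keep)))
      nullj <- .lmm_fit_ml(egj$values, ysj, Xs0)
      Xs1 <- cbind(Xs0, crossprod(egj$vectors, x[keep]))
      alt <- .lmm_fit_ml(egj$values, ysj, Xs1)
      l0 <- nullj$loglik
      nn[j] <- sum(keep)
    } else {
      Xs1 <- cbind(ones_s, crossprod(eg$vectors, x))
      alt <- .lmm_fit_ml(eg$values, ys, Xs1)
      l0 <- null_fit$loglik
    }
    if (!is.finite(alt$loglik)) { flagged[j] <- TRUE; next }
    vb <- tryCatch(alt$vg * solve(alt$XtWX), error = function(e) NULL)
    beta[j] <- alt$beta[2]
    if (!is.null(vb)) se[j] <- sqrt(vb[2, 2])
    lrt[j] <- max(0, 2 * (alt$loglik - l0))
    p[j] <- stats::pchisq(lrt[j], df = 1, lower.tail = FALSE)
  }
  data.frame(marker = colnames(g), n = nn, beta = beta, se = se,
             LRT = lrt, p = p, flagged = flagged,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Profiled REML criterion (intercept-only fixed effects unless Xs given).
.lmm_profile_reml <- function(log_delta, d, ys, Xs) {
  delta <- exp(log_delta)
  w <- 1 / (d + delta)
  XtWX <- crossprod(Xs, Xs * w)
  b <- solve(XtWX, crossprod(Xs, ys * w))
  r <- ys - Xs %*% b
  nq <- length(ys) - ncol(Xs)
  rss <- sum(w * r^2)
  vg <- rss / nq
  ll <- -0.5 * (nq * log(2 * pi * vg) + sum(log(d + delta)) +
                  determinant(XtWX, logarithm = TRUE)$modulus + nq)
  list(loglik = as.numeric(ll), vg = vg, ve = delta * vg)
}

# Unprofiled REML loglik at (vg, ve), for the information matrix.
.reml_loglik_at <- function(vg, ve, d, ys, Xs) {
  s <- vg * d + ve
  if (any(s <= 0)) return(-Inf)
  w <- 1 / s
  XtWX <- crossprod(Xs, Xs * w)
  b <- solve(XtWX, crossprod(Xs, ys * w))
  r <- ys - Xs %*% b
  -0.5 * (sum(log(s)) +
            as.numeric(determinant(XtWX, logarithm = TRUE)$modulus) +
            sum(w * r^2) + (length(ys) - ncol(Xs)) * log(2 * pi))
}

#' REML variance components and proportion of variance explained
#'
#' Restricted maximum likelihood estimates of the genetic (v_g) and
#' residual (v_e) variance in y = mu + u + e with cov(u) = v_g * GRM,
#' via a one-dimensional optimization over the variance ratio in the
#' GRM's eigenbasis. PVE = v_g / (v_g + v_e); its standard error comes
#' from the inverse observed information at the optimum by the delta
#' method.
#'
#' @param pheno Phenotype vector (binary case-control treated on the
#'   observed scale; see [liability_transform()]).
#' @param grm Positive-definite relatedness matrix.
#' @return List with vg, ve, pve, se_pve, loglik and a `boundary` flag
#'   (TRUE when the optimum sits at the edge of the search range, i.e.
#'   the fit did not converge to an interior maximum).
#' @export
reml_pve <- function(pheno, grm) {
  use <- !is.na(pheno)
  y <- pheno[use]
  K <- unclass(grm)[use, use]
  n <- length(y)
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(eg$values)) {
    stop("`grm` must be positive definite; apply near_pd() first")
  }
  ys <- crossprod(eg$vectors, y)
  Xs <- crossprod(eg$vectors, rep(1, n))
  opt <- stats::optimize(function(ld)
    .lmm_profile_reml(ld, eg$values, ys, Xs)$loglik,
    interval = c(-15, 15), maximum = TRUE, tol = 1e-7)
  fit <- .lmm_profile_reml(opt$maximum, eg$values, ys, Xs)
  vg <- fit$vg; ve <- fit$ve
  boundary <- abs(opt$maximum - 15) < 0.01 || abs(opt$maximum + 15) < 0.01
  if (boundary) {
    warning("REML optimum at the boundary; variance component pinned")
  }
  # observed information by central differences on (vg, ve)
  h <- c(vg, ve) * 1e-4 + 1e-10
  f <- function(th) .reml_loglik_at(th[1], th[2], eg$values, ys, Xs)
  H <- matrix(NA_real_, 2, 2)
  th0 <- c(vg, ve)
  for (a in 1:2) for (b in 1:2) {
    ea <- eb <- c(0, 0); ea[a] <- h[a]; eb[b] <- h[b]
    H[a, b] <- (f(th0 + ea + eb) - f(th0 + ea - eb) -
                  f(th0 - ea + eb) + f(th0 - ea - eb)) / (4 * h[a] * h[b])
  }
  se_pve <- tryCatch({
    V <- solve(-H)
    s <- vg + ve
    gr <- c(ve, -vg) / s^2
    sqrt(max(0, drop(t(gr) %*% V %*% gr)))
  }, error = function(e) NA_real_)
  list(vg = vg, ve = ve, pve = vg / (vg + ve), se_pve = se_pve,
       loglik = fit$loglik, boundary = boundary)
}

#' Odds ratio from a logistic mixed model
#'
#' Penalized quasi-likelihood fit of logit P(y = 1) = mu + x beta + u with
#' cov(u) = v_g * GRM: iterates the logistic working response and, at each
#' step, refits the variance ratio of the weighted linear mixed model by
#' maximum likelihood. Controls for relatedness when estimating a locus
#' odds ratio in a cohort of mixed generations.
#'
#' @param x Genotype vector at the marker (0/1/2; NA dropped).
#' @param pheno Binary phenotype.
#' @param grm Positive-definite relatedness matrix.
#' @param max_iter,tol PQL iteration controls.
#' @return List with beta, se, OR = exp(beta), vg, iterations, converged,
#'   and `separated` (TRUE when the fit diverged, no estimate reported).
#' @export
logistic_mixed_or <- function(x, pheno, grm, max_iter = 25, tol = 1e-5) {
  use <- !is.na(pheno) & !is.na(x)
  y <- pheno[use]; xv <- x[use]
  K <- unclass(grm)[use, use]
  n <- length(y)
  X <- cbind(1, xv)
  start <- tryCatch(suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial())$coefficients),
    error = function(e) c(stats::qlogis(max(mean(y), 1e-3)), 0))
  b <- start; u <- rep(0, n); vg <- 0.1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b) + u
    mu <- stats::plogis(eta)
    W <- pmax(mu * (1 - mu), 1e-6)
    z <- eta + (y - mu) / W
    sw <- sqrt(W)
    zt <- sw * z
    Xt <- X * sw
    Kt <- K * tcrossprod(sw)
    eg <- eigen((Kt + t(Kt)) / 2, symmetric = TRUE)
    d <- pmax(eg$values, 0)
    zs <- crossprod(eg$vectors, zt)
    Xs <- crossprod(eg$vectors, Xt)
    # working-scale model: zt = Xt b + ut + et, cov(ut) = vg Kt, cov(et) = I
    opt <- stats::optimize(function(lv) {
      v <- exp(lv)
      s <- v * d + 1
      w <- 1 / s
      bb <- tryCatch(solve(crossprod(Xs, Xs * w), crossprod(Xs, zs * w)),
                     error = function(e) NULL)
      if (is.null(bb)) return(-Inf)
      r <- zs - Xs %*% bb
      -0.5 * (sum(log(s)) + sum(w * r^2))
    }, interval = c(-12, 6), maximum = TRUE, tol = 1e-5)
    vg <- exp(opt$maximum)
    s <- vg * d + 1
    w <- 1 / s
    XtWX <- crossprod(Xs, Xs * w)
    b_new <- drop(solve(XtWX, crossprod(Xs, zs * w)))
    r <- zs - Xs %*% b_new
    ut <- eg$vectors %*% (vg * d * w * r)
    u_new <- drop(ut / sw)
    if (any(!is.finite(b_new)) || abs(b_new[2]) > 15) {
      return(list(beta = NA_real_, se = NA_real_, OR = NA_real_, vg = vg,
                  iterations = it, converged = FALSE, separated = TRUE))
    }
    delta <- max(abs(b_new - b), max(abs(u_new - u)) / (1 + max(abs(u_new))))
    b <- b_new; u <- u_new
    if (delta < tol) { converged <- TRUE; break }
  }
  se <- sqrt(solve(XtWX)[2, 2])
  list(beta = unname(b[2]), se = unname(se), OR = exp(unname(b[2])), vg = vg,
       iterations = it, converged = converged, separated = FALSE)
}
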