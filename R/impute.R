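#' Impute missing log2 intensities by EM under a multivariate normal model
#'
#' Fits a multivariate normal over the sample columns (mean vector and
#' sample-by-sample covariance; proteins are the observations) by
#' expectation-maximization, grouping rows by missingness pattern, then fills
#' each missing cell from the conditional distribution of the missing
#' coordinates given the row's observed coordinates: either a single seeded
#' random draw (`mode = "conditional_draw"`) or the conditional mean
#' (`"conditional_mean"`). Observed cells are returned bit-identically.
#'
#' The observed-data log-likelihood is non-decreasing over iterations;
#' convergence is declared when its relative change drops below `tol`. A
#' singular covariance triggers automatic ridge escalation (multiples of
#' `1e-6 * mean(diag)`), and an error if the matrix stays singular.
#'
#' @param block Numeric matrix (proteins x samples, log2 scale) with `NA` for
#'   missing cells.
#' @param seed Integer seed used for `"conditional_draw"`.
#' @param mode `"conditional_draw"` or `"conditional_mean"`.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter Maximum EM iterations (default 500).
#' @return The completed matrix, with attributes `mu`, `sigma`, `loglik`
#'   (per-iteration trace), `iterations` and `converged`.
#' @export
impute_em <- function(block, seed = 1L,
                      mode = c("conditional_draw", "conditional_mean"),
                      tol = 1e-6, max_iter = 500L) {
  mode <- match.arg(mode)
  block <- as.matrix(block)
  storage.mode(block) <- "double"
  n <- nrow(block)
  p <- ncol(block)
  obs <- !is.na(block)
  all_missing_col <- colSums(obs) == 0
  if (any(all_missing_col)) {
    stop("column(s) with no observed values: ",
         paste(colnames(block)[all_missing_col], collapse = ", "))
  }
  if (all(obs)) {
    out <- block
    mu <- colMeans(block)
    sigma <- stats::cov(block) * (n - 1) / n
    attr(out, "mu") <- mu
    attr(out, "sigma") <- sigma
    attr(out, "loglik") <- mvn_obs_loglik(block, obs, mu, sigma)
    attr(out, "iterations") <- 0L
    attr(out, "converged") <- TRUE
    return(out)
  }

  mu <- colMeans(block, na.rm = TRUE)
  v <- apply(block, 2, stats::var, na.rm = TRUE)
  v[!is.finite(v) | v == 0] <- mean(v[is.finite(v) & v > 0], na.rm = TRUE)
  if (!is.finite(mean(v))) v[] <- 1
  sigma <- diag(v, p)

  pattern <- apply(obs, 1, function(z) paste(as.integer(z), collapse = ""))
  groups <- split(seq_len(n), pattern)

  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    t1 <- numeric(p)
    t2 <- matrix(0, p, p)
    ll <- 0
    for (rows in groups) {
      o <- obs[rows[1], ]
      m <- !o
      if (!any(o)) {
        # fully missing rows carry no observed-data information; their
        # conditional distribution is the current marginal
        t1 <- t1 + length(rows) * mu
        t2 <- t2 + length(rows) * (sigma + tcrossprod(mu))
        next
      }
      xo <- block[rows, o, drop = FALSE]
      soo <- ridge_chol(sigma[o, o, drop = FALSE])
      # log-likelihood of the observed sub-vector for every row of the pattern
      dev <- sweep(xo, 2, mu[o], `-`)
      z <- backsolve(soo, t(dev), transpose = TRUE)   # soo is upper Cholesky
      ll <- ll + length(rows) * (-0.5 * sum(o) * log(2 * pi) - sum(log(diag(soo)))) -
        0.5 * sum(z^2)
      if (!any(m)) {
        t1 <- t1 + colSums(matrix(block[rows, , drop = FALSE], ncol = p))
        t2 <- t2 + crossprod(block[rows, , drop = FALSE])
        next
      }
      # conditional of missing given observed: B = Sigma_mo Sigma_oo^{-1}
      b <- t(backsolve(soo, backsolve(soo, t(sigma[m, o, drop = FALSE]), transpose = TRUE)))
      cond_mean <- matrix(mu[m], nrow = length(rows), ncol = sum(m), byrow = TRUE) +
        dev %*% t(b)
      cond_cov <- sigma[m, m, drop = FALSE] - b %*% sigma[o, m, drop = FALSE]
      xfull <- matrix(0, length(rows), p)
      xfull[, o] <- xo
      xfull[, m] <- cond_mean
      t1 <- t1 + colSums(xfull)
      t2 <- t2 + crossprod(xfull)
      t2[m, m] <- t2[m, m] + length(rows) * cond_cov
    }
    mu <- t1 / n
    sigma <- t2 / n - tcrossprod(mu)
    sigma <- (sigma + t(sigma)) / 2
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged) {
    stop(sprintf(
      "EM did not converge in %d iterations (last log-likelihood change %.3g)",
      max_iter, ll_trace[length(ll_trace)] - ll_old
    ))
  }

  out <- block
  if (mode == "conditional_draw") {
    withr::local_seed(seed)
  }
  for (rows in groups) {
    o <- obs[rows[1], ]
    m <- !o
    if (!any(m)) next
    if (!any(o)) {
      if (mode == "conditional_mean") {
        out[rows, ] <- matrix(mu, length(rows), p, byrow = TRUE)
      } else {
        zdraw <- matrix(stats::rnorm(length(rows) * p), length(rows), p)
        out[rows, ] <- matrix(mu, length(rows), p, byrow = TRUE) +
          zdraw %*% ridge_chol(sigma)
      }
      next
    }
    soo <- ridge_chol(sigma[o, o, drop = FALSE])
    b <- t(backsolve(soo, backsolve(soo, t(sigma[m, o, drop = FALSE]), transpose = TRUE)))
    dev <- sweep(block[rows, o, drop = FALSE], 2, mu[o], `-`)
    cond_mean <- matrix(mu[m], nrow = length(rows), ncol = sum(m), byrow = TRUE) +
      dev %*% t(b)
    if (mode == "conditional_mean") {
      out[rows, m] <- cond_mean
    } else {
      cond_cov <- sigma[m, m, drop = FALSE] - b %*% sigma[o, m, drop = FALSE]
      cc <- ridge_chol((cond_cov + t(cond_cov)) / 2)
      zdraw <- matrix(stats::rnorm(length(rows) * sum(m)), length(rows), sum(m))
      out[rows, m] <- cond_mean + zdraw %*% cc
    }
  }
  attr(out, "mu") <- mu
  attr(out, "sigma") <- sigma
  attr(out, "loglik") <- ll_trace
  attr(out, "iterations") <- iter
  attr(out, "converged") <- converged
  out
}

# Upper-triangular Cholesky factor with automatic ridge escalation.
ridge_chol <- function(s) {
  r <- tryCatch(chol(s), error = function(e) NULL)
  if (!is.null(r)) return(r)
  base_ridge <- 1e-6 * mean(diag(s))
  if (!is.finite(base_ridge) || base_ridge <= 0) base_ridge <- 1e-8
  for (mult in 10^(0:4)) {
    r <- tryCatch(chol(s + diag(base_ridge * mult, nrow(s))), error = function(e) NULL)
    if (!is.null(r)) return(r)
  }
  stop("covariance matrix is singular even after ridge escalation")
}

mvn_obs_loglik <- function(x, obs, mu, sigma) {
  ll <- 0
  pattern <- apply(obs, 1, function(z) paste(as.integer(z), collapse = ""))
  for (rows in split(seq_len(nrow(x)), pattern)) {
    o <- obs[rows[1], ]
    if (!any(o)) next
    soo <- ridge_chol(sigma[o, o, drop = FALSE])
    dev <- sweep(x[rows, o, drop = FALSE], 2, mu[o], `-`)
    z <- backsolve(soo, t(dev), transpose = TRUE)
    ll <- ll + length(rows) * (-0.5 * sum(o) * log(2 * pi) - sum(log(diag(soo)))) -
      0.5 * sum(z^2)
  }
  ll
}
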