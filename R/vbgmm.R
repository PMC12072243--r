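#' @include AllGenerics.R
#' @importFrom stats kmeans cov dist
NULL

## Variational Bayesian Gaussian mixture (mean-field, full covariance,
## Dirichlet distribution prior over the mixing weights). The number of
## effective components is inferred from the data: superfluous components
## collapse onto negligible weight.

.logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# one variational fit from a given hard initial assignment
.vbgmmRun <- function(X, z0, k_max, alpha0, beta0, m0, W0inv, nu0,
                      max_iter = 300, tol = 1e-6) {
  n <- nrow(X); d <- ncol(X)
  resp <- matrix(1e-10, n, k_max)
  resp[cbind(seq_len(n), z0)] <- 1
  resp <- resp / rowSums(resp)
  score <- -Inf
  for (iter in seq_len(max_iter)) {
    ## M-like step: update variational posteriors
    Nk <- colSums(resp) + 1e-10
    alpha <- alpha0 + Nk
    beta <- beta0 + Nk
    nu <- nu0 + Nk
    xbar <- t(resp) %*% X / Nk
    m <- (beta0 * matrix(m0, k_max, d, byrow = TRUE) + Nk * xbar) / beta
    W <- vector("list", k_max)
    for (k in seq_len(k_max)) {
      xc <- sweep(X, 2, xbar[k, ])
      Sk <- t(xc * resp[, k]) %*% xc / Nk[k]
      dm <- xbar[k, ] - m0
      Winv_k <- W0inv + Nk[k] * Sk +
        (beta0 * Nk[k] / (beta0 + Nk[k])) * tcrossprod(dm)
      W[[k]] <- chol2inv(chol((Winv_k + t(Winv_k)) / 2))
    }
    ## E step: responsibilities from expected log weights and precisions
    elog_pi <- digamma(alpha) - digamma(sum(alpha))
    log_rho <- matrix(0, n, k_max)
    for (k in seq_len(k_max)) {
      elog_lam <- sum(digamma((nu[k] + 1 - seq_len(d)) / 2)) +
        d * log(2) + determinant(W[[k]], logarithm = TRUE)$modulus
      xc <- sweep(X, 2, m[k, ])
      quad <- d / beta[k] + nu[k] * rowSums((xc %*% W[[k]]) * xc)
      log_rho[, k] <- elog_pi[k] + 0.5 * elog_lam -
        0.5 * d * log(2 * pi) - 0.5 * quad
    }
    lse <- .logsumexp(log_rho)
    new_resp <- exp(log_rho - lse)
    new_score <- sum(lse)
    delta <- mean(abs(new_resp - resp))
    resp <- new_resp
    score <- new_score
    if (delta < tol) break
  }
  list(resp = resp, score = score, weights = (alpha0 + colSums(resp)),
       means = m, W = W, nu = nu, beta = beta, alpha = alpha,
       n_iter = iter)
}

#' Fit a variational Bayesian Gaussian mixture to classification features
#'
#' Mean-field variational inference for a Gaussian mixture with a Dirichlet
#' distribution prior over the mixing weights: the posterior prunes
#' superfluous components, so the number of effective clusters is inferred
#' rather than fixed. Defaults follow common practice for this analysis:
#' at most `k_max = 10` components, `n_init = 10` seeded k-means restarts
#' (the best variational score wins), weight concentration prior `1/k_max`,
#' and the empirical covariance as the scale prior. Features are
#' standardized (optionally after `log10(x+1)` transform of the first
#' column, useful when RDP durations span orders of magnitude) before
#' fitting; component means are reported in the original feature space.
#'
#' @param points Matrix or data.frame with two columns, typically
#'   `(rdp_ms, fai)`; at least 10 finite rows.
#' @param seed Integer seed controlling all restarts.
#' @param k_max Maximum number of mixture components.
#' @param n_init Number of initialisations.
#' @param log_rdp Apply `log10(x + 1)` to the first column before
#'   standardizing (default on: durations span orders of magnitude).
#' @param weight_floor Fraction of total weight below which a component is
#'   not counted as effective.
#' @return List of class `"vbgmm"`: `means` (original space), `weights`,
#'   `covariances` (standardized space), `effective` (logical per
#'   component), `k_effective`, `labels` (MAP assignment per row),
#'   `responsibilities`, `transform` (centring/scaling info), `score`.
#' @examples
#' pts <- makeClusterLayout(15, seed = 1)
#' fit <- fitVbgmm(pts[, c("rdp_ms", "fai")], seed = 1)
#' fit$k_effective
#' @export
fitVbgmm <- function(points, seed = 0, k_max = 10, n_init = 10,
                     log_rdp = TRUE, weight_floor = 0.01) {
  X0 <- as.matrix(points)
  if (ncol(X0) != 2) stop("expected a two-column feature matrix")
  if (nrow(X0) < 10) stop("need at least 10 points to fit the mixture")
  if (any(!is.finite(X0))) stop("features must be finite")
  X <- X0
  if (log_rdp) X[, 1] <- log10(X[, 1] + 1)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  degenerate <- all(scl < 1e-12)
  scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  n <- nrow(Xs); d <- 2L

  if (degenerate || nrow(unique(Xs)) == 1) {
    # all points identical: a single component carries all the weight
    resp <- matrix(0, n, k_max); resp[, 1] <- 1
    labels <- rep(1L, n)
    means_orig <- matrix(colMeans(X0), 1, 2,
                         dimnames = list(NULL, colnames(X0)))
    eff <- c(TRUE, rep(FALSE, k_max - 1))
    return(structure(list(means = means_orig,
                          weights = c(1, rep(0, k_max - 1)),
                          covariances = list(diag(1e-12, 2)),
                          effective = eff, k_effective = 1L,
                          labels = labels, responsibilities = resp,
                          transform = list(center = ctr, scale = scl,
                                           log_rdp = log_rdp),
                          score = NA_real_, k_max = k_max),
                     class = "vbgmm"))
  }

  alpha0 <- 1 / k_max
  beta0 <- 1
  m0 <- colMeans(Xs)
  # scale prior sized to one component's share of the data variance, so a
  # tight cluster is not inflated toward the global spread
  W0inv <- cov(Xs) / k_max
  nu0 <- d

  best <- NULL
  for (init in seq_len(n_init)) {
    z0 <- .withSeed(as.integer(seed) * 1000L + init, {
      km <- tryCatch(
        kmeans(Xs, centers = min(k_max, nrow(unique(Xs))), nstart = 1,
               iter.max = 50),
        error = function(e) NULL)
      if (is.null(km)) sample.int(k_max, n, replace = TRUE)
      else km$cluster
    })
    run <- .vbgmmRun(Xs, z0, k_max, alpha0, beta0, m0, W0inv, nu0)
    if (is.null(best) || run$score > best$score) best <- run
  }

  w <- colSums(best$resp) / n
  eff <- w > weight_floor
  labels <- max.col(best$resp)
  # back-transform component means to the original feature space
  mu <- sweep(sweep(best$means, 2, scl, "*"), 2, ctr, "+")
  if (log_rdp) mu[, 1] <- 10^mu[, 1] - 1
  colnames(mu) <- colnames(X0)
  covs <- lapply(seq_len(k_max), function(k)
    chol2inv(chol(best$W[[k]] * best$nu[k])))   # posterior mean covariance
  structure(list(means = mu, weights = w, covariances = covs,
                 effective = eff, k_effective = sum(eff),
                 labels = labels, responsibilities = best$resp,
                 transform = list(center = ctr, scale = scl,
                                  log_rdp = log_rdp),
                 score = best$score, k_max = k_max),
            class = "vbgmm")
}

#' @export
print.vbgmm <- function(x, ...) {
  cat(sprintf("Variational Bayesian GMM: %d effective of %d components\n",
              x$k_effective, x$k_max))
  eff <- which(x$effective)
  tab <- data.frame(component = eff,
                    weight = round(x$weights[eff], 3),
                    round(x$means[eff, , drop = FALSE], 2))
  print(tab, row.names = FALSE)
  invisible(x)
}
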