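#' Fit a scalar Gaussian mixture by expectation-maximization
#'
#' One shared K-component univariate mixture plays the role of the visual
#' word dictionary for all deep filters. Initialisation is k-means++-style
#' (seeded): centres drawn with probability proportional to squared distance
#' from the nearest centre chosen so far; initial weights uniform, initial
#' variances the pool variance. EM stops when the log-likelihood gain drops
#' below `tol` or after `max_iter` iterations. Variances are floored at
#' `1e-6` times the pool variance.
#'
#' @param x numeric pool of scalar responses (needs at least `10 * K`
#'   distinct values).
#' @param K number of components (default 64).
#' @param seed RNG seed for the initialisation.
#' @param max_iter,tol EM stopping rule.
#' @param max_pool if the pool exceeds this size, a seeded subsample of this
#'   size is used for fitting (the fit is a density estimate; a bounded
#'   subsample keeps it cheap without changing it materially).
#' @return object of class `gmm_model`: `weights`, `means`, `variances`,
#'   `K`, `loglik`, `n`, `n_iter`, `seed`.
#' @export
fit_gmm <- function(x, K = 64L, seed = 1L, max_iter = 500L, tol = 1e-6,
                    max_pool = 5e4) {
  x <- x[is.finite(x)]
  if (length(x) > max_pool) {
    x <- with_seed(seed, sample(x, max_pool))
  }
  n <- length(x)
  if (length(unique(x)) < 10L * K) {
    stop(sprintf("pool has %d distinct values; need at least 10*K = %d",
                 length(unique(x)), 10L * K), call. = FALSE)
  }
  pool_var <- stats::var(x)
  if (pool_var <= 0) stop("degenerate pool (zero variance)", call. = FALSE)
  floor_var <- 1e-6 * pool_var
  with_seed(seed, {
    # k-means++ seeding of the component means
    mu <- numeric(K)
    mu[1L] <- x[sample.int(n, 1L)]
    d2 <- (x - mu[1L])^2
    for (k in seq_len(K)[-1L]) {
      p <- d2 / sum(d2)
      mu[k] <- x[sample.int(n, 1L, prob = p)]
      d2 <- pmin(d2, (x - mu[k])^2)
    }
    w <- rep(1 / K, K)
    v <- rep(pool_var, K)
    ll_old <- -Inf
    it <- 0L
    X2 <- cbind(x^2, x, 1)                           # quadratic design, reused
    repeat {
      it <- it + 1L
      # log w_k + log N(x; mu_k, v_k) as one GEMM over (x^2, x, 1)
      lp <- X2 %*% rbind(-0.5 / v, mu / v,
                         log(w) - 0.5 * log(2 * pi * v) - 0.5 * mu^2 / v)
      lse <- logsumexp_rows(lp)
      ll <- sum(lse)
      r <- exp(lp - lse)                             # responsibilities
      nk <- colSums(r)
      nk[nk < 1e-300] <- 1e-300
      w <- nk / n
      mu <- as.vector(crossprod(r, x)) / nk
      v <- pmax(as.vector(crossprod(r, x^2)) / nk - mu^2, floor_var)
      if (it >= max_iter || (ll - ll_old) < tol) break
      ll_old <- ll
    }
    structure(list(weights = w, means = mu, variances = v, K = as.integer(K),
                   loglik = ll, n = n, n_iter = it, seed = as.integer(seed)),
              class = "gmm_model")
  })
}

#' Component responsibilities of scalar observations under a mixture
#'
#' `gamma_k(x) = w_k N(x; mu_k, s2_k) / sum_j w_j N(x; mu_j, s2_j)`,
#' evaluated in log space for numerical stability.
#'
#' @param gmm a `gmm_model`.
#' @param x numeric vector of observations.
#' @return `length(x) x K` matrix of responsibilities; rows sum to 1.
#' @export
gmm_posterior <- function(gmm, x) {
  stopifnot(inherits(gmm, "gmm_model"))
  lp <- outer(x, gmm$means, "-")
  lp <- sweep(-0.5 * sweep(lp^2, 2L, gmm$variances, "/"), 2L,
              log(gmm$weights) - 0.5 * log(2 * pi * gmm$variances), "+")
  exp(lp - logsumexp_rows(lp))
}

#' Sample from a fitted scalar mixture
#'
#' @param gmm a `gmm_model`.
#' @param n sample size.
#' @param seed RNG seed.
#' @return numeric vector of length `n`.
#' @export
gmm_sample <- function(gmm, n, seed = 1L) {
  with_seed(seed, {
    comp <- sample.int(gmm$K, n, replace = TRUE, prob = gmm$weights)
    stats::rnorm(n, gmm$means[comp], sqrt(gmm$variances[comp]))
  })
}

#' Canonical index of one Fisher-descriptor coordinate
#'
#' The descriptor layout (version 1) is
#' `idx(f, k, order) = f * 2K + order * K + k` with 0-based `f` (filter),
#' `k` (mixture component) and `order` (0 = first-order, 1 = second-order
#' statistic), returned 1-based for R indexing.
#'
#' @param f filter index in `0 .. F-1`.
#' @param k component index in `0 .. K-1`.
#' @param order 0 or 1.
#' @param K,F mixture size and filter count of the layout.
#' @return 1-based position in the descriptor vector.
#' @export
descriptor_index <- function(f, k, order, K = 64L, F = 128L) {
  if (any(f < 0 | f >= F) || any(k < 0 | k >= K) || any(!order %in% c(0L, 1L))) {
    stop("descriptor_index: argument out of range", call. = FALSE)
  }
  as.integer(f * 2L * K + order * K + k + 1L)
}

#' @rdname descriptor_index
#' @param idx 1-based descriptor position.
#' @return `descriptor_index_inverse`: list `(f, k, order)`, 0-based.
#' @export
descriptor_index_inverse <- function(idx, K = 64L, F = 128L) {
  i0 <- idx - 1L
  if (any(i0 < 0 | i0 >= 2L * K * F)) {
    stop("descriptor_index_inverse: index out of range", call. = FALSE)
  }
  f <- i0 %/% (2L * K)
  rem <- i0 %% (2L * K)
  list(f = as.integer(f), k = as.integer(rem %% K),
       order = as.integer(rem %/% K))
}

#' Encode pooled filter responses as an improved Fisher vector
#'
#' For every filter `f` with responses `x_1..x_T` and every mixture
#' component `k`, the first-order statistic is
#' `G_fk = 1/(T sqrt(w_k)) * sum_t gamma_k(x_t) (x_t - mu_k)/s_k`
#' and the second-order statistic is
#' `H_fk = 1/(T sqrt(2 w_k)) * sum_t gamma_k(x_t) (((x_t - mu_k)/s_k)^2 - 1)`.
#' The blocks are assembled in the canonical layout of
#' [descriptor_index()] (length `2*K*F`; 16,384 at the defaults `F = 128`,
#' `K = 64`) and, in the "improved" form, post-processed by element-wise
#' signed square root and global L2 normalization.
#'
#' @param response_set a `filter_response_set` (or plain `T x F` matrix).
#' @param gmm the shared `gmm_model` dictionary.
#' @param signed_sqrt,l2 improved-FV post-processing flags (both default on).
#' @return object of class `fisher_descriptor`: `values` (numeric
#'   `2*K*F`), `K`, `F`, `signed_sqrt`, `l2`, `layout_version`, `case_id`.
#' @export
encode_case <- function(response_set, gmm, signed_sqrt = TRUE, l2 = TRUE) {
  stopifnot(inherits(gmm, "gmm_model"))
  R <- if (inherits(response_set, "filter_response_set")) {
    response_set$responses
  } else as.matrix(response_set)
  Tn <- nrow(R)
  if (is.null(Tn) || Tn == 0L) stop("response set has no responses (T = 0)",
                                    call. = FALSE)
  nf <- ncol(R)
  K <- gmm$K
  sdk <- sqrt(gmm$variances)
  values <- numeric(2L * K * nf)
  for (f in seq_len(nf)) {
    x <- R[, f]
    g <- gmm_posterior(gmm, x)                       # T x K
    u <- sweep(outer(x, gmm$means, "-"), 2L, sdk, "/")
    G <- colSums(g * u) / (Tn * sqrt(gmm$weights))
    H <- colSums(g * (u^2 - 1)) / (Tn * sqrt(2 * gmm$weights))
    values[descriptor_index(f - 1L, 0:(K - 1L), 0L, K, nf)] <- G
    values[descriptor_index(f - 1L, 0:(K - 1L), 1L, K, nf)] <- H
  }
  if (signed_sqrt) values <- sign(values) * sqrt(abs(values))
  if (l2) {
    nrm <- sqrt(sum(values^2))
    if (nrm > 0) values <- values / nrm
  }
  structure(list(values = values, K = K, F = nf,
                 signed_sqrt = signed_sqrt, l2 = l2, layout_version = 1L,
                 case_id = if (inherits(response_set, "filter_response_set"))
                   response_set$case_id else NA_character_),
            class = "fisher_descriptor")
}
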