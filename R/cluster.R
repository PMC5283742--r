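#' Classify dyad positional regularity
#'
#' Emulates a log-likelihood / Bayesian-criterion cluster analysis of the 45
#' dyad ApEn values of a team with a one-dimensional Gaussian mixture:
#' expectation-maximisation is run for each candidate number of components,
#' the number of components is selected by the Schwarz / Bayesian information
#' criterion (unless forced), and components are mapped to regularity terms
#' by ascending mean ApEn -- the lowest-ApEn (most regular, most predictable)
#' component is labelled `"higher"` regularity, the highest `"lower"`.
#'
#' @param apen_values Numeric vector of dyad ApEn values (`>= 6` finite
#'   values unless all are identical).
#' @param k_candidates Candidate component counts (default `1:5`).
#' @param n_restarts Random EM initialisations per k, in addition to a
#'   deterministic quantile-based start (default 20).
#' @param seed Seed making the fit deterministic.
#' @param force_k Optional fixed number of components (replication mode).
#' @return An object of class `regularity_classification`: list with
#'   `class` (character vector aligned with `apen_values`), `component`
#'   (integer, 1 = most regular), `k_selected`, `bic_trace` (named by k; the
#'   maximised-BIC convention `2 logL - p log n`), and `model` (weights,
#'   means, sds ordered by mean).
#' @export
fit_regularity_classes <- function(apen_values, k_candidates = 1:5,
                                   n_restarts = 20, seed = 1L,
                                   force_k = NULL) {
  x <- apen_values
  if (any(!is.finite(x))) stop("ApEn values must be finite", call. = FALSE)
  n <- length(x)
  if (sd(x) == 0) {
    warning("all regularity values identical: single class")
    return(structure(list(class = rep("medium", n),
                          component = rep(1L, n), k_selected = 1L,
                          bic_trace = c(`1` = NA_real_),
                          model = list(weight = 1, mean = x[1], sd = 0)),
                     class = "regularity_classification"))
  }
  if (n < 6) stop("need at least 6 values to classify regularity", call. = FALSE)
  ks <- if (is.null(force_k)) k_candidates else force_k
  ks <- ks[ks <= n]
  fits <- with_seed(seed, lapply(ks, function(k) gmm1d_fit(x, k, n_restarts)))
  bic <- vapply(fits, function(f) f$bic, numeric(1))
  names(bic) <- as.character(ks)
  best <- which.max(bic)
  fit <- fits[[best]]
  k <- ks[best]
  ord <- order(fit$mean)
  rank_of <- match(seq_len(k), ord)
  comp <- rank_of[fit$assignment]
  structure(list(class = regularity_labels(k)[comp],
                 component = comp, k_selected = k, bic_trace = bic,
                 model = list(weight = fit$weight[ord], mean = fit$mean[ord],
                              sd = fit$sd[ord])),
            class = "regularity_classification")
}

# label components ordered by ascending ApEn: low ApEn = high regularity
regularity_labels <- function(k) {
  if (k == 1) return("medium")
  if (k == 2) return(c("higher", "lower"))
  c("higher", rep("medium", k - 2), "lower")
}

gmm1d_fit <- function(x, k, n_restarts) {
  n <- length(x)
  # variance floor: keeps EM away from singleton zero-variance spikes that
  # would otherwise dominate the likelihood and inflate k
  floor_var <- max(1e-2 * var(x), 1e-12)
  best <- NULL
  starts <- c(list(quantile_start(x, k)),
              replicate(n_restarts, random_start(x, k), simplify = FALSE))
  for (st in starts) {
    fit <- tryCatch(gmm1d_em(x, st, floor_var), error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) best <- fit
  }
  if (is.null(best)) {
    return(list(weight = NA, mean = NA, sd = NA, loglik = -Inf, bic = -Inf,
                assignment = rep(1L, n)))
  }
  p <- 3 * k - 1  # k means, k variances, k-1 free weights
  best$bic <- 2 * best$loglik - p * log(n)
  best$assignment <- max.col(best$resp)
  best
}

quantile_start <- function(x, k) {
  mu <- as.numeric(quantile(x, probs = (seq_len(k) - 0.5) / k, type = 7))
  list(weight = rep(1 / k, k), mean = mu, sd = rep(max(sd(x) / k, 1e-6), k))
}

random_start <- function(x, k) {
  mu <- sample(x, k)
  list(weight = rep(1 / k, k), mean = mu, sd = rep(max(sd(x) / k, 1e-6), k))
}

gmm1d_em <- function(x, st, floor_var, max_iter = 500, tol = 1e-10) {
  n <- length(x)
  k <- length(st$mean)
  w <- st$weight; mu <- st$mean; s2 <- pmax(st$sd^2, floor_var)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * dnorm(x, mu[j], sqrt(s2[j])),
                   numeric(n))
    dens <- matrix(dens, n, k)
    rs <- rowSums(dens)
    rs[rs == 0] <- .Machine$double.xmin
    ll <- sum(log(rs))
    resp <- dens / rs
    nk <- colSums(resp)
    if (any(nk < 1e-10)) stop("empty component")
    w <- nk / n
    mu <- colSums(resp * x) / nk
    s2 <- pmax(colSums(resp * (outer(x, mu, "-")^2)) / nk, floor_var)
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(weight = w, mean = mu, sd = sqrt(s2), loglik = ll, resp = resp)
}
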