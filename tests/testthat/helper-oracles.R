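# Independent oracles used to validate the package's core primitives.
# These deliberately use naive, exhaustive formulations.

# --- exhaustive shortest-path census -----------------------------------------
# Enumerates every simple path between every ordered node pair by DFS, keeps
# the minimal-length ones (with relative tolerance), and derives dist, sigma,
# per-intermediate counts, closeness and betweenness from the raw path list.
oracle_path_census <- function(lengths, tol = 1e-9) {
  n <- nrow(lengths)
  paths_between <- function(s, t) {
    out <- list()
    walk <- function(path, len) {
      u <- path[length(path)]
      if (u == t && length(path) > 1) {
        out[[length(out) + 1]] <<- list(path = path, len = len)
        return()
      }
      for (w in seq_len(n)) {
        if (w %in% path || !is.finite(lengths[u, w])) next
        if (w == t) {
          out[[length(out) + 1]] <<- list(path = c(path, w),
                                          len = len + lengths[u, w])
        } else {
          walk(c(path, w), len + lengths[u, w])
        }
      }
    }
    walk(s, 0)
    out
  }
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  sigma_through <- array(0, dim = c(n, n, n))
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      ps <- paths_between(s, t)
      if (!length(ps)) next
      lens <- vapply(ps, `[[`, numeric(1), "len")
      dmin <- min(lens)
      keep <- ps[abs(lens - dmin) <= tol * max(dmin, 1)]
      dist[s, t] <- dmin
      sigma[s, t] <- length(keep)
      for (p in keep) {
        mid <- setdiff(p$path, c(s, t))
        for (v in mid) sigma_through[s, t, v] <- sigma_through[s, t, v] + 1
      }
    }
  }
  list(dist = dist, sigma = sigma, sigma_through = sigma_through)
}

oracle_closeness <- function(oc) {
  n <- nrow(oc$dist)
  sapply(seq_len(n), function(v) {
    d <- oc$dist[v, -v]
    reach <- is.finite(d)
    if (!any(reach)) 0 else 1 / sum(d[reach])
  })
}

oracle_betweenness <- function(oc) {
  n <- nrow(oc$dist)
  sapply(seq_len(n), function(v) {
    tot <- 0
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s == t || s == v || t == v || oc$sigma[s, t] == 0) next
        tot <- tot + oc$sigma_through[s, t, v] / oc$sigma[s, t]
      }
    }
    tot
  })
}

random_pass_digraph <- function(n = 5, p_edge = 0.5, max_count = 5) {
  A <- matrix(0L, n, n, dimnames = list(LETTERS[1:n], LETTERS[1:n]))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && runif(1) < p_edge) A[i, j] <- sample.int(max_count, 1)
    }
  }
  structure(list(nodes = rownames(A), A = A), class = "passing_network")
}

# --- direct ApEn from the definition ----------------------------------------
# Template-by-template evaluation of Phi^m with max-norm comparison,
# self-matches included: the textbook double loop.
oracle_apen <- function(x, m = 2, r_frac = 0.2) {
  x <- x[!is.na(x)]
  N <- length(x)
  r <- r_frac * sd(x)
  phi <- function(mm) {
    M <- N - mm + 1
    E <- sapply(seq_len(mm), function(k) x[k:(k + M - 1)])
    E <- matrix(E, M, mm)
    total <- 0
    for (i in seq_len(M)) {
      dmax <- rep(0, M)
      for (k in seq_len(mm)) {
        dmax <- pmax(dmax, abs(E[, k] - E[i, k]))
      }
      total <- total + log(sum(dmax <= r) / M)
    }
    total / M
  }
  phi(m) - phi(m + 1)
}

# --- nearest-site raster areas ----------------------------------------------
oracle_voronoi_raster <- function(points, pitch = c(106, 65), h = 0.25) {
  gx <- seq(h / 2, pitch[1] - h / 2, by = h)
  gy <- seq(h / 2, pitch[2] - h / 2, by = h)
  G <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  n <- nrow(points)
  best <- rep(1L, nrow(G))
  bestd <- (G[, 1] - points[1, 1])^2 + (G[, 2] - points[1, 2])^2
  for (i in seq_len(n)[-1]) {
    d <- (G[, 1] - points[i, 1])^2 + (G[, 2] - points[i, 2])^2
    upd <- d < bestd
    best[upd] <- i
    bestd[upd] <- d[upd]
  }
  counts <- tabulate(best, nbins = n)
  setNames(counts * h^2, rownames(points))
}

# --- small fixture helpers ---------------------------------------------------
tiny_config <- function(seed = 1, period_min = 1, n_periods = 2, hz = 5) {
  match_config(period_min = period_min, n_periods = n_periods, hz = hz,
               seed = seed)
}

# vectors with exact sample correlation r (residualise then mix)
pair_with_correlation <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  e <- rnorm(n)
  e <- residuals(lm(e ~ x))
  y <- r * scale(x)[, 1] + sqrt(1 - r^2) * scale(e)[, 1]
  list(x = x, y = y)
}

# vector with exact sample mean and sd
fixed_moments <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  mean + sd * scale(z)[, 1]
}
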