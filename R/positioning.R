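#' Approximate Entropy parameters
#'
#' Defaults follow the convention of the movement-analysis literature:
#' embedding dimension `m = 2` and tolerance `r = 0.2 * SD` of the series.
#' Both are echoed in every output because ApEn values are only comparable
#' within one parameterisation.
#'
#' @param m Embedding dimension (template length), `>= 1`.
#' @param r_frac Tolerance as a fraction of the series standard deviation.
#' @return An object of class `apen_params`.
#' @export
apen_params <- function(m = 2L, r_frac = 0.2) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (r_frac <= 0) stop("r_frac must be > 0", call. = FALSE)
  structure(list(m = as.integer(m), r_frac = r_frac), class = "apen_params")
}

#' Approximate Entropy of a time series
#'
#' Classical ApEn: `Phi^m(r) - Phi^(m+1)(r)` where `Phi^m(r)` is the mean log
#' fraction of templates of length `m` lying within max-norm tolerance `r` of
#' each template, self-matches included. Lower values indicate a more
#' regular, predictable series. The tolerance is `r_frac * sd(x)`, which
#' makes the statistic invariant under affine rescaling of the series.
#' Missing samples are removed (not interpolated) before computation.
#'
#' @param x Numeric series; `NA`s are dropped.
#' @param params An [apen_params()].
#' @return ApEn value (non-negative scalar) with attributes `m`, `r`, `N`,
#'   and `constant` (`TRUE` when the series had zero variance, for which the
#'   value is exactly 0).
#' @export
approximate_entropy <- function(x, params = apen_params()) {
  x <- x[!is.na(x)]
  m <- params$m
  N <- length(x)
  if (N <= m + 1) {
    stop("insufficient data for ApEn: need N > m + 1 after removing missing samples",
         call. = FALSE)
  }
  s <- sd(x)
  if (s == 0) {
    return(structure(0, m = m, r = 0, N = N, constant = TRUE))
  }
  r <- params$r_frac * s
  val <- apen_phi(x, m, r) - apen_phi(x, m + 1L, r)
  structure(max(val, 0), m = m, r = r, N = N, constant = FALSE)
}

# Phi^m(r) = (N-m+1)^-1 sum_i log C_i, C_i = #{j: max_k |x[i+k]-x[j+k]| <= r}
# / (N-m+1). Row-blocked so memory stays ~ block * (N-m+1) doubles.
apen_phi <- function(x, m, r) {
  N <- length(x)
  M <- N - m + 1L
  cols <- lapply(seq_len(m), function(k) x[k:(k + M - 1L)])
  logC <- numeric(M)
  block <- max(1L, floor(4e6 / M))
  i <- 1L
  while (i <= M) {
    j <- min(M, i + block - 1L)
    Dmax <- abs(outer(cols[[1L]][i:j], cols[[1L]], "-"))
    if (m > 1L) {
      for (k in 2:m) {
        Dmax <- pmax(Dmax, abs(outer(cols[[k]][i:j], cols[[k]], "-")))
      }
    }
    logC[i:j] <- log(.rowSums(Dmax <= r, j - i + 1L, M) / M)
    i <- j + 1L
  }
  mean(logC)
}

#' Dyad distance time series
#'
#' Euclidean distance between every unordered pair of outfield teammates on
#' the uniform sampling grid; for 10 players this yields exactly 45 series.
#' Frames where either player is missing are marked missing.
#'
#' @param traj A `trajectory_set`.
#' @param team Team label.
#' @return An object of class `dyad_series`: list with `time_s`, `period`,
#'   `pairs` (tibble `player_a`, `player_b`) and `d` (matrix, one column per
#'   dyad in `pairs` order).
#' @export
dyad_distance_series <- function(traj, team) {
  stopifnot(inherits(traj, "trajectory_set"))
  pos <- traj$positions[traj$positions$team == team, ]
  ids <- unique(pos$player_id)
  if (length(ids) < 2) stop("need at least 2 players for dyad distances", call. = FALSE)
  tgrid <- sort(unique(pos$time_s))
  period <- pos$period[match(tgrid, pos$time_s)]
  X <- matrix(NA_real_, length(tgrid), length(ids), dimnames = list(NULL, ids))
  Y <- X
  idx <- cbind(match(pos$time_s, tgrid), match(pos$player_id, ids))
  X[idx] <- pos$x_m
  Y[idx] <- pos$y_m
  pairs <- utils::combn(ids, 2)
  d <- sqrt((X[, pairs[1, ], drop = FALSE] - X[, pairs[2, ], drop = FALSE])^2 +
            (Y[, pairs[1, ], drop = FALSE] - Y[, pairs[2, ], drop = FALSE])^2)
  colnames(d) <- paste(pairs[1, ], pairs[2, ], sep = "|")
  structure(list(time_s = tgrid, period = period,
                 pairs = tibble::tibble(player_a = pairs[1, ],
                                        player_b = pairs[2, ]),
                 d = d),
            class = "dyad_series")
}

#' Per-dyad Approximate Entropy table
#'
#' Computes ApEn for each of the 45 dyad distance series of one team. The
#' series is analysed per period (avoiding the artificial discontinuity at
#' half-time) and the per-period values are combined as a sample-size
#' weighted mean; whole-match concatenation is available with
#' `per_period = FALSE`. Long series can be decimated to at most
#' `max_samples_per_period` samples per period (uniform stride), which
#' bounds the quadratic template search.
#'
#' @param traj A `trajectory_set`.
#' @param team Team label.
#' @param params An [apen_params()].
#' @param per_period Analyse per period and combine (default) or concatenate.
#' @param max_samples_per_period Decimation cap per period (default `Inf`).
#' @param min_valid Dyads with fewer valid samples are flagged low-confidence.
#' @return Tibble `(player_a, player_b, apen, n_valid, low_confidence)`.
#' @export
dyad_apen <- function(traj, team, params = apen_params(), per_period = TRUE,
                      max_samples_per_period = Inf, min_valid = 100) {
  ds <- dyad_distance_series(traj, team)
  periods <- if (per_period) unique(ds$period) else NA
  n_dyads <- nrow(ds$pairs)
  apen <- numeric(n_dyads)
  n_valid <- integer(n_dyads)
  for (j in seq_len(n_dyads)) {
    vals <- numeric(0)
    wts <- numeric(0)
    for (p in periods) {
      x <- if (is.na(p[1])) ds$d[, j] else ds$d[ds$period == p, j]
      x <- x[!is.na(x)]
      if (is.finite(max_samples_per_period) && length(x) > max_samples_per_period) {
        stride <- ceiling(length(x) / max_samples_per_period)
        x <- x[seq(1, length(x), by = stride)]
      }
      if (length(x) > params$m + 1) {
        vals <- c(vals, as.numeric(approximate_entropy(x, params)))
        wts <- c(wts, length(x))
      }
    }
    apen[j] <- if (length(vals)) sum(vals * wts) / sum(wts) else NA_real_
    n_valid[j] <- sum(!is.na(ds$d[, j]))
  }
  tibble::tibble(player_a = ds$pairs$player_a, player_b = ds$pairs$player_b,
                 apen = apen, n_valid = n_valid,
                 low_confidence = n_valid < min_valid)
}

#' Voronoi dominant regions for one frame
#'
#' Planar Voronoi tessellation of player positions clipped to the pitch
#' rectangle, computed cell by cell as the intersection of the pitch with
#' the half-planes closer to the owning player than to each other player
#' (Sutherland-Hodgman clipping). Positions are clamped to the pitch;
#' coincident points receive a deterministic perturbation of 1e-6 m keyed to
#' point index so the tessellation is always defined and reproducible.
#'
#' @param points Two-column matrix or data frame of positions (metres), one
#'   row per player; row names (or a `player_id` column) identify players.
#' @param pitch Length-2 numeric `c(length_m, width_m)`.
#' @return List with `areas` (named vector, m^2; sums to the pitch area) and
#'   `cells` (named list of polygon matrices, closed implicitly).
#' @export
voronoi_frame <- function(points, pitch = c(106, 65)) {
  if (is.data.frame(points)) {
    ids <- points$player_id %||% rownames(points)
    points <- as.matrix(points[, c("x_m", "y_m")])
    rownames(points) <- ids
  }
  n <- nrow(points)
  ids <- rownames(points) %||% as.character(seq_len(n))
  rect <- cbind(c(0, pitch[1], pitch[1], 0), c(0, 0, pitch[2], pitch[2]))
  if (n < 2) {
    area <- pitch[1] * pitch[2]
    return(list(areas = setNames(area, ids[1]),
                cells = setNames(list(rect), ids[1])))
  }
  px <- pmin(pmax(points[, 1], 0), pitch[1])
  py <- pmin(pmax(points[, 2], 0), pitch[2])
  dup <- duplicated(cbind(px, py))
  while (any(dup)) {
    k <- which(dup)
    px[k] <- px[k] + 1e-6 * k
    py[k] <- py[k] + 1e-6 * k
    dup <- duplicated(cbind(px, py))
  }
  cells <- vector("list", n)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    poly <- rect
    for (j in seq_len(n)) {
      if (j == i) next
      nx <- px[j] - px[i]
      ny <- py[j] - py[i]
      cc <- nx * (px[i] + px[j]) / 2 + ny * (py[i] + py[j]) / 2
      poly <- clip_halfplane(poly, nx, ny, cc)
      if (nrow(poly) == 0) break
    }
    cells[[i]] <- poly
    areas[i] <- polygon_area(poly)
  }
  list(areas = setNames(areas, ids), cells = setNames(cells, ids))
}

# Keep the part of `poly` with nx*x + ny*y <= c (Sutherland-Hodgman).
clip_halfplane <- function(poly, nx, ny, c) {
  m <- nrow(poly)
  if (m == 0) return(poly)
  f <- nx * poly[, 1] + ny * poly[, 2] - c
  fn <- f[c(2:m, 1)]
  nxt <- poly[c(2:m, 1), , drop = FALSE]
  out <- matrix(numeric(0), 0, 2)
  for (k in seq_len(m)) {
    inside_a <- f[k] <= 0
    inside_b <- fn[k] <= 0
    if (inside_a) out <- rbind(out, poly[k, ])
    if (inside_a != inside_b) {
      t <- f[k] / (f[k] - fn[k])
      out <- rbind(out, poly[k, ] + t * (nxt[k, ] - poly[k, ]))
    }
  }
  out
}

polygon_area <- function(poly) {
  m <- nrow(poly)
  if (is.null(m) || m < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- x[c(2:m, 1)]; yn <- y[c(2:m, 1)]
  abs(sum(x * yn - xn * y)) / 2
}

#' Per-player Voronoi area summary over a match
#'
#' Tessellates every processed frame jointly over the 20 outfield players of
#' both teams (a dominant region is only meaningful against the opposition)
#' and summarises each player's cell area as a mean and a coefficient of
#' variation (100 * SD / mean, sample SD) across frames.
#'
#' @param traj A `trajectory_set` holding both teams.
#' @param stride_s Seconds between processed frames (default 1 s).
#' @return Tibble `(team, player_id, mean_area_m2, cv_area_pct, n_frames)`,
#'   one row per outfield player.
#' @export
voronoi_summary <- function(traj, stride_s = 1) {
  stopifnot(inherits(traj, "trajectory_set"))
  pos <- traj$positions
  ids <- unique(pos$player_id)
  tgrid <- sort(unique(pos$time_s))
  step <- max(1L, round(stride_s * traj$hz))
  frames <- tgrid[seq(1, length(tgrid), by = step)]
  X <- matrix(NA_real_, length(tgrid), length(ids), dimnames = list(NULL, ids))
  Y <- X
  idx <- cbind(match(pos$time_s, tgrid), match(pos$player_id, ids))
  X[idx] <- pos$x_m
  Y[idx] <- pos$y_m
  sel <- match(frames, tgrid)
  A <- matrix(NA_real_, length(frames), length(ids), dimnames = list(NULL, ids))
  used <- 0L
  for (k in seq_along(sel)) {
    xs <- X[sel[k], ]; ys <- Y[sel[k], ]
    if (anyNA(xs) || anyNA(ys)) next
    vf <- voronoi_frame(cbind(x_m = xs, y_m = ys), traj$pitch)
    A[k, names(vf$areas)] <- vf$areas
    used <- used + 1L
  }
  if (used == 0L) stop("no complete frames available for Voronoi summary", call. = FALSE)
  mean_a <- colMeans(A, na.rm = TRUE)
  sd_a <- apply(A, 2, sd, na.rm = TRUE)
  tibble::tibble(team = pos$team[match(ids, pos$player_id)], player_id = ids,
                 mean_area_m2 = as.numeric(mean_a),
                 cv_area_pct = 100 * as.numeric(sd_a) / as.numeric(mean_a),
                 n_frames = used)
}
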