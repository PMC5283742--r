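#' Read a positional stream from CSV
#'
#' Expects a header row with `time_s`, `player_id`, optionally `team`, and
#' either geodetic (`lat`, `lon`) or pitch-plane (`x_m`, `y_m`) coordinates.
#' Rows duplicated on (player, time) are collapsed to their mean position;
#' the number of collapsed rows is recorded in the `"n_collapsed"` attribute.
#'
#' @param path CSV file path.
#' @return Tibble of raw position records, time-ordered within player, with
#'   attributes `coordinates` (`"geodetic"` or `"pitch"`) and `n_collapsed`.
#' @export
read_positions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty positions file: ", path, call. = FALSE)
  need <- c("time_s", "player_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("schema error: missing columns ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  geodetic <- all(c("lat", "lon") %in% names(df))
  planar <- all(c("x_m", "y_m") %in% names(df))
  if (!geodetic && !planar) {
    stop("schema error: need either (lat, lon) or (x_m, y_m) columns",
         call. = FALSE)
  }
  if (geodetic && (any(abs(df$lat) > 90) || any(abs(df$lon) > 180))) {
    stop("latitude/longitude out of range", call. = FALSE)
  }
  if (!"team" %in% names(df)) df$team <- "unknown"
  coord_cols <- if (geodetic) c("lat", "lon") else c("x_m", "y_m")
  key <- interaction(df$player_id, df$time_s, drop = TRUE)
  n_dup <- nrow(df) - length(levels(key))
  if (n_dup > 0) {
    agg <- aggregate(df[coord_cols], by = list(key = key), FUN = mean)
    first <- df[!duplicated(key), c("time_s", "player_id", "team")]
    first <- first[order(interaction(first$player_id, first$time_s, drop = TRUE)), ]
    agg <- agg[order(agg$key), ]
    df <- cbind(first, agg[coord_cols])
  }
  df <- df[order(df$player_id, df$time_s), c("time_s", "player_id", "team",
                                             coord_cols)]
  out <- tibble::as_tibble(df)
  attr(out, "coordinates") <- if (geodetic) "geodetic" else "pitch"
  attr(out, "n_collapsed") <- n_dup
  out
}

#' Project geodetic coordinates onto the pitch plane
#'
#' Local equirectangular projection around a reference point:
#' `x_east = (lon - lon0) * cos(lat0) * 111320` m/degree and
#' `y_north = (lat - lat0) * 110540` m/degree, then rotated by
#' `rotation_deg` so the pitch length can be aligned with the x axis. For
#' displacements at pitch scale this is distance-preserving to well under
#' 0.5% at moderate latitudes.
#'
#' @param df Tibble with `lat` and `lon` columns (degrees).
#' @param lat0,lon0 Reference point (defaults: centroid of the data).
#' @param rotation_deg Counter-clockwise rotation applied after projection.
#' @return `df` with `x_m`, `y_m` columns added (reference maps to (0, 0)).
#' @export
project_latlon_to_pitch <- function(df, lat0 = NULL, lon0 = NULL,
                                    rotation_deg = 0) {
  if (!all(c("lat", "lon") %in% names(df))) {
    stop("schema error: lat/lon columns required", call. = FALSE)
  }
  if (any(abs(df$lat) > 89)) {
    stop("unsupported latitude: |lat| > 89 degrees", call. = FALSE)
  }
  lat0 <- lat0 %||% mean(range(df$lat))
  lon0 <- lon0 %||% mean(range(df$lon))
  x <- (df$lon - lon0) * cos(lat0 * pi / 180) * 111320
  y <- (df$lat - lat0) * 110540
  th <- rotation_deg * pi / 180
  df$x_m <- cos(th) * x - sin(th) * y
  df$y_m <- sin(th) * x + cos(th) * y
  df
}

#' Resample a positional stream onto a uniform clock
#'
#' Linear interpolation of each player's `x_m`, `y_m` onto a grid at `hz`,
#' anchored at the earliest timestamp in the data. Grid points falling
#' inside an observation gap longer than `max_gap_s` (or outside a player's
#' observed span) are marked missing rather than interpolated. Applying the
#' operation twice is idempotent.
#'
#' @param df Tibble with `time_s`, `player_id`, `team`, `x_m`, `y_m`.
#' @param hz Target sampling rate (default 5).
#' @param max_gap_s Longest gap that may be bridged by interpolation (s).
#' @return Tibble on the uniform grid, with `NA` positions at flagged gaps.
#' @export
resample_uniform <- function(df, hz = 5, max_gap_s = 2) {
  if (!all(c("time_s", "player_id", "x_m", "y_m") %in% names(df))) {
    stop("schema error: need time_s, player_id, x_m, y_m", call. = FALSE)
  }
  t0 <- min(df$time_s)
  t1 <- max(df$time_s)
  if (t1 <= t0) stop("time span must be positive", call. = FALSE)
  grid <- seq(t0, t1 + 1e-9, by = 1 / hz)
  out <- lapply(split(df, df$player_id), function(p) {
    p <- p[order(p$time_s), ]
    p <- p[!is.na(p$x_m) & !is.na(p$y_m), ]
    if (nrow(p) < 2) {
      stop("cannot resample a single sample (player ", p$player_id[1], ")",
           call. = FALSE)
    }
    x <- approx(p$time_s, p$x_m, xout = grid, rule = 1)$y
    y <- approx(p$time_s, p$y_m, xout = grid, rule = 1)$y
    # flag grid points bridged across a gap longer than max_gap_s
    right <- findInterval(grid, p$time_s, left.open = FALSE)
    prev_t <- p$time_s[pmax(right, 1)]
    next_t <- p$time_s[pmin(right + 1, nrow(p))]
    on_sample <- right >= 1 & abs(grid - prev_t) < 1e-9
    gap <- next_t - prev_t
    bad <- !on_sample & (right < 1 | right >= nrow(p) | gap > max_gap_s + 1e-9)
    x[bad] <- NA_real_
    y[bad] <- NA_real_
    tibble::tibble(time_s = grid, player_id = p$player_id[1],
                   team = p$team[1], x_m = x, y_m = y)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Low-pass filter positions
#'
#' Two-pass (forward then backward) moving average with a 5-sample window
#' per player and axis -- a simple zero-phase smoother applied after
#' resampling. Edges are padded by replicating the end samples; missing
#' samples stay missing.
#'
#' @param df Uniform-grid tibble from [resample_uniform()].
#' @param window Moving-average window in samples (odd, default 5).
#' @return Tibble with smoothed `x_m`, `y_m`.
#' @export
lowpass_positions <- function(df, window = 5) {
  if (window %% 2 != 1 || window < 1) stop("window must be odd", call. = FALSE)
  smooth1 <- function(v) {
    ok <- !is.na(v)
    if (sum(ok) < window) return(v)
    idx <- which(ok)
    z <- v[idx]
    h <- (window - 1) / 2
    pad <- c(rep(z[1], h), z, rep(z[length(z)], h))
    ma <- stats::filter(pad, rep(1 / window, window), sides = 2)
    z1 <- as.numeric(ma[(h + 1):(h + length(z))])
    pad <- c(rep(z1[1], h), rev(z1), rep(z1[length(z1)], h))
    ma <- stats::filter(pad, rep(1 / window, window), sides = 2)
    v[idx] <- rev(as.numeric(ma[(h + 1):(h + length(z1))]))
    v
  }
  out <- lapply(split(df, df$player_id), function(p) {
    p <- p[order(p$time_s), ]
    p$x_m <- smooth1(p$x_m)
    p$y_m <- smooth1(p$y_m)
    p
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read a pass-event log from CSV
#'
#' Expects `time_s, team, passer_id, receiver_id, success`. Only successful
#' events are retained for network construction. Rows with
#' `passer == receiver` are rejected with a warning; goalkeeper rows are
#' dropped (goalkeepers are excluded from all analyses) with the count
#' recorded in the `"n_goalkeeper_dropped"` attribute; ids outside the
#' roster raise an error.
#'
#' @param path CSV file path.
#' @param roster Optional character vector of valid outfield player ids.
#' @param goalkeeper_ids Character vector of goalkeeper ids to drop.
#' @return A `pass_log` tibble of successful outfield passes, with
#'   attributes `n_unsuccessful`, `n_self_rejected`, `n_goalkeeper_dropped`.
#' @export
read_passes <- function(path, roster = NULL, goalkeeper_ids = character()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "team", "passer_id", "receiver_id", "success")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("schema error: missing columns ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$success <- df$success %in% c(TRUE, "TRUE", "true", "True", 1, "1")
  n_unsuccessful <- sum(!df$success)
  df <- df[df$success, ]
  self_pass <- df$passer_id == df$receiver_id
  if (any(self_pass)) {
    warning(sum(self_pass), " rows with passer == receiver rejected")
    df <- df[!self_pass, ]
  }
  gk <- df$passer_id %in% goalkeeper_ids | df$receiver_id %in% goalkeeper_ids
  df <- df[!gk, ]
  if (!is.null(roster)) {
    bad <- setdiff(c(df$passer_id, df$receiver_id), roster)
    if (length(bad)) {
      stop("unknown player id in pass log: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  out <- new_pass_log(tibble::as_tibble(df[order(df$time_s), need]))
  attr(out, "n_unsuccessful") <- n_unsuccessful
  attr(out, "n_self_rejected") <- sum(self_pass)
  attr(out, "n_goalkeeper_dropped") <- sum(gk)
  out
}

#' Write a trajectory set to positional CSV
#' @param traj A `trajectory_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_positions_csv <- function(traj, path) {
  utils::write.csv(traj$positions[, c("time_s", "team", "player_id",
                                      "x_m", "y_m")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a pass log to CSV
#' @param log A `pass_log`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_passes_csv <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}

#' Read a match configuration from a YAML file
#'
#' Accepts any subset of the [match_config()] arguments (e.g. `hz`,
#' `period_min`, `teams`, `seed`); unknown keys raise an error rather than
#' being silently ignored.
#'
#' @param path YAML file path.
#' @return A [match_config()].
#' @export
read_config_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read YAML configs", call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  bad <- setdiff(names(y), names(formals(match_config)))
  if (length(bad)) {
    stop("schema error: unknown config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(match_config, y)
}

#' Write a fixture manifest (seed, parameters) as JSON
#' @param fixture A `match_fixture`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(fixture, path) {
  cfg <- fixture$config
  jsonlite::write_json(
    list(seed = cfg$seed, hz = cfg$hz,
         pitch = c(cfg$pitch_length_m, cfg$pitch_width_m),
         period_min = cfg$period_min, n_periods = cfg$n_periods,
         teams = cfg$teams, planted_rho = fixture$planted$rho,
         noise_sd_m = as.list(fixture$planted$noise_sd_m)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
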