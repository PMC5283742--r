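#' Simulate player and ball trajectories
#'
#' Generates formation-anchored, ball-coupled player movement for both teams.
#' Each player's position follows a first-order mean-reverting process around
#' a moving target `anchor + ball_coupling * (ball - pitch centre)`; with the
#' ball pinned to the centre and zero noise every player sits exactly on its
#' anchor. Sampling is uniform at `config$hz`; positions are clamped to the
#' pitch rectangle. The whole simulation is deterministic given `config$seed`.
#'
#' @param config A [match_config()].
#' @param params A [movement_params()].
#' @return An object of class `trajectory_set`: a list with `positions`
#'   (tibble `time_s, period, team, player_id, x_m, y_m`), `ball` (tibble
#'   `time_s, period, x_m, y_m`), `hz`, `pitch`, `roster`.
#' @export
simulate_trajectories <- function(config, params = movement_params()) {
  stopifnot(inherits(config, "match_config"), inherits(params, "movement_params"))
  hz <- config$hz
  n_per <- round(config$period_min * 60 * hz)
  if (n_per < 2) stop("configuration error: period too short for hz", call. = FALSE)
  centre <- c(config$pitch_length_m / 2, config$pitch_width_m / 2)
  roster <- config$roster
  n_players <- nrow(roster)
  sds <- resolve_noise_sd(params$noise_sd_m, roster$player_id)

  with_seed(config$seed, {
    out_pos <- vector("list", config$n_periods)
    out_ball <- vector("list", config$n_periods)
    for (p in seq_len(config$n_periods)) {
      t_local <- (seq_len(n_per) - 1) / hz
      time_s <- (p - 1) * config$period_min * 60 + t_local

      ball <- ou_path_2d(n_per, hz, mean = centre, sd = params$ball_sd_m,
                         tau = params$ball_tau_s)
      xs <- matrix(NA_real_, n_per, n_players)
      ys <- matrix(NA_real_, n_per, n_players)
      gains <- params$ball_coupling * role_coupling_factor(roster$role)
      for (i in seq_len(n_players)) {
        anchor <- c(roster$anchor_x[i], roster$anchor_y[i])
        tgt_x <- anchor[1] + gains[i] * (ball[, 1] - centre[1])
        tgt_y <- anchor[2] + gains[i] * (ball[, 2] - centre[2])
        xs[, i] <- ou_track(tgt_x, hz, params$relaxation_s, sds[i])
        ys[, i] <- ou_track(tgt_y, hz, params$relaxation_s, sds[i])
      }
      xs <- pmin(pmax(xs, 0), config$pitch_length_m)
      ys <- pmin(pmax(ys, 0), config$pitch_width_m)
      ball[, 1] <- pmin(pmax(ball[, 1], 0), config$pitch_length_m)
      ball[, 2] <- pmin(pmax(ball[, 2], 0), config$pitch_width_m)

      out_pos[[p]] <- tibble::tibble(
        time_s = rep(time_s, n_players),
        period = p,
        team = rep(roster$team, each = n_per),
        player_id = rep(roster$player_id, each = n_per),
        x_m = as.vector(xs), y_m = as.vector(ys)
      )
      out_ball[[p]] <- tibble::tibble(time_s = time_s, period = p,
                                      x_m = ball[, 1], y_m = ball[, 2])
    }
    new_trajectory_set(do.call(rbind, out_pos), do.call(rbind, out_ball),
                       config)
  })
}

new_trajectory_set <- function(positions, ball, config) {
  structure(list(positions = positions, ball = ball, hz = config$hz,
                 pitch = c(length_m = config$pitch_length_m,
                           width_m = config$pitch_width_m),
                 roster = config$roster),
            class = "trajectory_set")
}

# Role-graded ball-following gains: defenders hold their line, midfielders
# track the ball closely, forwards push beyond it. The grading makes the
# ball-driven component differential across dyads, so dyad distances carry a
# smooth regular component whose relative weight shrinks as positional noise
# grows -- the single knob controlling dyad regularity.
role_coupling_factor <- function(roles) {
  f <- c(RB = 0.5, RCB = 0.4, LCB = 0.6, LB = 0.7, DCM = 1.0, RCM = 1.1,
         LCM = 0.9, RW = 1.3, CF = 1.5, LW = 1.2)
  out <- f[roles]
  out[is.na(out)] <- 1
  unname(out)
}

resolve_noise_sd <- function(noise_sd_m, player_ids) {
  if (length(noise_sd_m) == 1 && is.null(names(noise_sd_m))) {
    return(setNames(rep(noise_sd_m, length(player_ids)), player_ids))
  }
  if (is.null(names(noise_sd_m)) || !all(player_ids %in% names(noise_sd_m))) {
    stop("noise_sd_m must be a scalar or named by player id", call. = FALSE)
  }
  noise_sd_m[player_ids]
}

# Stationary AR(1) tracking of a moving target: x_t = tgt_t + phi (x_{t-1} -
# tgt_{t-1}) + e_t with e ~ N(0, sd^2 (1 - phi^2)); the deviation from the
# target is a discretised Ornstein-Uhlenbeck process with stationary SD `sd`.
ou_track <- function(target, hz, tau, sd) {
  n <- length(target)
  phi <- exp(-1 / (hz * tau))
  if (sd <= 0) return(target)
  innov <- rnorm(n, 0, sd * sqrt(1 - phi^2))
  innov[1] <- rnorm(1, 0, sd)
  dev <- stats::filter(innov, phi, method = "recursive")
  target + as.numeric(dev)
}

# Smooth stochastic path: an integrated Ornstein-Uhlenbeck velocity process,
# rescaled to the requested stationary amplitude around `mean`. Integration
# makes the path differentiable-looking (highly predictable sample to
# sample), which is what distinguishes ball-driven collective movement from
# positional jitter.
ou_smooth <- function(n, hz, tau, sd_target) {
  v <- ou_track(rep(0, n), hz, tau, 1)
  x <- cumsum(v) / hz
  s <- sd(x)
  if (s == 0) return(rep(0, n))
  (x - mean(x)) / s * sd_target
}

ou_path_2d <- function(n, hz, mean, sd, tau) {
  cbind(mean[1] + if (sd[1] > 0) ou_smooth(n, hz, tau, sd[1]) else rep(0, n),
        mean[2] + if (sd[2] > 0) ou_smooth(n, hz, tau, sd[2]) else rep(0, n))
}

#' Simulate a pass log for one team
#'
#' Draws a chain of `n_passes` successful passes: the first passer is chosen
#' uniformly, each receiver is drawn from the passer's row of the transition
#' matrix, and the receiver becomes the next passer. Event times are uniform
#' over the match duration. Under the uniform topology the 90 directed dyad
#' counts are multinomial with equal expectation; under a hub topology chains
#' alternate through the hub role.
#'
#' @param config A [match_config()].
#' @param topology A [pass_topology()].
#' @param trajectories Optional `trajectory_set`; if supplied, its time span
#'   must cover the match duration.
#' @param team Team label (one of `config$teams`).
#' @param seed Seed for the pass draw (default `config$seed`).
#' @return A `pass_log` tibble `(time_s, team, passer_id, receiver_id,
#'   success)`.
#' @export
simulate_passes <- function(config, topology, trajectories = NULL,
                            team = config$teams[1], seed = config$seed) {
  stopifnot(inherits(config, "match_config"), inherits(topology, "pass_topology"))
  validate_transition_matrix(topology$transition_matrix)
  if (!team %in% config$teams) stop("unknown team: ", team, call. = FALSE)
  if (!is.null(trajectories)) {
    span <- max(trajectories$positions$time_s)
    if (span < match_duration_s(config) - 1 / config$hz - 1e-9) {
      stop("trajectories do not cover the match duration", call. = FALSE)
    }
  }
  ids <- config$roster$player_id[config$roster$team == team]
  P <- apply_hub_bias(topology, config, team)
  n <- topology$n_passes
  if (n == 0) {
    return(new_pass_log(tibble::tibble(time_s = numeric(0), team = character(0),
                                       passer_id = character(0),
                                       receiver_id = character(0),
                                       success = logical(0))))
  }
  with_seed(seed, {
    passer <- integer(n)
    receiver <- integer(n)
    cur <- sample.int(10, 1)
    for (k in seq_len(n)) {
      passer[k] <- cur
      receiver[k] <- sample.int(10, 1, prob = P[cur, ])
      cur <- receiver[k]
    }
    new_pass_log(tibble::tibble(
      time_s = sort(runif(n, 0, match_duration_s(config))),
      team = team, passer_id = ids[passer], receiver_id = ids[receiver],
      success = TRUE))
  })
}

apply_hub_bias <- function(topology, config, team) {
  P <- topology$transition_matrix
  b <- topology$hub_bias
  if (b <= 0) return(P)
  roles <- config$roster$role[config$roster$team == team]
  hub <- match(topology$hub_role, roles)
  if (is.na(hub)) stop("hub_role not in roster", call. = FALSE)
  for (i in seq_len(10)) {
    if (i == hub) next
    P[i, ] <- P[i, ] * (1 - b)
    P[i, hub] <- P[i, hub] + b
  }
  P
}

new_pass_log <- function(df) {
  class(df) <- c("pass_log", class(df))
  df
}

#' Generate a complete synthetic match fixture
#'
#' Co-generates trajectories, pass logs and shot events so that the
#' population correlation between directed-dyad pass counts and dyad
#' positional regularity (Approximate Entropy) equals `planted_rho`.
#' Per-player noise amplitudes are drawn over a wide range, the realised dyad
#' ApEn values are computed from the simulated tracking, and per-dyad pass
#' propensities are built as `rho * z(ApEn) + sqrt(1 - rho^2) * noise`;
#' directed pass counts are then multinomial in those propensities, so the
#' coupling is exact in expectation and attenuated only by multinomial
#' sampling noise.
#'
#' @param config A [match_config()].
#' @param params A [movement_params()]; its `noise_sd_m` (scalar) sets the
#'   geometric centre of the per-player noise range.
#' @param topology A [pass_topology()]; only `n_passes` is used (the dyad
#'   propensities replace the transition matrix).
#' @param planted_rho Target pass-count/ApEn correlation, in `[-1, 0]`.
#' @param shots,goals Named or positional integer vectors per team; shot
#'   events get uniform times and `goals <= shots` is enforced.
#' @param noise_range Multiplicative range of per-player noise SDs around
#'   `params$noise_sd_m`.
#' @param apen ApEn parameterisation used for the planting, a
#'   [apen_params()].
#' @return A list of class `match_fixture` with elements `trajectories`,
#'   `passes` (both teams combined), `shots`, `config`, and `planted`
#'   (the per-team ApEn, propensities and noise SDs actually used).
#' @export
make_match_fixture <- function(config, params = movement_params(),
                               topology = pass_topology(),
                               planted_rho = -0.4,
                               shots = c(6, 4), goals = c(2, 1),
                               noise_range = c(0.4, 2.5),
                               apen = apen_params()) {
  stopifnot(inherits(config, "match_config"))
  if (!is.numeric(planted_rho) || length(planted_rho) != 1 ||
      abs(planted_rho) > 1) {
    stop("planted_rho must be a correlation in [-1, 0]", call. = FALSE)
  }
  if (planted_rho > 0) stop("planted_rho must be in [-1, 0]", call. = FALSE)
  shots <- rep_len(shots, 2); goals <- rep_len(goals, 2)
  if (any(goals > shots) || any(shots < 0) || any(goals < 0)) {
    stop("need 0 <= goals <= shots per team", call. = FALSE)
  }

  with_seed(config$seed, {
    ids <- config$roster$player_id
    base_sd <- params$noise_sd_m[1]
    sds <- setNames(base_sd * exp(runif(length(ids), log(noise_range[1]),
                                        log(noise_range[2]))), ids)
    params$noise_sd_m <- sds
    traj_seed <- sample.int(.Machine$integer.max, 1)
    pass_seed <- sample.int(.Machine$integer.max, 1)
    eps_seed <- sample.int(.Machine$integer.max, 1)

    cfg <- config
    cfg$seed <- traj_seed
    traj <- simulate_trajectories(cfg, params)

    planted <- list(rho = planted_rho, noise_sd_m = sds)
    logs <- list()
    with_seed(eps_seed, {
      for (team in config$teams) {
        dm <- dyad_apen(traj, team, params = apen,
                        max_samples_per_period = 750)
        z <- if (sd(dm$apen) > 0) as.numeric(scale(dm$apen)) else rep(0, nrow(dm))
        eps <- rnorm(nrow(dm))
        mk_v <- function(rr) rr * z + sqrt(max(0, 1 - rr^2)) * eps
        shape <- function(v) v - min(v) + 0.15 * max(diff(range(v)), 1e-12)
        # counts are multinomial around the propensities, which attenuates the
        # realised count-ApEn correlation by sd(mu)/sqrt(sd(mu)^2 + mean(mu));
        # strengthen the latent coupling to compensate (capped near -1, where
        # the sampling noise makes the target unattainable)
        rho_eff <- planted_rho
        if (planted_rho != 0 && topology$n_passes > 0) {
          mu0 <- topology$n_passes * shape(mk_v(planted_rho)) /
            (2 * sum(shape(mk_v(planted_rho))))
          att <- sd(mu0) / sqrt(sd(mu0)^2 + mean(mu0))
          if (att > 0) rho_eff <- max(-0.99, planted_rho / att)
        }
        v <- mk_v(rho_eff)
        w <- shape(v)
        prob <- rep(w / sum(w) / 2, each = 2)  # both directions share the dyad
        counts <- as.integer(rmultinom(1, topology$n_passes, prob))
        passer <- as.vector(rbind(dm$player_a, dm$player_b))
        receiver <- as.vector(rbind(dm$player_b, dm$player_a))
        n <- sum(counts)
        ord <- if (n > 0) sample.int(n) else integer(0)
        logs[[team]] <- tibble::tibble(
          time_s = sort(runif(n, 0, match_duration_s(config))),
          team = team,
          passer_id = rep(passer, counts)[ord],
          receiver_id = rep(receiver, counts)[ord],
          success = TRUE)
        planted[[paste0("dyads_", team)]] <-
          tibble::tibble(player_a = dm$player_a, player_b = dm$player_b,
                         apen = dm$apen, propensity = w)
      }
    })
    passes <- new_pass_log(do.call(rbind, logs))

    shot_rows <- lapply(seq_along(config$teams), function(i) {
      n <- shots[i]
      if (n == 0) {
        return(tibble::tibble(time_s = numeric(0), team = character(0),
                              goal = logical(0)))
      }
      tibble::tibble(time_s = sort(runif(n, 0, match_duration_s(config))),
                     team = config$teams[i],
                     goal = seq_len(n) %in% sample.int(n, goals[i]))
    })
    structure(list(trajectories = traj, passes = passes,
                   shots = do.call(rbind, shot_rows),
                   config = config, planted = planted),
              class = "match_fixture")
  })
}
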