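#' Default 1-4-3-3 outfield formation anchors
#'
#' Anchor coordinates for the ten outfield roles of a 1-4-3-3 formation
#' (goalkeeper excluded from all analyses), for a team defending the goal at
#' `x = 0` and attacking towards `x = pitch_length_m`. Coordinates are metres
#' in the pitch frame: origin at one corner, x along the pitch length, y along
#' the width.
#'
#' @param pitch_length_m,pitch_width_m Pitch dimensions in metres.
#' @param mirrored If `TRUE`, reflect anchors through the halfway line (the
#'   opposing team's copy of the same formation).
#' @return A data frame with columns `role`, `anchor_x`, `anchor_y`.
#' @export
default_formation <- function(pitch_length_m = 106, pitch_width_m = 65,
                              mirrored = FALSE) {
  # fractions of pitch length/width; 4 defenders, 3 midfielders, 3 forwards
  f <- data.frame(
    role = c("RB", "RCB", "LCB", "LB", "DCM", "RCM", "LCM", "RW", "CF", "LW"),
    fx = c(0.24, 0.22, 0.22, 0.24, 0.40, 0.52, 0.52, 0.72, 0.75, 0.72),
    fy = c(0.14, 0.38, 0.62, 0.86, 0.50, 0.26, 0.74, 0.16, 0.50, 0.84),
    stringsAsFactors = FALSE
  )
  x <- f$fx * pitch_length_m
  if (mirrored) x <- pitch_length_m - x
  data.frame(role = f$role, anchor_x = x, anchor_y = f$fy * pitch_width_m,
             stringsAsFactors = FALSE)
}

#' Match configuration
#'
#' Describes the pitch, sampling clock, match structure and the two rosters
#' used by both the synthetic generator and the analysis pipeline. Each team
#' fields ten outfield players in a 1-4-3-3 shape; goalkeepers are excluded
#' throughout.
#'
#' @param pitch_length_m,pitch_width_m Pitch dimensions in metres (default
#'   106 x 65).
#' @param hz Sampling rate of the positional stream in Hz (default 5).
#' @param period_min Minutes per period (default 25).
#' @param n_periods Number of periods (default 2).
#' @param teams Character vector of two team labels.
#' @param formation Data frame `(role, anchor_x, anchor_y)` for the first
#'   team; the second team uses its mirror image. Defaults to
#'   [default_formation()].
#' @param seed Integer seed controlling all randomness downstream.
#' @return An object of class `match_config`.
#' @export
match_config <- function(pitch_length_m = 106, pitch_width_m = 65, hz = 5,
                         period_min = 25, n_periods = 2,
                         teams = c("home", "away"), formation = NULL,
                         seed = 1L) {
  if (pitch_length_m <= 0 || pitch_width_m <= 0) {
    stop("configuration error: pitch dimensions must be positive", call. = FALSE)
  }
  if (hz <= 0) stop("configuration error: hz must be positive", call. = FALSE)
  if (period_min <= 0 || n_periods < 1) {
    stop("configuration error: non-positive match duration", call. = FALSE)
  }
  if (length(teams) != 2 || anyDuplicated(teams)) {
    stop("configuration error: exactly two distinct team labels required",
         call. = FALSE)
  }
  formation <- formation %||% default_formation(pitch_length_m, pitch_width_m)
  if (nrow(formation) != 10) {
    stop("configuration error: exactly 10 outfield roles per team", call. = FALSE)
  }
  if (any(formation$anchor_x < 0 | formation$anchor_x > pitch_length_m |
          formation$anchor_y < 0 | formation$anchor_y > pitch_width_m)) {
    stop("configuration error: formation anchors outside pitch rectangle",
         call. = FALSE)
  }
  roster <- do.call(rbind, lapply(seq_along(teams), function(i) {
    f <- formation
    if (i == 2) f$anchor_x <- pitch_length_m - f$anchor_x
    data.frame(team = teams[i],
               player_id = paste(teams[i], f$role, sep = "_"),
               role = f$role, anchor_x = f$anchor_x, anchor_y = f$anchor_y,
               stringsAsFactors = FALSE)
  }))
  structure(
    list(pitch_length_m = pitch_length_m, pitch_width_m = pitch_width_m,
         hz = hz, period_min = period_min, n_periods = n_periods,
         teams = teams, roster = roster, seed = as.integer(seed)),
    class = "match_config"
  )
}

#' Movement model parameters
#'
#' Parameters of the mean-reverting position process used by the synthetic
#' generator: each player relaxes towards `anchor + ball_coupling * (ball -
#' pitch centre)` with time constant `relaxation_s`, perturbed by stationary
#' noise of standard deviation `noise_sd_m` per axis. The ball follows an
#' independent mean-reverting path around the pitch centre.
#'
#' @param ball_coupling Gain in `[0, 1]` towards the ball displacement from
#'   the pitch centre.
#' @param noise_sd_m Stationary positional jitter SD in metres; a scalar, or a
#'   vector named by player id for heterogeneous regularity.
#' @param relaxation_s Mean-reversion time constant of the player process, s.
#' @param ball_sd_m Length-2 stationary SD of the ball path (x, y), metres;
#'   `c(0, 0)` pins the ball to the pitch centre.
#' @param ball_tau_s Mean-reversion time constant of the ball path, s.
#' @return An object of class `movement_params`.
#' @export
movement_params <- function(ball_coupling = 0.3, noise_sd_m = 1.0,
                            relaxation_s = 8, ball_sd_m = c(20, 12),
                            ball_tau_s = 15) {
  if (any(noise_sd_m < 0)) stop("noise_sd_m must be >= 0", call. = FALSE)
  if (ball_coupling < 0 || ball_coupling > 1) {
    stop("ball_coupling must be in [0, 1]", call. = FALSE)
  }
  if (relaxation_s <= 0 || ball_tau_s <= 0) {
    stop("relaxation time constants must be positive", call. = FALSE)
  }
  structure(list(ball_coupling = ball_coupling, noise_sd_m = noise_sd_m,
                 relaxation_s = relaxation_s,
                 ball_sd_m = rep_len(ball_sd_m, 2), ball_tau_s = ball_tau_s),
            class = "movement_params")
}

#' Passing topology
#'
#' Receiver-probability structure for the pass generator of one team: a
#' 10 x 10 row-stochastic transition matrix (zero diagonal) giving the
#' probability of each receiver conditional on the passer, the total number
#' of successful passes to generate, and an optional hub bias that
#' concentrates flow through one role so that pass chains alternate
#' hub-to-others.
#'
#' @param transition_matrix 10 x 10 row-stochastic matrix, zero diagonal;
#'   `NULL` for the uniform topology (each of the 9 teammates equally likely).
#' @param n_passes Total successful passes to generate for the team.
#' @param hub_bias In `[0, 1)`: probability mass redirected from every
#'   non-hub passer to the hub role.
#' @param hub_role Role receiving the hub bias (default `"DCM"`).
#' @return An object of class `pass_topology`.
#' @export
pass_topology <- function(transition_matrix = NULL, n_passes = 450,
                          hub_bias = 0, hub_role = "DCM") {
  if (n_passes < 0) stop("n_passes must be >= 0", call. = FALSE)
  if (hub_bias < 0 || hub_bias >= 1) stop("hub_bias must be in [0, 1)", call. = FALSE)
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(1 / 9, 10, 10)
    diag(transition_matrix) <- 0
  }
  validate_transition_matrix(transition_matrix)
  structure(list(transition_matrix = transition_matrix,
                 n_passes = as.integer(n_passes), hub_bias = hub_bias,
                 hub_role = hub_role),
            class = "pass_topology")
}

validate_transition_matrix <- function(P, tol = 1e-9) {
  if (!is.matrix(P) || nrow(P) != 10 || ncol(P) != 10) {
    stop("transition_matrix must be 10 x 10", call. = FALSE)
  }
  if (any(P < 0)) stop("transition_matrix entries must be >= 0", call. = FALSE)
  if (any(abs(diag(P)) > 0)) {
    stop("transition_matrix diagonal must be zero (no self-passes)", call. = FALSE)
  }
  if (any(abs(rowSums(P) - 1) > tol)) {
    stop("transition_matrix rows must sum to 1", call. = FALSE)
  }
  invisible(P)
}

match_duration_s <- function(config) config$n_periods * config$period_min * 60

#' @export
print.match_config <- function(x, ...) {
  cat(sprintf("<match_config> pitch %g x %g m, %d x %g min at %g Hz, teams: %s\n",
              x$pitch_length_m, x$pitch_width_m, x$n_periods, x$period_min,
              x$hz, paste(x$teams, collapse = " vs ")))
  invisible(x)
}
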