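#' Correlate pass counts with dyad positional regularity
#'
#' Pairs each dyad's ApEn with its pass count: in `"directed"` mode every
#' unordered dyad contributes both directions (90 pairs for 10 players, the
#' ApEn value duplicated); in `"undirected"` mode the two directions are
#' summed (45 pairs). When every ApEn value is identical the correlation is
#' undefined and the result is returned flagged `"unclear"` with
#' `degenerate = TRUE` instead of failing the pipeline.
#'
#' @param net A `passing_network` of the team.
#' @param dyads Tibble from [dyad_apen()].
#' @param mode `"directed"` (default) or `"undirected"`.
#' @param conf Confidence level.
#' @return A `correlation_result` (see [pearson_ci()]) with a `mode` field.
#' @export
correlate_passes_regularity <- function(net, dyads,
                                        mode = c("directed", "undirected"),
                                        conf = 0.90) {
  mode <- match.arg(mode)
  a <- dyads$player_a
  b <- dyads$player_b
  if (!all(c(a, b) %in% net$nodes)) {
    stop("dyad players missing from the passing network", call. = FALSE)
  }
  p_ab <- net$A[cbind(a, b)]
  p_ba <- net$A[cbind(b, a)]
  if (mode == "directed") {
    counts <- c(p_ab, p_ba)
    apen <- rep(dyads$apen, 2)
  } else {
    counts <- p_ab + p_ba
    apen <- dyads$apen
  }
  ok <- is.finite(apen)
  if (sum(ok) < 4) stop("fewer than 4 usable dyads", call. = FALSE)
  if (sd(apen[ok]) == 0) {
    res <- structure(list(r = NA_real_, lower = NA_real_, upper = NA_real_,
                          n = sum(ok), conf = conf, magnitude = NA_character_,
                          clarity = "unclear"),
                     class = "correlation_result")
    res$degenerate <- TRUE
    res$mode <- mode
    return(res)
  }
  res <- pearson_ci(counts[ok], apen[ok], conf = conf)
  res$degenerate <- FALSE
  res$mode <- mode
  res
}

count_by_segment <- function(time_s, duration_s, n_segments) {
  breaks <- seq(0, duration_s, length.out = n_segments + 1)
  as.numeric(table(cut(time_s, breaks, include.lowest = TRUE)))
}

#' Between-team comparison of performance indicators
#'
#' Standardized mean differences (pooled SD, 90% limits) for closeness and
#' betweenness use the ten per-player centrality scores of each team as the
#' groups. Pass and shot totals are compared as percent differences; their
#' within-match variability comes from splitting the match into
#' `n_segments` equal time segments (default 6) and treating per-segment
#' counts as replicates (log mode when all segment counts are positive,
#' raw-difference mode otherwise). Teams are designated lower / higher
#' performance by number of shots, ties broken by efficacy; an unresolved
#' tie is flagged. Effects are oriented B minus A, so swapping the teams
#' negates every standardized difference.
#'
#' @param team_a,team_b Lists with elements `centrality` (tibble from
#'   [centrality_scores()]), `pass_times`, `shot_times` (event-time
#'   vectors), `shots`, `goals` (counts), `team` (label).
#' @param duration_s Match duration in seconds.
#' @param n_segments Number of equal time segments (default 6).
#' @return List with `closeness`, `betweenness` (`effect_result`), `passes`,
#'   `shots` (`percent_result`), `efficacy` per team, and `designation`.
#' @export
compare_teams <- function(team_a, team_b, duration_s, n_segments = 6) {
  eff <- list()
  eff$closeness <- cohen_d_pooled(team_a$centrality$closeness,
                                  team_b$centrality$closeness)
  eff$betweenness <- cohen_d_pooled(team_a$centrality$betweenness,
                                    team_b$centrality$betweenness)
  seg <- function(x) count_by_segment(x, duration_s, n_segments)
  pct_safe <- function(a, b) {
    if (all(a > 0) && all(b > 0)) {
      percent_difference(a, b, mode = "log")
    } else {
      percent_difference(a, b, mode = "raw")
    }
  }
  eff$passes <- pct_safe(seg(team_a$pass_times), seg(team_b$pass_times))
  eff$shots <- if (length(team_a$shot_times) && length(team_b$shot_times)) {
    pct_safe(seg(team_a$shot_times), seg(team_b$shot_times))
  } else {
    NULL
  }
  eff$efficacy <- c(setNames(efficacy(team_a$goals, team_a$shots), team_a$team),
                    setNames(efficacy(team_b$goals, team_b$shots), team_b$team))
  higher <- if (team_a$shots > team_b$shots) team_a$team
            else if (team_b$shots > team_a$shots) team_b$team
            else if (eff$efficacy[1] > eff$efficacy[2]) team_a$team
            else if (eff$efficacy[2] > eff$efficacy[1]) team_b$team
            else NA_character_
  eff$designation <- list(higher_performance = higher,
                          tie = is.na(higher))
  eff
}

#' Run the full match analysis
#'
#' Orchestrates the pipeline for one match: pass-network construction and
#' centralities per team, dyad distance / ApEn / regularity classification
#' per team, a joint Voronoi dominant-region summary, efficacy, between-team
#' effect sizes, and the pass-count/regularity correlation per team. All
#' stages are deterministic given `config$seed`.
#'
#' @param fixture A `match_fixture` from [make_match_fixture()], or a list
#'   with elements `trajectories` (`trajectory_set`), `passes` (`pass_log`
#'   covering both teams), `shots` (tibble `time_s, team, goal`) and
#'   `config` (a [match_config()]).
#' @param convention Edge-length convention for centralities.
#' @param apen ApEn parameterisation.
#' @param max_samples_per_period Decimation cap for the ApEn stage.
#' @param voronoi_stride_s Seconds between tessellated frames.
#' @param n_segments Segments for the count comparisons.
#' @return An object of class `match_report`.
#' @export
run_match_analysis <- function(fixture, convention = "reciprocal",
                               apen = apen_params(),
                               max_samples_per_period = 1500,
                               voronoi_stride_s = 1, n_segments = 6) {
  config <- fixture$config
  traj <- fixture$trajectories
  passes <- fixture$passes
  shots <- fixture$shots
  duration <- match_duration_s(config)

  teams <- config$teams
  per_team <- list()
  for (team in teams) {
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        stop(sprintf("stage %s failed for team %s: %s", what, team,
                     conditionMessage(e)), call. = FALSE)
      })
    }
    roster <- config$roster$player_id[config$roster$team == team]
    log <- passes[passes$team == team, ]
    net <- stage("network", build_adjacency(log, roster))
    cent <- stage("centrality", centrality_scores(net, convention))
    dyads <- stage("positioning",
                   dyad_apen(traj, team, params = apen,
                             max_samples_per_period = max_samples_per_period))
    dyads$passes_ab <- net$A[cbind(dyads$player_a, dyads$player_b)]
    dyads$passes_ba <- net$A[cbind(dyads$player_b, dyads$player_a)]
    classes <- stage("clustering",
                     fit_regularity_classes(dyads$apen, seed = config$seed))
    dyads$regularity_class <- classes$class
    corr_dir <- stage("correlation",
                      correlate_passes_regularity(net, dyads, "directed"))
    corr_undir <- stage("correlation",
                        correlate_passes_regularity(net, dyads, "undirected"))
    sh <- shots[shots$team == team, ]
    per_team[[team]] <- list(
      team = team, network = net, centrality = cent, dyads = dyads,
      classification = classes,
      correlation = list(directed = corr_dir, undirected = corr_undir),
      pass_times = log$time_s, shot_times = sh$time_s,
      shots = nrow(sh), goals = sum(sh$goal))
  }

  vor <- voronoi_summary(traj, stride_s = voronoi_stride_s)
  between <- compare_teams(per_team[[teams[1]]], per_team[[teams[2]]],
                           duration, n_segments)

  structure(list(teams = per_team, voronoi = vor, between = between,
                 provenance = list(seed = config$seed,
                                   convention = convention,
                                   apen = unclass(apen),
                                   max_samples_per_period = max_samples_per_period,
                                   voronoi_stride_s = voronoi_stride_s,
                                   n_segments = n_segments)),
            class = "match_report")
}

#' Write a match report to disk
#'
#' Emits the CSV tables (centralities, dyad metrics with regularity class,
#' Voronoi summary), a GraphML export per team, and a JSON report holding
#' the between-team effects, correlations, efficacies and provenance.
#'
#' @param report A `match_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_match_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (team in names(report$teams)) {
    tt <- report$teams[[team]]
    utils::write.csv(tt$centrality,
                     file.path(out_dir, paste0("centrality_", team, ".csv")),
                     row.names = FALSE)
    utils::write.csv(tt$dyads,
                     file.path(out_dir, paste0("dyads_", team, ".csv")),
                     row.names = FALSE)
    export_network(tt$network, tt$centrality,
                   file.path(out_dir, paste0("network_", team, ".graphml")))
  }
  utils::write.csv(report$voronoi, file.path(out_dir, "voronoi.csv"),
                   row.names = FALSE)
  simplify_corr <- function(cr) {
    list(r = cr$r, lower = cr$lower, upper = cr$upper, n = cr$n,
         magnitude = cr$magnitude, clarity = cr$clarity, mode = cr$mode)
  }
  json <- list(
    between = list(
      closeness = unclass(report$between$closeness),
      betweenness = unclass(report$between$betweenness),
      passes = unclass(report$between$passes),
      shots = if (is.null(report$between$shots)) NULL
              else unclass(report$between$shots),
      efficacy = as.list(report$between$efficacy),
      designation = report$between$designation),
    correlations = lapply(report$teams, function(tt) {
      lapply(tt$correlation, simplify_corr)
    }),
    cluster = lapply(report$teams, function(tt) {
      list(k_selected = tt$classification$k_selected,
           bic_trace = as.list(tt$classification$bic_trace))
    }),
    provenance = report$provenance)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(out_dir)
}
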