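#' Build the directed weighted passing adjacency
#'
#' `A[v, w]` counts the successful passes from player `v` to player `w`; for
#' 10 outfield players there are 45 unordered dyads and 90 possible directed
#' entries. The matrix total always equals the number of successful passes in
#' the log.
#'
#' @param log A `pass_log` (already filtered to successful passes of one
#'   team, see [read_passes()]).
#' @param roster Character vector of the team's outfield player ids.
#' @return An object of class `passing_network`: list with `nodes` and the
#'   integer matrix `A`.
#' @export
build_adjacency <- function(log, roster) {
  if (anyDuplicated(roster)) stop("duplicate ids in roster", call. = FALSE)
  bad <- setdiff(c(log$passer_id, log$receiver_id), roster)
  if (length(bad)) {
    stop("pass event references players outside the roster: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- length(roster)
  A <- matrix(0L, n, n, dimnames = list(roster, roster))
  if (nrow(log)) {
    keep <- if ("success" %in% names(log)) log$success else TRUE
    tab <- table(factor(log$passer_id[keep], roster),
                 factor(log$receiver_id[keep], roster))
    A[] <- as.integer(tab)
  }
  structure(list(nodes = roster, A = A), class = "passing_network")
}

#' Edge lengths from pass counts
#'
#' Turns the pass-count adjacency into geodesic edge lengths. Under the
#' `"reciprocal"` convention more passes make a pair closer
#' (`length = 1 / count`); `"hop"` treats every existing edge as length 1
#' (unweighted replication). Absent edges get infinite length.
#'
#' @param net A `passing_network`.
#' @param convention `"reciprocal"` (default) or `"hop"`.
#' @return Numeric matrix of edge lengths with `Inf` for absent edges and a
#'   `"convention"` attribute.
#' @export
edge_distances <- function(net, convention = c("reciprocal", "hop")) {
  convention <- match.arg(convention)
  A <- net$A
  L <- matrix(Inf, nrow(A), ncol(A), dimnames = dimnames(A))
  pos <- A > 0
  L[pos] <- if (convention == "reciprocal") 1 / A[pos] else 1
  diag(L) <- 0
  attr(L, "convention") <- convention
  L
}

#' All-pairs shortest-path census
#'
#' Dijkstra from every source with shortest-path counting: geodesic lengths
#' `dist(s, t)`, the number of shortest paths `sigma[s, t]`, and the number
#' passing through each intermediate node, obtained from the standard
#' decomposition `sigma_st(v) = sigma_sv * sigma_vt` when
#' `dist(s, v) + dist(v, t) = dist(s, t)`. Equal-length ties are detected
#' with relative tolerance `tol` to avoid floating-point path-splitting
#' artefacts with reciprocal edge lengths.
#'
#' @param lengths Square matrix of non-negative edge lengths (`Inf` = no
#'   edge, zero diagonal).
#' @param tol Relative tolerance for tie detection.
#' @return An object of class `path_census`: list with `dist`, `sigma`,
#'   `sigma_through` (3-d array `[s, t, v]`) and `convention`.
#' @export
shortest_path_census <- function(lengths, tol = 1e-12) {
  if (any(lengths[is.finite(lengths)] < 0)) {
    stop("negative edge lengths are not allowed", call. = FALSE)
  }
  n <- nrow(lengths)
  ids <- rownames(lengths) %||% as.character(seq_len(n))
  dist <- matrix(Inf, n, n, dimnames = list(ids, ids))
  sigma <- matrix(0, n, n, dimnames = list(ids, ids))
  for (s in seq_len(n)) {
    res <- dijkstra_count(lengths, s, tol)
    dist[s, ] <- res$dist
    sigma[s, ] <- res$sigma
  }
  diag(dist) <- 0
  diag(sigma) <- 1
  sthrough <- array(0, dim = c(n, n, n), dimnames = list(ids, ids, ids))
  for (v in seq_len(n)) {
    dv <- outer(dist[, v], dist[v, ], "+")
    on_geo <- is.finite(dv) & is.finite(dist) &
      abs(dv - dist) <= tol * pmax(dv, dist, 1)
    sv <- outer(sigma[, v], sigma[v, ])
    contrib <- ifelse(on_geo, sv, 0)
    contrib[v, ] <- 0
    contrib[, v] <- 0
    diag(contrib) <- 0
    sthrough[, , v] <- contrib
  }
  structure(list(dist = dist, sigma = sigma, sigma_through = sthrough,
                 convention = attr(lengths, "convention") %||% "custom",
                 tol = tol),
            class = "path_census")
}

dijkstra_count <- function(lengths, s, tol) {
  n <- nrow(lengths)
  dist <- rep(Inf, n)
  sigma <- rep(0, n)
  dist[s] <- 0
  sigma[s] <- 1
  done <- rep(FALSE, n)
  for (iter in seq_len(n)) {
    u <- which(!done & dist == min(dist[!done]))[1]
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    for (w in seq_len(n)) {
      if (done[w] || !is.finite(lengths[u, w]) || u == w) next
      alt <- dist[u] + lengths[u, w]
      if (!is.finite(dist[w]) || alt < dist[w] - tol * max(alt, dist[w], 1)) {
        dist[w] <- alt
        sigma[w] <- sigma[u]
      } else if (is.finite(dist[w]) &&
                 abs(alt - dist[w]) <= tol * max(alt, dist[w], 1)) {
        sigma[w] <- sigma[w] + sigma[u]
      }
    }
  }
  list(dist = dist, sigma = sigma)
}

#' Closeness centrality
#'
#' The reciprocal of a node's farness: `1 / sum(dist(v, w))` over the targets
#' `w` reachable from `v`. A node reaching no other node scores 0. The number
#' of reachable targets is reported alongside, since summing over reachable
#' targets only would otherwise hide weak connectivity.
#'
#' @param census A `path_census`.
#' @return Tibble `(player_id, closeness, reachable_count)`.
#' @export
closeness_centrality <- function(census) {
  d <- census$dist
  diag(d) <- NA
  reach <- rowSums(is.finite(d), na.rm = TRUE)
  farness <- rowSums(ifelse(is.finite(d), d, 0), na.rm = TRUE)
  score <- ifelse(reach > 0 & farness > 0, 1 / farness,
                  ifelse(reach > 0, Inf, 0))
  tibble::tibble(player_id = rownames(d), closeness = as.numeric(score),
                 reachable_count = as.integer(reach))
}

#' Betweenness centrality
#'
#' Sum over ordered pairs `(s, t)` (both different from `v`, `t` reachable
#' from `s`) of the pair-dependency `sigma_st(v) / sigma_st`: the fraction of
#' geodesics between other players that pass through `v`. Unnormalised;
#' zero for every node of a complete equal-weight digraph.
#'
#' @param census A `path_census`.
#' @return Tibble `(player_id, betweenness)`.
#' @export
betweenness_centrality <- function(census) {
  n <- nrow(census$dist)
  ids <- rownames(census$dist)
  ratio <- census$sigma_through
  for (v in seq_len(n)) {
    sl <- ratio[, , v]
    ok <- census$sigma > 0
    sl[ok] <- sl[ok] / census$sigma[ok]
    sl[!ok] <- 0
    ratio[, , v] <- sl
  }
  tibble::tibble(player_id = ids,
                 betweenness = as.numeric(apply(ratio, 3, sum)))
}

#' Centrality table for a passing network
#'
#' Convenience wrapper: adjacency -> edge lengths -> path census ->
#' closeness + betweenness, under one edge-length convention.
#'
#' @param net A `passing_network`.
#' @param convention Edge-length convention, see [edge_distances()].
#' @return Tibble `(player_id, closeness, betweenness, reachable_count)`
#'   with the convention recorded as an attribute.
#' @export
centrality_scores <- function(net, convention = "reciprocal") {
  census <- shortest_path_census(edge_distances(net, convention))
  out <- closeness_centrality(census)
  out$betweenness <- betweenness_centrality(census)$betweenness
  attr(out, "convention") <- convention
  out
}

#' Export a passing network to GraphML
#'
#' Writes the directed weighted network with node attributes (closeness,
#' betweenness, role, optional mean Voronoi area) and the pass count as edge
#' weight, for rendering in external tools. Re-importing with
#' [import_network()] reproduces the adjacency exactly.
#'
#' @param net A `passing_network`.
#' @param scores Optional centrality tibble from [centrality_scores()].
#' @param path Output file path.
#' @param roles Optional named character vector of roles by player id.
#' @param mean_area Optional named numeric vector of mean Voronoi areas.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, scores = NULL, path, roles = NULL,
                           mean_area = NULL) {
  g <- igraph::graph_from_adjacency_matrix(net$A, mode = "directed",
                                           weighted = "passes")
  if (!is.null(scores)) {
    ord <- match(igraph::V(g)$name, scores$player_id)
    g <- igraph::set_vertex_attr(g, "closeness", value = scores$closeness[ord])
    g <- igraph::set_vertex_attr(g, "betweenness", value = scores$betweenness[ord])
  }
  if (!is.null(roles)) {
    g <- igraph::set_vertex_attr(g, "role",
                                 value = unname(roles[igraph::V(g)$name]))
  }
  if (!is.null(mean_area)) {
    g <- igraph::set_vertex_attr(g, "mean_area_m2",
                                 value = unname(mean_area[igraph::V(g)$name]))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Import a GraphML passing network
#'
#' @param path GraphML file written by [export_network()].
#' @return A `passing_network`.
#' @export
import_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::ecount(g) == 0) {
    A <- matrix(0L, igraph::vcount(g), igraph::vcount(g),
                dimnames = list(igraph::V(g)$name, igraph::V(g)$name))
  } else {
    A <- as.matrix(igraph::as_adjacency_matrix(g, attr = "passes",
                                               sparse = FALSE))
  }
  storage.mode(A) <- "integer"
  structure(list(nodes = rownames(A), A = A), class = "passing_network")
}
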