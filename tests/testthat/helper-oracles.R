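# Shared fixtures and independent oracles used across the test files.
# The oracles deliberately use a different computational route than the
# package (exhaustive simple-path enumeration, permutation recursion over
# igraph distances) so agreement is meaningful.

# small named worlds ----------------------------------------------------------

path_graph <- function(n = 5L) {
  ids <- LETTERS[seq_len(n)]
  spatial_graph(ids, lapply(seq_len(n - 1L), function(i) ids[i:(i + 1L)]))
}

star_graph <- function(leaves = 4L) {
  ids <- c("HUB", paste0("S", seq_len(leaves)))
  spatial_graph(ids, lapply(ids[-1L], function(s) c("HUB", s)))
}

# a 5-location manor with one item per wing, used for scripted playthroughs:
#   A - B - C        items: X1 at B, X2 at D, X3 at E
#       |
#   D - E
manor_world <- function() {
  nodes <- data.frame(
    id = c("A", "B", "C", "D", "E", "X1", "X2", "X3"),
    kind = c(rep("location", 5), rep("object", 3)),
    label = c("hall", "corridor", "study", "kitchen", "cellar",
              "letter", "map", "flask"))
  edges <- list(c("A", "B"), c("B", "C"), c("B", "E"), c("D", "E"),
                c("B", "X1"), c("D", "X2"), c("E", "X3"))
  graph <- spatial_graph(nodes, edges, game_start_node = "A")
  t1 <- task("T1", "A",
             data.frame(id = c("T1_o1", "T1_o2"),
                        target_node = c("X1", "X3")))
  t2 <- task("T2", "X3",
             data.frame(id = "T2_o1", target_node = "X2"))
  list(graph = graph, tasks = task_set(list(t1, t2), game_start_node = "A"))
}

# hand-scripted event logs -----------------------------------------------------

script_log <- function(steps, player = "P001") {
  # steps: list of c(kind, node_or_NA, task_or_NA, objective_or_NA)
  df <- do.call(rbind, lapply(steps, function(s) {
    data.frame(kind = s[[1L]],
               node = if (length(s) > 1L) s[[2L]] else NA_character_,
               task = if (length(s) > 2L) s[[3L]] else NA_character_,
               objective = if (length(s) > 3L) s[[4L]] else NA_character_,
               stringsAsFactors = FALSE)
  }))
  n <- nrow(df)
  df$ts <- sprintf("2020-01-01T00:%02d:%02dZ", (seq_len(n) - 1L) %/% 60L,
                   (seq_len(n) - 1L) %% 60L)
  df$seq <- seq_len(n) - 1L
  df$player <- player
  event_log(df)
}

# a perfect playthrough of manor_world(): every walk is a shortest path and
# the task windows follow the minimum routes exactly
perfect_manor_log <- function() {
  script_log(list(
    list("task_start", NA, "T1"),
    list("move", "B"),
    list("move", "X1"),
    list("pickup", "X1"),
    list("objective_complete", "X1", NA, "T1_o1"),
    list("move", "B"),
    list("move", "E"),
    list("move", "X3"),
    list("pickup", "X3"),
    list("objective_complete", "X3", NA, "T1_o2"),
    list("task_complete", NA, "T1"),
    list("task_start", NA, "T2"),
    list("move", "E"),
    list("move", "D"),
    list("move", "X2"),
    list("pickup", "X2"),
    list("objective_complete", "X2", NA, "T2_o1"),
    list("task_complete", NA, "T2")))
}

# random graphs and enumeration oracles ----------------------------------------

# connected random graph on n nodes: random spanning tree + extra edges
random_connected_graph <- function(n, p_extra = 0.3) {
  ids <- sprintf("n%02d", seq_len(n))
  edges <- lapply(seq_len(n - 1L) + 1L, function(i) {
    c(ids[sample.int(i - 1L, 1L)], ids[i])
  })
  if (n > 2L) {
    pairs <- utils::combn(n, 2L)
    for (j in seq_len(ncol(pairs))) {
      if (runif(1L) < p_extra) {
        edges[[length(edges) + 1L]] <- ids[pairs[, j]]
      }
    }
  }
  spatial_graph(ids, edges)
}

# oracle: minimum simple-path length from a to b by exhaustive DFS
enumerate_min_path <- function(graph, a, b) {
  adj <- graph$adj
  best <- Inf
  recurse <- function(u, depth, visited) {
    if (depth >= best) return()
    for (v in adj[[u]]) {
      if (v == b) {
        best <<- min(best, depth + 1L)
      } else if (!v %in% visited) {
        recurse(v, depth + 1L, c(visited, v))
      }
    }
  }
  if (a == b) return(0L)
  recurse(a, 0L, a)
  best
}

# oracle: minimum multi-target route cost by explicit permutation recursion
# over igraph shortest-path distances
brute_force_route <- function(graph, start, targets) {
  ig <- igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                      vertices = graph$nodes$id)
  D <- igraph::distances(ig)
  targets <- setdiff(unique(targets), start)
  if (!length(targets)) return(0)
  best <- Inf
  recurse <- function(cur, left, cost) {
    if (!length(left)) {
      best <<- min(best, cost)
      return()
    }
    for (i in seq_along(left)) {
      recurse(left[i], left[-i], cost + D[cur, left[i]])
    }
  }
  recurse(start, targets, 0)
  best
}
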