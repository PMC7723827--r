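# World model: the spatial node graph players navigate and the task/objective
# structure laid over it. Movement is only allowed along links, so navigation
# is graph traversal and minimum routes come from breadth-first search.

NODE_KINDS <- c("location", "interactable", "object")

#' Construct a spatial node graph
#'
#' A spatial graph is the link-node model of a node-based movement system:
#' nodes are the discrete positions a player can occupy (overall locations,
#' interactable fixtures, and pickupable objects) and edges are the allowed
#' moves between them. Edges are undirected: if a player can move from A to
#' B they can move back.
#'
#' @param nodes Data frame with columns `id` (unique, nonempty strings),
#'   `kind` (one of `"location"`, `"interactable"`, `"object"`) and
#'   optionally `label`. A bare character vector is promoted to all-location
#'   nodes.
#' @param edges Two-column data frame or matrix of node-id pairs, or a list
#'   of length-2 character vectors. Self-loops are rejected; duplicate and
#'   reversed pairs are collapsed.
#' @param game_start_node Optional id of the node where every playthrough
#'   begins.
#' @return An object of class `spatial_graph` with elements `nodes`,
#'   `edges`, `adj` (named list of lexicographically sorted neighbor ids)
#'   and `game_start_node`.
#' @examples
#' g <- spatial_graph(c("A", "B", "C"), list(c("A", "B"), c("B", "C")))
#' shortest_hops(g, "A", "C")
#' @export
spatial_graph <- function(nodes, edges, game_start_node = NULL) {
  if (is.character(nodes)) {
    nodes <- data.frame(id = nodes, kind = "location", label = nodes,
                        stringsAsFactors = FALSE)
  }
  if (!is.data.frame(nodes) || !all(c("id", "kind") %in% names(nodes))) {
    stop("`nodes` must be a data frame with columns `id` and `kind`")
  }
  nodes$id <- as.character(nodes$id)
  nodes$kind <- as.character(nodes$kind)
  if (is.null(nodes$label)) nodes$label <- nodes$id
  if (anyNA(nodes$id) || any(!nzchar(nodes$id))) {
    stop("node ids must be nonempty strings")
  }
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node id: ", nodes$id[duplicated(nodes$id)][1L])
  }
  bad_kind <- setdiff(unique(nodes$kind), NODE_KINDS)
  if (length(bad_kind)) {
    stop("unknown node kind: ", bad_kind[1L],
         " (expected one of ", paste(NODE_KINDS, collapse = ", "), ")")
  }

  edges <- as_edge_frame(edges)
  unknown <- setdiff(unique(c(edges$from, edges$to)), nodes$id)
  if (length(unknown)) {
    stop("edge references unknown node id: ", unknown[1L])
  }
  if (any(edges$from == edges$to)) {
    stop("self-loop edges are not allowed (node ",
         edges$from[edges$from == edges$to][1L], ")")
  }
  # canonical undirected form: from < to, deduplicated
  lo <- pmin(edges$from, edges$to)
  hi <- pmax(edges$from, edges$to)
  key <- paste(lo, hi, sep = "\r")
  keep <- !duplicated(key)
  edges <- data.frame(from = lo[keep], to = hi[keep], stringsAsFactors = FALSE)

  ids <- nodes$id
  adj <- lapply(stats::setNames(ids, ids), function(i) character(0))
  for (k in seq_len(nrow(edges))) {
    adj[[edges$from[k]]] <- c(adj[[edges$from[k]]], edges$to[k])
    adj[[edges$to[k]]] <- c(adj[[edges$to[k]]], edges$from[k])
  }
  adj <- lapply(adj, function(x) sort(unique(x)))

  if (!is.null(game_start_node)) {
    if (!game_start_node %in% ids) {
      stop("game_start_node `", game_start_node, "` is not a node in the graph")
    }
  }

  g <- list(nodes = nodes[, c("id", "kind", "label")], edges = edges,
            adj = adj, game_start_node = game_start_node)
  # integer adjacency in id order, neighbors pre-sorted lexicographically,
  # used by the BFS routines
  g$adj_idx <- lapply(g$adj, function(nb) match(nb, ids))
  class(g) <- "spatial_graph"
  g
}

as_edge_frame <- function(edges) {
  if (is.list(edges) && !is.data.frame(edges)) {
    if (!length(edges)) {
      return(data.frame(from = character(0), to = character(0),
                        stringsAsFactors = FALSE))
    }
    stopifnot(all(lengths(edges) == 2L))
    m <- do.call(rbind, lapply(edges, as.character))
    edges <- data.frame(from = m[, 1L], to = m[, 2L], stringsAsFactors = FALSE)
  }
  if (is.matrix(edges)) {
    edges <- data.frame(from = as.character(edges[, 1L]),
                        to = as.character(edges[, 2L]),
                        stringsAsFactors = FALSE)
  }
  if (!is.data.frame(edges) || ncol(edges) < 2L) {
    stop("`edges` must be a two-column data frame, matrix, or list of pairs")
  }
  names(edges)[1:2] <- c("from", "to")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges[, c("from", "to")]
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat("<spatial_graph> ", nrow(x$nodes), " nodes (",
      sum(x$nodes$kind == "location"), " locations), ",
      nrow(x$edges), " undirected edges", sep = "")
  if (!is.null(x$game_start_node)) cat(", start at", x$game_start_node)
  cat("\n")
  invisible(x)
}

check_node_id <- function(graph, id, what = "node") {
  if (length(id) != 1L || is.na(id) || !id %in% graph$nodes$id) {
    stop("unknown ", what, " id: ", id)
  }
  invisible(id)
}

# BFS distances (in hops) from node index `s` to every node; NA if
# unreachable. Neighbors are expanded in lexicographic id order so path
# reconstruction is deterministic.
bfs_dist_from <- function(graph, s) {
  n <- nrow(graph$nodes)
  dist <- rep(NA_integer_, n)
  dist[s] <- 0L
  queue <- integer(n)
  queue[1L] <- s
  qhead <- 1L
  qtail <- 1L
  adj <- graph$adj_idx
  while (qhead <= qtail) {
    u <- queue[qhead]
    qhead <- qhead + 1L
    for (v in adj[[u]]) {
      if (is.na(dist[v])) {
        dist[v] <- dist[u] + 1L
        qtail <- qtail + 1L
        queue[qtail] <- v
      }
    }
  }
  dist
}

#' Minimum number of hops between two nodes
#'
#' Breadth-first search distance on the spatial graph: the number of edges
#' on a shortest path from `a` to `b` (0 when `a == b`). This is the `R`
#' value of a single objective-to-objective segment.
#'
#' @param graph A [spatial_graph].
#' @param a,b Node ids.
#' @return Nonnegative integer hop count.
#' @export
shortest_hops <- function(graph, a, b) {
  check_node_id(graph, a)
  check_node_id(graph, b)
  if (a == b) return(0L)
  ids <- graph$nodes$id
  d <- bfs_dist_from(graph, match(a, ids))[match(b, ids)]
  if (is.na(d)) {
    stop("nodes `", a, "` and `", b, "` are unreachable from each other")
  }
  d
}

# All-pairs hop distances and deterministic next-hop table.
# next_hop[u, t] is the neighbor of u to enter when heading for t
# (ties broken by lexicographic node id).
build_router <- function(graph) {
  ids <- graph$nodes$id
  n <- length(ids)
  D <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
  for (s in seq_len(n)) D[s, ] <- bfs_dist_from(graph, s)
  NH <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
  for (u in seq_len(n)) {
    nb <- graph$adj_idx[[u]]
    if (!length(nb)) next
    dn <- D[nb, , drop = FALSE]
    # first index on ties; neighbors are already in lexicographic order
    pick <- max.col(-t(dn), ties.method = "first")
    NH[u, ] <- nb[pick]
    NH[u, u] <- NA_integer_
  }
  list(ids = ids, D = D, next_hop = NH, cache = new.env(parent = emptyenv()))
}

# Task minimum route, memoized on the router when one is supplied (the
# route depends only on the world, not the player).
task_route <- function(graph, tdef, router) {
  if (is.null(router)) {
    return(min_task_route(graph, tdef$start_node, tdef$objectives$target_node,
                          manual_override = tdef$manual_R))
  }
  key <- tdef$id
  hit <- router$cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- min_task_route(graph, tdef$start_node, tdef$objectives$target_node,
                        manual_override = tdef$manual_R, router = router)
  assign(key, val, envir = router$cache)
  val
}

route_dist <- function(router, a, b) {
  d <- router$D[a, b]
  if (is.na(d)) stop("nodes `", a, "` and `", b,
                     "` are unreachable from each other")
  d
}

all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- vector("list", 0L)
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

#' Minimum route length through a set of target nodes
#'
#' The `R` value of a whole task: the smallest total hop count of any route
#' that starts at `start` and visits every target node in some order. Exact
#' search over all visiting orders is used for up to 8 targets; beyond that
#' a nearest-neighbor heuristic is used with a warning. A `manual_override`
#' (the convention of specifying `R` from a perfect playthrough by hand)
#' takes precedence when given.
#'
#' @param graph A [spatial_graph].
#' @param start Starting node id.
#' @param targets Character vector of target node ids (nonempty).
#' @param manual_override Optional positive integer replacing the computed
#'   value. A warning is issued if it is smaller than the computed minimum.
#' @param router Optional precomputed routing table (internal use).
#' @return Nonnegative integer hop count.
#' @export
min_task_route <- function(graph, start, targets, manual_override = NULL,
                           router = NULL) {
  check_node_id(graph, start, "start")
  if (!length(targets)) stop("`targets` must be nonempty")
  for (t in targets) check_node_id(graph, t, "target")
  targets <- setdiff(unique(targets), start)

  computed <- if (!length(targets)) {
    0L
  } else {
    if (is.null(router)) router <- build_router(graph)
    pts <- c(start, targets)
    for (t in targets) route_dist(router, start, t)  # unreachable -> error
    k <- length(targets)
    if (k <= 8L) {
      best <- Inf
      for (p in all_perms(targets)) {
        cost <- router$D[start, p[1L]]
        if (k > 1L) {
          for (j in 2:k) cost <- cost + router$D[p[j - 1L], p[j]]
        }
        if (cost < best) best <- cost
      }
      as.integer(best)
    } else {
      warning("more than 8 targets: using nearest-neighbor heuristic for R")
      cur <- start
      left <- targets
      total <- 0L
      while (length(left)) {
        d <- router$D[cur, left]
        i <- which.min(d)  # first index on ties; `left` keeps input order
        total <- total + d[i]
        cur <- left[i]
        left <- left[-i]
      }
      as.integer(total)
    }
  }

  if (!is.null(manual_override)) {
    manual_override <- as.integer(manual_override)
    if (is.na(manual_override) || manual_override < 0L) {
      stop("`manual_override` must be a nonnegative integer")
    }
    if (manual_override < computed) {
      warning("manual R (", manual_override,
              ") is below the computed minimum route (", computed, ")")
    }
    return(manual_override)
  }
  computed
}

# ---- tasks and objectives ---------------------------------------------------

#' Define a task with its objectives
#'
#' A task is a gathering activity: a set of fact-finding objectives, each
#' bound to one target node, that must all be achieved to complete the
#' task. `start_node` is where a player stands when the task opens; it is
#' the origin of the task's minimum route.
#'
#' @param id Unique task id.
#' @param start_node Node id the task starts from.
#' @param objectives Data frame with columns `id`, `target_node` and
#'   optionally `label`; row order is presentation order.
#' @param manual_R Optional positive integer overriding the computed
#'   minimum route for this task.
#' @return A list of class `lost_task`.
#' @export
task <- function(id, start_node, objectives, manual_R = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.data.frame(objectives) ||
      !all(c("id", "target_node") %in% names(objectives)) ||
      !nrow(objectives)) {
    stop("`objectives` must be a nonempty data frame with columns `id` and `target_node`")
  }
  objectives$id <- as.character(objectives$id)
  objectives$target_node <- as.character(objectives$target_node)
  if (is.null(objectives$label)) objectives$label <- objectives$id
  if (anyDuplicated(objectives$id)) {
    stop("duplicate objective id within task `", id, "`")
  }
  structure(list(id = id, start_node = as.character(start_node),
                 objectives = objectives[, c("id", "target_node", "label")],
                 manual_R = manual_R),
            class = "lost_task")
}

#' Bundle tasks into a task set
#'
#' @param tasks List of [task()] objects, in presentation order.
#' @param game_start_node Node id where every playthrough begins; the origin
#'   of the first objective segment.
#' @return A list of class `task_set` with elements `tasks` and
#'   `game_start_node`.
#' @export
task_set <- function(tasks, game_start_node) {
  if (inherits(tasks, "lost_task")) tasks <- list(tasks)
  stopifnot(length(tasks) >= 1L, all(vapply(tasks, inherits, TRUE, "lost_task")))
  tids <- vapply(tasks, `[[`, "", "id")
  if (anyDuplicated(tids)) stop("duplicate task id: ", tids[duplicated(tids)][1L])
  oids <- unlist(lapply(tasks, function(t) t$objectives$id))
  if (anyDuplicated(oids)) {
    stop("objective ids must be unique across the task set (duplicate: ",
         oids[duplicated(oids)][1L], ")")
  }
  structure(list(tasks = stats::setNames(tasks, tids),
                 game_start_node = as.character(game_start_node)),
            class = "task_set")
}

#' @export
print.task_set <- function(x, ...) {
  cat("<task_set> ", length(x$tasks), " tasks, ",
      nrow(all_objectives(x)), " objectives, game start at ",
      x$game_start_node, "\n", sep = "")
  invisible(x)
}

#' Flat table of every objective in a task set
#'
#' @param tasks A [task_set].
#' @return Data frame with columns `objective`, `task`, `target_node`,
#'   `label` in presentation order.
#' @export
all_objectives <- function(tasks) {
  out <- do.call(rbind, lapply(tasks$tasks, function(t) {
    data.frame(objective = t$objectives$id, task = t$id,
               target_node = t$objectives$target_node,
               label = t$objectives$label, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Cross-check every node reference in a task set against the graph.
check_world <- function(graph, tasks) {
  stopifnot(inherits(graph, "spatial_graph"), inherits(tasks, "task_set"))
  check_node_id(graph, tasks$game_start_node, "game_start_node")
  for (t in tasks$tasks) {
    check_node_id(graph, t$start_node, paste0("start (task ", t$id, ")"))
    for (tn in t$objectives$target_node) {
      check_node_id(graph, tn, paste0("objective target (task ", t$id, ")"))
    }
  }
  invisible(TRUE)
}

# ---- JSON file formats ------------------------------------------------------

#' Read and write spatial graph files
#'
#' The graph file is JSON:
#' `{"nodes": [{"id", "kind", "label"}], "edges": [["idA","idB"], ...],
#' "game_start_node": "id"}`. Structural problems (missing fields, unknown
#' ids, self-loops) raise errors naming the offending element.
#'
#' @param path File path.
#' @return [read_graph_json()] returns a [spatial_graph].
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                            simplifyMatrix = TRUE)
  if (is.null(obj$nodes)) stop("graph file is missing `nodes`: ", path)
  edges <- obj$edges %||% list()
  spatial_graph(obj$nodes, edges, game_start_node = obj$game_start_node)
}

#' @param graph A [spatial_graph].
#' @rdname read_graph_json
#' @export
write_graph_json <- function(graph, path) {
  stopifnot(inherits(graph, "spatial_graph"))
  obj <- list(nodes = graph$nodes,
              edges = unname(as.matrix(graph$edges)),
              game_start_node = graph$game_start_node)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' Read and write task definition files
#'
#' The task file is JSON:
#' `{"tasks": [{"id", "start_node", "objectives": [{"id", "target_node",
#' "label"}], "manual_R": optional}], "game_start_node": "id"}`. The game
#' start node may instead be supplied from the graph file.
#'
#' @param path File path.
#' @param game_start_node Optional start node id, used when the file does
#'   not carry one.
#' @return [read_task_json()] returns a [task_set].
#' @export
read_task_json <- function(path, game_start_node = NULL) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(obj$tasks) || !length(obj$tasks)) {
    stop("task file is missing `tasks`: ", path)
  }
  start <- obj$game_start_node %||% game_start_node
  if (is.null(start)) {
    stop("no `game_start_node` in task file and none supplied")
  }
  tasks <- lapply(obj$tasks, function(t) {
    if (is.null(t$id) || is.null(t$start_node) || is.null(t$objectives)) {
      stop("task entry missing `id`, `start_node` or `objectives` in ", path)
    }
    objs <- do.call(rbind, lapply(t$objectives, function(o) {
      data.frame(id = o$id, target_node = o$target_node,
                 label = o$label %||% o$id, stringsAsFactors = FALSE)
    }))
    task(t$id, t$start_node, objs, manual_R = t$manual_R)
  })
  task_set(tasks, game_start_node = start)
}

#' @param tasks A [task_set].
#' @rdname read_task_json
#' @export
write_task_json <- function(tasks, path) {
  stopifnot(inherits(tasks, "task_set"))
  obj <- list(
    game_start_node = tasks$game_start_node,
    tasks = lapply(unname(tasks$tasks), function(t) {
      out <- list(id = t$id, start_node = t$start_node,
                  objectives = lapply(seq_len(nrow(t$objectives)), function(i) {
                    as.list(t$objectives[i, c("id", "target_node", "label")])
                  }))
      if (!is.null(t$manual_R)) out$manual_R <- t$manual_R
      out
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}
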