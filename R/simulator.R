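# Synthetic worlds and playthroughs. The agent is an epsilon-greedy walker:
# at every step it takes the deterministic BFS next hop toward the current
# objective's target with probability 1 - wander_prob, and a uniformly
# random neighbor otherwise. wander_prob = 0 is a perfect player; 1 is a
# pure random walk. This single knob gives a controllable ground-truth
# axis from full orientation to full disorientation.

#' Generate a synthetic world
#'
#' Builds a connected spatial graph shaped like a small explorable house: a
#' location backbone (random spanning tree plus a few shortcut edges) with
#' pickupable object nodes and interactable fixtures attached as leaves,
#' and a task set whose objective targets are the object nodes. Tasks are
#' chained: each task starts where the previous one ends, and objectives
#' are presented in the optimal visiting order from the task's start (the
#' order a well-designed game would suggest).
#'
#' @param n_locations Number of backbone location nodes (at least 2).
#' @param n_tasks Number of tasks.
#' @param objectives_per_task Objectives per task.
#' @param seed Optional integer seed; the same seed reproduces the world
#'   exactly.
#' @param p_extra_edge Probability of adding each non-tree location pair as
#'   a shortcut edge (default 0.15).
#' @return List with elements `graph` (a [spatial_graph]) and `tasks` (a
#'   [task_set]).
#' @export
generate_world <- function(n_locations, n_tasks, objectives_per_task,
                           seed = NULL, p_extra_edge = 0.15) {
  if (n_locations < 2L) stop("configuration error: need at least 2 locations")
  if (n_tasks < 1L || objectives_per_task < 1L) {
    stop("configuration error: need at least 1 task and 1 objective per task")
  }
  with_seed(seed, {
    loc <- sprintf("L%02d", seq_len(n_locations))
    # random spanning tree keeps the backbone connected
    edges <- lapply(2:n_locations, function(i) {
      c(loc[sample.int(i - 1L, 1L)], loc[i])
    })
    if (n_locations > 2L && p_extra_edge > 0) {
      pairs <- utils::combn(n_locations, 2L)
      tree <- vapply(edges, paste, "", collapse = "\r")
      for (j in seq_len(ncol(pairs))) {
        a <- loc[pairs[1L, j]]
        b <- loc[pairs[2L, j]]
        if (paste(a, b, sep = "\r") %in% tree) next
        if (runif(1L) < p_extra_edge) edges[[length(edges) + 1L]] <- c(a, b)
      }
    }

    n_obj <- n_tasks * objectives_per_task
    obj_ids <- sprintf("B%02d", seq_len(n_obj))
    obj_loc <- loc[sample.int(n_locations, n_obj, replace = n_obj > n_locations)]
    for (k in seq_len(n_obj)) edges[[length(edges) + 1L]] <- c(obj_loc[k], obj_ids[k])

    int_ids <- sprintf("I%02d", seq_len(n_tasks))
    int_loc <- loc[sample.int(n_locations, n_tasks, replace = n_tasks > n_locations)]
    for (k in seq_len(n_tasks)) edges[[length(edges) + 1L]] <- c(int_loc[k], int_ids[k])

    nodes <- data.frame(
      id = c(loc, int_ids, obj_ids),
      kind = c(rep("location", n_locations),
               rep("interactable", n_tasks),
               rep("object", n_obj)),
      label = c(paste("room", seq_len(n_locations)),
                paste("door", seq_len(n_tasks)),
                paste("item", seq_len(n_obj))),
      stringsAsFactors = FALSE)
    graph <- spatial_graph(nodes, edges, game_start_node = loc[1L])
    router <- build_router(graph)

    tasks <- vector("list", n_tasks)
    start <- loc[1L]
    for (t in seq_len(n_tasks)) {
      targ <- obj_ids[((t - 1L) * objectives_per_task + 1L):(t * objectives_per_task)]
      ord <- best_route_order(router, start, targ)
      objs <- data.frame(id = sprintf("T%d_o%d", t, seq_along(ord)),
                         target_node = ord,
                         label = paste("find", ord), stringsAsFactors = FALSE)
      tasks[[t]] <- task(sprintf("T%d", t), start, objs)
      start <- ord[length(ord)]
    }
    list(graph = graph, tasks = task_set(tasks, game_start_node = loc[1L]))
  })
}

# Visiting order of `targets` from `start` minimizing total hops (exact for
# up to 8 targets, nearest-neighbor beyond).
best_route_order <- function(router, start, targets) {
  targets <- unique(targets)
  k <- length(targets)
  if (k <= 1L) return(targets)
  if (k <= 8L) {
    best <- Inf
    best_p <- targets
    for (p in all_perms(targets)) {
      cost <- router$D[start, p[1L]]
      for (j in 2:k) cost <- cost + router$D[p[j - 1L], p[j]]
      if (cost < best) {
        best <- cost
        best_p <- p
      }
    }
    best_p
  } else {
    cur <- start
    left <- targets
    out <- character(0)
    while (length(left)) {
      i <- which.min(router$D[cur, left])
      cur <- left[i]
      out <- c(out, cur)
      left <- left[-i]
    }
    out
  }
}

#' Simulate one playthrough
#'
#' An epsilon-greedy agent works through the tasks in presentation order,
#' and within each task through its objectives in presentation order. At
#' each step it moves to the deterministic BFS next hop toward the current
#' target with probability `1 - wander_prob`, otherwise to a uniformly
#' random neighbor. Reaching an item target emits a `pickup`, then the
#' `objective_complete`; finishing a task's objectives emits
#' `task_complete`. The walk halts at `max_steps` moves and the log is then
#' flagged incomplete.
#'
#' @param graph A [spatial_graph].
#' @param tasks A [task_set].
#' @param wander_prob Probability of a random step (0 = perfect player).
#' @param max_steps Move budget before the session is cut off.
#' @param player Player id written into the events.
#' @param seed Optional integer seed.
#' @param router Optional precomputed routing table (internal use).
#' @return An [event_log]; attribute `incomplete` is `TRUE` when the agent
#'   ran out of steps.
#' @export
simulate_playthrough <- function(graph, tasks, wander_prob = 0.2,
                                 max_steps = 4000L, player = "P001",
                                 seed = NULL, router = NULL) {
  stopifnot(wander_prob >= 0, wander_prob <= 1, max_steps >= 1L)
  check_world(graph, tasks)
  if (is.null(router)) router <- build_router(graph)
  with_seed(seed, {
    ids <- graph$nodes$id
    kind_of <- graph$nodes$kind
    adj <- graph$adj_idx
    NH <- router$next_hop
    objs <- all_objectives(tasks)
    n_cap <- max_steps + 2L * nrow(objs) + 2L * length(tasks$tasks) + 4L
    ev_kind <- character(n_cap)
    ev_node <- integer(n_cap)
    ev_task <- rep(NA_character_, n_cap)
    ev_obj <- rep(NA_character_, n_cap)
    n_ev <- 0L
    steps <- 0L
    pos <- match(tasks$game_start_node, ids)
    incomplete <- FALSE

    for (t in tasks$tasks) {
      n_ev <- n_ev + 1L
      ev_kind[n_ev] <- "task_start"
      ev_node[n_ev] <- pos
      ev_task[n_ev] <- t$id
      for (j in seq_len(nrow(t$objectives))) {
        target <- match(t$objectives$target_node[j], ids)
        while (pos != target) {
          if (steps >= max_steps) {
            incomplete <- TRUE
            break
          }
          steps <- steps + 1L
          if (wander_prob > 0 && runif(1L) < wander_prob) {
            nb <- adj[[pos]]
            pos <- nb[sample.int(length(nb), 1L)]
          } else {
            pos <- NH[pos, target]
          }
          n_ev <- n_ev + 1L
          ev_kind[n_ev] <- "move"
          ev_node[n_ev] <- pos
        }
        if (incomplete) break
        if (kind_of[pos] %in% c("object", "interactable")) {
          n_ev <- n_ev + 1L
          ev_kind[n_ev] <- "pickup"
          ev_node[n_ev] <- pos
        }
        n_ev <- n_ev + 1L
        ev_kind[n_ev] <- "objective_complete"
        ev_node[n_ev] <- pos
        ev_obj[n_ev] <- t$objectives$id[j]
      }
      if (incomplete) break
      n_ev <- n_ev + 1L
      ev_kind[n_ev] <- "task_complete"
      ev_node[n_ev] <- pos
      ev_task[n_ev] <- t$id
    }

    i <- seq_len(n_ev)
    log <- event_log(data.frame(
      ts = iso_ts(n_ev), seq = i - 1L, player = player,
      kind = ev_kind[i], node = ids[ev_node[i]],
      task = ev_task[i], objective = ev_obj[i],
      stringsAsFactors = FALSE))
    attr(log, "incomplete") <- incomplete
    attr(log, "wander_prob") <- wander_prob
    log
  })
}

# One-second-spaced ISO-8601 timestamps from a fixed session start.
iso_ts <- function(n) {
  i <- seq_len(n) - 1L
  day <- i %/% 86400L
  r <- i %% 86400L
  date <- if (any(day > 0L)) {
    as.character(as.Date("2020-01-01") + day)
  } else "2020-01-01"
  sprintf("%sT%02d:%02d:%02dZ", date, r %/% 3600L, (r %% 3600L) %/% 60L,
          r %% 60L)
}
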