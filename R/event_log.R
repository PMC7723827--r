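# Event logs: ordered, timestamped interaction records (moves, pickups,
# task/objective markers) from which the player's path is reconstructed.
# Segmentation turns a log into the (R, S, N) path counts that feed the
# lostness formula: task windows for the global measure, objective-to-
# objective segments for the local one.

EVENT_KINDS <- c("move", "pickup", "inspect",
                 "task_start", "objective_complete", "task_complete")
EVENT_COLS <- c("ts", "seq", "player", "kind", "node", "task", "objective")

#' Construct an event log
#'
#' An event log is an ordered record of one player's interactions. Each
#' event has an ISO-8601 timestamp `ts`, a capture-time ordinal `seq` used
#' to break timestamp ties, the `player` id, the event `kind`, and the
#' `node` / `task` / `objective` ids the kind requires: movement events
#' (`move`, `pickup`, `inspect`) carry a node, `task_start` and
#' `task_complete` carry a task, and `objective_complete` carries both the
#' objective and the node at which it was achieved.
#'
#' @param events Data frame with columns `ts`, `seq`, `player`, `kind`,
#'   `node`, `task`, `objective` (missing reference columns are filled with
#'   `NA`).
#' @return The validated data frame with class `event_log`.
#' @export
event_log <- function(events) {
  stopifnot(is.data.frame(events))
  for (col in EVENT_COLS) {
    if (!col %in% names(events)) {
      if (col %in% c("node", "task", "objective")) {
        events[[col]] <- NA_character_
      } else {
        stop("event log is missing required column `", col, "`")
      }
    }
  }
  extra <- setdiff(names(events), EVENT_COLS)
  events <- events[, c(EVENT_COLS, extra)]
  events$ts <- as.character(events$ts)
  events$seq <- as.integer(events$seq)
  events$player <- as.character(events$player)
  events$kind <- as.character(events$kind)
  for (col in c("node", "task", "objective")) {
    events[[col]] <- as.character(events[[col]])
  }
  check_events(events)
  class(events) <- c("event_log", "data.frame")
  events
}

check_events <- function(events, where = NULL) {
  at <- function(i) {
    if (is.null(where)) paste0("event ", i) else paste0("line ", where[i])
  }
  bad <- which(is.na(events$ts) | !nzchar(events$ts))
  if (length(bad)) stop("missing timestamp at ", at(bad[1L]))
  bad <- which(!grepl("^\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}:\\d{2}", events$ts))
  if (length(bad)) {
    stop("malformed ISO-8601 timestamp `", events$ts[bad[1L]], "` at ", at(bad[1L]))
  }
  bad <- which(is.na(events$seq) | events$seq < 0L)
  if (length(bad)) stop("missing or negative `seq` at ", at(bad[1L]))
  bad <- which(is.na(events$player) | !nzchar(events$player))
  if (length(bad)) stop("missing `player` at ", at(bad[1L]))
  bad <- which(!events$kind %in% EVENT_KINDS)
  if (length(bad)) {
    stop("unknown event kind `", events$kind[bad[1L]], "` at ", at(bad[1L]))
  }
  needs_node <- events$kind %in% c("move", "pickup", "inspect",
                                   "objective_complete")
  bad <- which(needs_node & is.na(events$node))
  if (length(bad)) {
    stop("`", events$kind[bad[1L]], "` event without a node id at ", at(bad[1L]))
  }
  needs_task <- events$kind %in% c("task_start", "task_complete")
  bad <- which(needs_task & is.na(events$task))
  if (length(bad)) {
    stop("`", events$kind[bad[1L]], "` event without a task id at ", at(bad[1L]))
  }
  bad <- which(events$kind == "objective_complete" & is.na(events$objective))
  if (length(bad)) stop("`objective_complete` without an objective id at ", at(bad[1L]))

  # strict (ts, seq) ordering within each player
  for (p in unique(events$player)) {
    i <- which(events$player == p)
    if (length(i) < 2L) next
    ts <- events$ts[i]
    sq <- events$seq[i]
    ok <- ts[-1L] > ts[-length(i)] |
      (ts[-1L] == ts[-length(i)] & sq[-1L] > sq[-length(i)])
    if (!all(ok)) {
      j <- i[which(!ok)[1L] + 1L]
      stop("events out of (ts, seq) order for player ", p, " at ", at(j))
    }
  }
  invisible(TRUE)
}

#' Read an event log file
#'
#' Accepts JSON-lines (one event object per line) or CSV with the same
#' column names (`ts`, `seq`, `player`, `kind`, `node`, `task`,
#' `objective`). Events must already be in strictly increasing `(ts, seq)`
#' order per player; violations are reported as parse errors with the
#' offending line. Unknown columns are preserved.
#'
#' @param path File path; format is chosen by extension (`.csv` vs
#'   anything else = JSONL).
#' @return An [event_log].
#' @export
read_event_log <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                   colClasses = "character")
    if (!nrow(df)) return(empty_event_log())
    df$seq <- as.integer(df$seq)
    where <- seq_len(nrow(df)) + 1L  # header line
  } else {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    keep <- which(nzchar(trimws(lines)))
    if (!length(keep)) return(empty_event_log())
    recs <- vector("list", length(keep))
    for (i in seq_along(keep)) {
      recs[[i]] <- tryCatch(
        jsonlite::fromJSON(lines[keep[i]], simplifyVector = TRUE),
        error = function(e) {
          stop("malformed JSON at line ", keep[i], " of ", path, ": ",
               conditionMessage(e), call. = FALSE)
        })
    }
    cols <- unique(unlist(lapply(recs, names)))
    df <- as.data.frame(
      lapply(stats::setNames(cols, cols), function(cl) {
        vapply(recs, function(r) {
          v <- r[[cl]]
          if (is.null(v) || !length(v) || is.na(v)) NA_character_ else as.character(v)
        }, "")
      }), stringsAsFactors = FALSE)
    df$seq <- as.integer(df$seq)
    where <- keep
  }
  key <- paste(df$ts, sprintf("%09d", df$seq), df$player)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate (ts, seq) pair at line ", where[dup[1L]], " of ", path)
  }
  withCallingHandlers(
    check_events(df, where = where),
    error = function(e) stop(conditionMessage(e), " of ", path, call. = FALSE))
  log <- event_log(df)
  attr(log, "source") <- path
  log
}

empty_event_log <- function() {
  event_log(data.frame(ts = character(0), seq = integer(0),
                       player = character(0), kind = character(0),
                       node = character(0), task = character(0),
                       objective = character(0), stringsAsFactors = FALSE))
}

#' Write an event log in canonical form
#'
#' The canonical form is UTF-8 JSON-lines sorted by `(player, ts, seq)`,
#' one event per line, with `null`-valued reference fields omitted.
#' Writing and re-reading a log reproduces it exactly.
#'
#' @param log An [event_log].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "event_log"))
  o <- order(log$player, log$ts, log$seq)
  log <- log[o, , drop = FALSE]
  lines <- vapply(seq_len(nrow(log)), function(i) {
    rec <- as.list(log[i, , drop = FALSE])
    rec <- rec[!vapply(rec, function(v) is.na(v[[1L]]), TRUE)]
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

# ---- path reconstruction ----------------------------------------------------

# Counted node entries of a log: every `move` enters its node; `pickup` and
# `inspect` enter theirs only when it differs from the current position
# (picking up or turning an item in hand is not movement). Returns the event
# indices and entered node ids, in order. Position starts at `start`.
log_entries <- function(log, start) {
  kind <- log$kind
  node <- log$node
  moves <- which(kind == "move")
  others <- which(kind %in% c("pickup", "inspect") & !is.na(node))
  if (!length(others)) {
    return(list(idx = moves, node = node[moves]))
  }
  # rare general case: walk the log once, tracking position
  cand <- sort(c(moves, others))
  pos <- start
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    if (kind[i] == "move") {
      keep[j] <- TRUE
      pos <- node[i]
    } else if (!identical(node[i], pos)) {
      keep[j] <- TRUE
      pos <- node[i]
    }
  }
  list(idx = cand[keep], node = node[cand[keep]])
}

# Index of the last event both measures should see: free exploration after
# the final task is completed is ignored. Only applies when every task in
# the set has been completed.
log_cutoff <- function(log, tasks) {
  done <- log$task[log$kind == "task_complete"]
  if (length(done) && all(names(tasks$tasks) %in% done)) {
    max(which(log$kind == "task_complete"))
  } else {
    nrow(log)
  }
}

#' Check a log against a world model
#'
#' Diagnostic (never-throwing) consistency checks of an event log against
#' the spatial graph and task set: moves between unlinked nodes
#' ("teleports"), references to unknown ids, objectives completed at a node
#' other than their target, and tasks completed before all their
#' objectives. An empty result means the log is fully consistent.
#'
#' @param log An [event_log].
#' @param graph A [spatial_graph].
#' @param tasks A [task_set].
#' @return Data frame with columns `event` (row index), `type`, `message`;
#'   zero rows when the log is consistent.
#' @export
validate_log <- function(log, graph, tasks) {
  stopifnot(inherits(log, "event_log"))
  check_world(graph, tasks)
  diags <- list()
  note <- function(i, type, msg) {
    diags[[length(diags) + 1L]] <<- data.frame(
      event = i, type = type, message = msg, stringsAsFactors = FALSE)
  }
  objs <- all_objectives(tasks)
  known_tasks <- names(tasks$tasks)
  pos <- tasks$game_start_node
  done_obj <- character(0)
  for (i in seq_len(nrow(log))) {
    k <- log$kind[i]
    nd <- log$node[i]
    if (!is.na(nd) && !nd %in% graph$nodes$id) {
      note(i, "unknown_node", paste0("unknown node id `", nd, "`"))
      next
    }
    if (k %in% c("task_start", "task_complete")) {
      tk <- log$task[i]
      if (!tk %in% known_tasks) {
        note(i, "unknown_task", paste0("unknown task id `", tk, "`"))
        next
      }
      if (k == "task_complete") {
        need <- objs$objective[objs$task == tk]
        if (!all(need %in% done_obj)) {
          note(i, "premature_task_complete",
               paste0("task `", tk, "` completed before all its objectives"))
        }
      }
    }
    if (k == "move") {
      if (identical(nd, pos)) {
        note(i, "self_move", paste0("move to current node `", nd, "`"))
      } else if (!nd %in% graph$adj[[pos]]) {
        note(i, "teleport",
             paste0("move from `", pos, "` to unlinked node `", nd, "`"))
      }
      pos <- nd
    } else if (k %in% c("pickup", "inspect")) {
      if (!identical(nd, pos)) pos <- nd
    } else if (k == "objective_complete") {
      ob <- log$objective[i]
      j <- match(ob, objs$objective)
      if (is.na(j)) {
        note(i, "unknown_objective", paste0("unknown objective id `", ob, "`"))
      } else {
        if (!identical(nd, objs$target_node[j])) {
          note(i, "objective_node_mismatch",
               paste0("objective `", ob, "` completed at `", nd,
                      "` but its target is `", objs$target_node[j], "`"))
        }
        done_obj <- c(done_obj, ob)
      }
    }
  }
  if (!length(diags)) {
    return(data.frame(event = integer(0), type = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, diags)
}

#' Segment a log into task windows
#'
#' One segment per completed task: the window runs from the task's
#' `task_start` event to its `task_complete` event. `S` is the number of
#' counted node entries inside the window, `N` the number of distinct nodes
#' among them, and `R` the task's minimum route (or its manual override).
#' Events inside overlapping task windows are counted in every open window
#' — a deliberate property of the task-scoped measure.
#'
#' @param log An [event_log] for a single player.
#' @param graph A [spatial_graph].
#' @param tasks A [task_set].
#' @param router Optional precomputed routing table (internal use).
#' @return Data frame with one row per completed task: `task`, `R`, `S`,
#'   `N`, `x` (number of objectives), `start_event`, `end_event`.
#' @export
segment_tasks <- function(log, graph, tasks, router = NULL) {
  stopifnot(inherits(log, "event_log"))
  check_world(graph, tasks)
  cut <- log_cutoff(log, tasks)
  log <- log[seq_len(cut), , drop = FALSE]
  ent <- log_entries(log, tasks$game_start_node)

  starts <- which(log$kind == "task_start")
  ends <- which(log$kind == "task_complete")
  m <- length(ends)
  task_v <- character(m)
  R_v <- S_v <- N_v <- x_v <- s_v <- integer(m)
  for (k in seq_len(m)) {
    e <- ends[k]
    tk <- log$task[e]
    s <- starts[log$task[starts] == tk & starts < e]
    if (!length(s)) {
      stop("task_complete for `", tk, "` without a matching task_start")
    }
    s <- s[1L]
    tdef <- tasks$tasks[[tk]]
    if (is.null(tdef)) stop("unknown task id in log: ", tk)
    in_win <- ent$idx > s & ent$idx <= e
    task_v[k] <- tk
    S_v[k] <- sum(in_win)
    N_v[k] <- length(unique(ent$node[in_win]))
    R_v[k] <- task_route(graph, tdef, router)
    x_v[k] <- nrow(tdef$objectives)
    s_v[k] <- s
  }
  data.frame(task = task_v, R = R_v, S = S_v, N = N_v, x = x_v,
             start_event = s_v, end_event = as.integer(ends),
             stringsAsFactors = FALSE)
}

#' Segment a log into objective-to-objective segments
#'
#' Segments partition the session at `objective_complete` events, in actual
#' completion order, counting from the start of the game: segment *k* runs
#' from the (*k*-1)-th completion (or the game start) up to and including
#' the *k*-th. `S` and `N` count node entries as in [segment_tasks()], and
#' the counters reset with every completion. `R` is the BFS shortest-hop
#' distance from the previous segment's end node to the node where the
#' objective was completed. Segments with no movement (two objectives
#' achieved at the same node back-to-back) are flagged `degenerate`.
#'
#' @inheritParams segment_tasks
#' @return Data frame with one row per completed objective: `objective`,
#'   `task`, `R`, `S`, `N`, `start_node`, `end_node`, `degenerate`.
#' @export
segment_objectives <- function(log, graph, tasks, router = NULL) {
  stopifnot(inherits(log, "event_log"))
  check_world(graph, tasks)
  cut <- log_cutoff(log, tasks)
  log <- log[seq_len(cut), , drop = FALSE]
  ent <- log_entries(log, tasks$game_start_node)

  comp <- which(log$kind == "objective_complete")
  if (!length(comp)) {
    return(data.frame(objective = character(0), task = character(0),
                      R = integer(0), S = integer(0), N = integer(0),
                      start_node = character(0), end_node = character(0),
                      degenerate = logical(0), stringsAsFactors = FALSE))
  }
  obs <- log$objective[comp]
  if (anyDuplicated(obs)) {
    stop("objective `", obs[duplicated(obs)][1L], "` completed more than once")
  }
  objs <- all_objectives(tasks)
  grp <- findInterval(ent$idx, comp, left.open = TRUE) + 1L
  use_router <- !is.null(router)
  m <- length(comp)
  end_v <- log$node[comp]
  start_v <- c(tasks$game_start_node, end_v[-m])
  R_v <- S_v <- N_v <- integer(m)
  for (k in seq_len(m)) {
    in_seg <- grp == k
    S_v[k] <- sum(in_seg)
    N_v[k] <- length(unique(ent$node[in_seg]))
    R_v[k] <- if (use_router) {
      route_dist(router, start_v[k], end_v[k])
    } else {
      shortest_hops(graph, start_v[k], end_v[k])
    }
  }
  data.frame(objective = obs,
             task = objs$task[match(obs, objs$objective)],
             R = R_v, S = S_v, N = N_v,
             start_node = start_v, end_node = end_v,
             degenerate = S_v == 0L, stringsAsFactors = FALSE)
}
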