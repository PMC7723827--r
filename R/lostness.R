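# The lostness statistic and its two whole-game aggregates.
#
# For one path segment with R = minimum node entries needed, S = total node
# entries made and N = unique node entries made,
#
#   L = (N/S - 1)^2 + (R/N - 1)^2
#
# is 0 for a perfect path and approaches 2 for complete disorientation. The
# first addend measures repetition (revisiting nodes), the second detours
# (visiting nodes off the minimum route).

#' Lostness of a path segment
#'
#' Evaluates the lostness statistic on one or more `(R, S, N)` path-count
#' triples, reporting the repetition and detour components separately.
#' Counts follow the node-entry convention: the segment's starting node is
#' not counted, so a single move to an adjacent node gives `R = S = N = 1`.
#'
#' @param R Minimum node entries needed (positive integer).
#' @param S Total node entries made (positive integer).
#' @param N Unique node entries made (positive integer, `N <= S`).
#' @param strict If `TRUE` (default) a segment with `R > N` is an error, as
#'   such counts cannot arise from a walk that actually reaches its target
#'   going through linked nodes. Task-level counts, whose `R` comes from a
#'   minimum multi-target route that may be forced to re-enter nodes, are
#'   evaluated with `strict = FALSE` and flagged instead.
#' @return Data frame with columns `value`, `repetition`, `detour` and, for
#'   `strict = FALSE`, `forced_revisit` (`R > N`). `value = repetition +
#'   detour` and lies in `[0, 2)` whenever `R <= N <= S`.
#' @examples
#' lostness(5, 5, 5)   # perfect: 0
#' lostness(2, 10, 4)  # (4/10 - 1)^2 + (2/4 - 1)^2 = 0.61
#' @export
lostness <- function(R, S, N, strict = TRUE) {
  n <- max(length(R), length(S), length(N))
  R <- rep_len(as.numeric(R), n)
  S <- rep_len(as.numeric(S), n)
  N <- rep_len(as.numeric(N), n)
  if (anyNA(R) || anyNA(S) || anyNA(N)) stop("path counts must not be NA")
  if (any(S < 1 | N < 1 | R < 1)) {
    stop("degenerate segment (R, S or N below 1): the lostness formula is ",
         "undefined; skip the segment (its zeros still enter summed counts)")
  }
  if (any(N > S)) {
    stop("inconsistent counts: N (unique entries) exceeds S (total entries)")
  }
  if (strict && any(R > N)) {
    stop("inconsistent counts: R (minimum entries) exceeds N (unique entries)")
  }
  repetition <- (N / S - 1)^2
  detour <- (R / N - 1)^2
  out <- data.frame(value = repetition + detour,
                    repetition = repetition, detour = detour)
  if (!strict) out$forced_revisit <- R > N
  out
}

#' Global (task-scoped) lostness
#'
#' The whole-game task measure: a weighted mean of per-task lostness
#' values, with each task weighted by its number of objectives so that
#' complex tasks are not masked by simple ones.
#'
#' @param L Numeric vector of per-task lostness values, each in `[0, 2]`.
#' @param x Positive integer vector of objective counts, one per task.
#' @param task Optional task ids for the report.
#' @return List of class `global_lostness` with elements `per_task` (data
#'   frame `task`, `L`, `x`, `weight`) and `L_G`.
#' @examples
#' global_lostness(c(0.2, 0.5), c(2, 4))$L_G  # 0.4
#' @export
global_lostness <- function(L, x, task = NULL) {
  if (!length(L)) {
    stop("no completed tasks: the global measure is undefined")
  }
  if (length(x) != length(L)) stop("`L` and `x` must have the same length")
  if (any(x < 1)) stop("objective counts `x` must be positive")
  if (any(L < 0 | L > 2)) stop("per-task lostness values must lie in [0, 2]")
  if (is.null(task)) task <- paste0("task", seq_along(L))
  w <- x / sum(x)
  structure(list(
    per_task = data.frame(task = task, L = L, x = x, weight = w,
                          stringsAsFactors = FALSE),
    L_G = sum(L * w)), class = "global_lostness")
}

#' @export
print.global_lostness <- function(x, ...) {
  cat("Global lostness L_G =", format(round(x$L_G, 3), nsmall = 3),
      "over", nrow(x$per_task), "task(s)\n")
  print(x$per_task, row.names = FALSE)
  invisible(x)
}

#' Local (objective-scoped) lostness
#'
#' The whole-game objective measure: the `R`, `S` and `N` counts of every
#' objective-to-objective segment are summed and the lostness formula is
#' applied once to the sums, treating the whole game as one long task.
#' Degenerate segments (no movement) contribute zeros to the sums; their
#' per-objective lostness is reported as `NA` with a flag rather than 0, so
#' "no navigation" cannot be mistaken for "perfect navigation".
#'
#' @param segments Data frame of objective segments with columns `R`, `S`,
#'   `N` and optionally `objective` and `degenerate`, as produced by
#'   [segment_objectives()].
#' @return List of class `local_lostness` with elements `per_objective`,
#'   `summed` (named vector of summed counts) and `L_L`.
#' @examples
#' segs <- data.frame(R = c(1, 2), S = c(4, 6), N = c(2, 3))
#' local_lostness(segs)$L_L  # 0.41
#' @export
local_lostness <- function(segments) {
  stopifnot(is.data.frame(segments), all(c("R", "S", "N") %in% names(segments)))
  if (!nrow(segments)) stop("no completed objectives: the local measure is undefined")
  if (any(segments$N > segments$S)) {
    stop("inconsistent counts: N exceeds S in a segment")
  }
  sums <- c(R = sum(segments$R), S = sum(segments$S), N = sum(segments$N))
  if (sums[["S"]] < 1 || sums[["N"]] < 1 || sums[["R"]] < 1) {
    stop("no navigation recorded: all segments are degenerate")
  }
  ok <- segments$R >= 1 & segments$S >= 1 & segments$N >= 1
  per <- data.frame(
    objective = if (!is.null(segments$objective)) segments$objective
                else paste0("objective", seq_len(nrow(segments))),
    R = segments$R, S = segments$S, N = segments$N,
    value = NA_real_, degenerate = !ok, stringsAsFactors = FALSE)
  if (any(ok)) {
    per$value[ok] <- lostness(segments$R[ok], segments$S[ok], segments$N[ok],
                              strict = FALSE)$value
  }
  L <- lostness(sums[["R"]], sums[["S"]], sums[["N"]], strict = FALSE)
  structure(list(per_objective = per, summed = sums, L_L = L$value,
                 repetition = L$repetition, detour = L$detour),
            class = "local_lostness")
}

#' @export
print.local_lostness <- function(x, ...) {
  cat("Local lostness L_L =", format(round(x$L_L, 3), nsmall = 3),
      "(sum R =", x$summed[["R"]], ", S =", x$summed[["S"]],
      ", N =", x$summed[["N"]], ") over",
      nrow(x$per_objective), "objective(s)\n")
  invisible(x)
}

#' Full lostness report for one player's log
#'
#' Composes validation, segmentation and both lostness measures. Per-task
#' lostness is evaluated tolerantly (`strict = FALSE`): a minimum
#' multi-target route can be forced to re-enter nodes, in which case
#' `R > N` is possible even for efficient play and the task is flagged
#' `forced_revisit`.
#'
#' @param log An [event_log] for a single player.
#' @param graph A [spatial_graph].
#' @param tasks A [task_set].
#' @param validate If `TRUE` (default), attach [validate_log()] diagnostics.
#' @param router Optional precomputed routing table (internal use).
#' @return List of class `player_report` with elements `player`, `global`
#'   (a [global_lostness] or `NULL` if no task was completed), `local` (a
#'   [local_lostness] or `NULL` if no objective was completed),
#'   `task_segments`, `objective_segments`, `diagnostics`, and `complete`
#'   (did the player finish every task?).
#' @export
player_report <- function(log, graph, tasks, validate = TRUE, router = NULL) {
  stopifnot(inherits(log, "event_log"))
  player <- unique(log$player)
  if (length(player) > 1L) {
    stop("log contains more than one player; report them separately")
  }
  diags <- if (validate) validate_log(log, graph, tasks) else NULL

  tseg <- segment_tasks(log, graph, tasks, router = router)
  global <- NULL
  if (nrow(tseg)) {
    lt <- lostness(tseg$R, tseg$S, tseg$N, strict = FALSE)
    global <- global_lostness(lt$value, tseg$x, task = tseg$task)
    global$per_task$repetition <- lt$repetition
    global$per_task$detour <- lt$detour
    global$per_task$forced_revisit <- lt$forced_revisit
  }

  oseg <- segment_objectives(log, graph, tasks, router = router)
  local <- if (nrow(oseg) && sum(oseg$S) >= 1L) local_lostness(oseg) else NULL

  structure(list(
    player = if (length(player)) player else NA_character_,
    global = global, local = local,
    task_segments = tseg, objective_segments = oseg,
    diagnostics = diags,
    complete = nrow(tseg) == length(tasks$tasks)),
    class = "player_report")
}

#' @export
print.player_report <- function(x, ...) {
  cat("Lostness report for player", x$player, "\n")
  cat("  tasks completed:", nrow(x$task_segments), "/",
      if (x$complete) nrow(x$task_segments) else "more", "\n")
  if (!is.null(x$global)) {
    cat("  global lostness L_G =", format(round(x$global$L_G, 3), nsmall = 3), "\n")
  } else cat("  global lostness: undefined (no completed task)\n")
  if (!is.null(x$local)) {
    cat("  local lostness  L_L =", format(round(x$local$L_L, 3), nsmall = 3), "\n")
  } else cat("  local lostness: undefined (no completed objective)\n")
  if (!is.null(x$diagnostics) && nrow(x$diagnostics)) {
    cat("  diagnostics:", nrow(x$diagnostics), "issue(s); first: ",
        x$diagnostics$message[1L], "\n")
  }
  invisible(x)
}
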