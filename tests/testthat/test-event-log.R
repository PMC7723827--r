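test_that("event logs enforce per-kind fields and (ts, seq) order", {
  expect_error(script_log(list(list("move", NA))), "without a node id")
  expect_error(script_log(list(list("task_start", NA))), "without a task id")
  df <- data.frame(ts = c("2020-01-01T00:00:01Z", "2020-01-01T00:00:00Z"),
                   seq = 0:1, player = "P1", kind = "move", node = "A",
                   stringsAsFactors = FALSE)
  expect_error(event_log(df), "out of \\(ts, seq\\) order")
  df$ts <- "not a timestamp"
  expect_error(event_log(df), "malformed ISO-8601")
})

test_that("reading an empty file gives an empty log", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(0), f)
  log <- read_event_log(f)
  expect_s3_class(log, "event_log")
  expect_equal(nrow(log), 0L)
})

test_that("out-of-order and duplicate (ts, seq) raise parse errors with line numbers", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"ts":"2020-01-01T00:00:00Z","seq":0,"player":"P1","kind":"move","node":"A"}',
    '{"ts":"2020-01-01T00:00:02Z","seq":1,"player":"P1","kind":"move","node":"B"}',
    '{"ts":"2020-01-01T00:00:01Z","seq":2,"player":"P1","kind":"move","node":"A"}'), f)
  expect_error(read_event_log(f), "line 3")
  writeLines(c(
    '{"ts":"2020-01-01T00:00:00Z","seq":0,"player":"P1","kind":"move","node":"A"}',
    '{"ts":"2020-01-01T00:00:00Z","seq":0,"player":"P1","kind":"move","node":"B"}'), f)
  expect_error(read_event_log(f), "duplicate \\(ts, seq\\).*line 2")
  writeLines('{"ts":', f)
  expect_error(read_event_log(f), "malformed JSON at line 1")
})

test_that("write/read round-trips the canonical JSONL form byte-identically", {
  w <- manor_world()
  log <- simulate_playthrough(w$graph, w$tasks, wander_prob = 0.5,
                              max_steps = 100L, seed = 11)
  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_event_log(log, f1)
  log2 <- read_event_log(f1)
  write_event_log(log2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(log2$node, log$node)
})

test_that("CSV logs with the same header names are accepted", {
  w <- manor_world()
  log <- perfect_manor_log()
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(log), f, row.names = FALSE, na = "")
  log2 <- read_event_log(f)
  log2[log2 == ""] <- NA  # blank CSV cells
  expect_equal(log2$kind, log$kind)
  expect_equal(nrow(segment_objectives(event_log(as.data.frame(log2)),
                                       w$graph, w$tasks)), 3L)
})

test_that("validate_log is silent on a perfect playthrough", {
  w <- manor_world()
  d <- validate_log(perfect_manor_log(), w$graph, w$tasks)
  expect_equal(nrow(d), 0L)
})

test_that("validate_log flags teleports, wrong-node objectives and unknown ids", {
  w <- manor_world()
  log <- script_log(list(
    list("task_start", NA, "T1"),
    list("move", "C"),                               # A-C not linked
    list("move", "ZZZ"),                             # unknown node
    list("objective_complete", "C", NA, "T1_o1"),    # target is X1
    list("task_complete", NA, "T1"),                 # T1_o2 never completed
    list("task_complete", NA, "T9")))                # unknown task
  d <- validate_log(log, w$graph, w$tasks)
  expect_setequal(d$type[d$event == 2L], "teleport")
  expect_setequal(d$type[d$event == 3L], "unknown_node")
  expect_setequal(d$type[d$event == 4L], "objective_node_mismatch")
  expect_setequal(d$type[d$event == 5L], "premature_task_complete")
  expect_setequal(d$type[d$event == 6L], "unknown_task")
})

test_that("task segmentation counts total and unique entries per window", {
  w <- manor_world()
  seg <- segment_tasks(perfect_manor_log(), w$graph, w$tasks)
  expect_equal(seg$task, c("T1", "T2"))
  # perfect play: S equals the walked minimum route
  expect_equal(seg$S, seg$R)
  expect_equal(seg$x, c(2L, 1L))

  # wandering window: entries B,A,B,A,B,X1 after task_start
  log <- script_log(list(
    list("task_start", NA, "T1"),
    list("move", "B"), list("move", "A"), list("move", "B"),
    list("move", "A"), list("move", "B"), list("move", "X1"),
    list("pickup", "X1"),
    list("objective_complete", "X1", NA, "T1_o1"),
    list("move", "B"), list("move", "E"), list("move", "X3"),
    list("objective_complete", "X3", NA, "T1_o2"),
    list("task_complete", NA, "T1")))
  seg <- segment_tasks(log, w$graph, w$tasks)
  expect_equal(seg$S, 9L)  # 6 + 3 entries
  expect_equal(seg$N, 5L)  # B, A, X1, E, X3
  expect_equal(seg$R, 5L)  # A->X1 (2) + X1->X3 (3)
})

test_that("a log with no completed task yields no task segments", {
  w <- manor_world()
  log <- script_log(list(list("task_start", NA, "T1"), list("move", "B")))
  expect_equal(nrow(segment_tasks(log, w$graph, w$tasks)), 0L)
  bad <- script_log(list(list("task_complete", NA, "T1")))
  expect_error(segment_tasks(bad, w$graph, w$tasks), "without a matching task_start")
})

test_that("overlapping task windows count shared events in every window", {
  w <- manor_world()
  log <- script_log(list(
    list("task_start", NA, "T1"),
    list("task_start", NA, "T2"),
    list("move", "B"), list("move", "X1"),
    list("objective_complete", "X1", NA, "T1_o1"),
    list("move", "B"), list("move", "E"), list("move", "X3"),
    list("objective_complete", "X3", NA, "T1_o2"),
    list("task_complete", NA, "T1"),
    list("move", "E"), list("move", "D"), list("move", "X2"),
    list("objective_complete", "X2", NA, "T2_o1"),
    list("task_complete", NA, "T2")))
  seg <- segment_tasks(log, w$graph, w$tasks)
  # T2's window spans the whole session: T1's 5 entries are counted again
  expect_equal(seg$S[seg$task == "T1"], 5L)
  expect_equal(seg$S[seg$task == "T2"], 8L)
})

test_that("objective segmentation resets counters at each completion", {
  w <- manor_world()
  seg <- segment_objectives(perfect_manor_log(), w$graph, w$tasks)
  expect_equal(seg$objective, c("T1_o1", "T1_o2", "T2_o1"))
  expect_equal(seg$S, seg$R)
  expect_equal(seg$N, seg$R)
  expect_equal(seg$start_node, c("A", "X1", "X3"))
  expect_equal(seg$end_node, c("X1", "X3", "X2"))
})

test_that("back-to-back objectives at one node give a degenerate zero segment", {
  g <- spatial_graph(
    data.frame(id = c("A", "B"), kind = c("location", "object")),
    list(c("A", "B")), game_start_node = "A")
  ts <- task_set(task("T1", "A",
                      data.frame(id = c("o1", "o2"), target_node = "B")), "A")
  log <- script_log(list(
    list("task_start", NA, "T1"),
    list("move", "B"),
    list("objective_complete", "B", NA, "o1"),
    list("objective_complete", "B", NA, "o2"),
    list("task_complete", NA, "T1")))
  seg <- segment_objectives(log, g, ts)
  expect_equal(seg$R, c(1L, 0L))
  expect_equal(seg$S, c(1L, 0L))
  expect_true(seg$degenerate[2L])
})

test_that("a repeated objective completion is a structural error", {
  w <- manor_world()
  log <- script_log(list(
    list("move", "B"), list("move", "X1"),
    list("objective_complete", "X1", NA, "T1_o1"),
    list("objective_complete", "X1", NA, "T1_o1")))
  expect_error(segment_objectives(log, w$graph, w$tasks),
               "completed more than once")
})

test_that("objective segments tile the log and inspect events never count", {
  w <- manor_world()
  log <- script_log(list(
    list("task_start", NA, "T1"),
    list("move", "B"), list("inspect", "B"), list("move", "X1"),
    list("pickup", "X1"), list("inspect", "X1"),
    list("objective_complete", "X1", NA, "T1_o1"),
    list("move", "B"), list("move", "A"), list("move", "B"),
    list("move", "E"), list("move", "X3"),
    list("objective_complete", "X3", NA, "T1_o2")))
  seg <- segment_objectives(log, w$graph, w$tasks)
  expect_equal(sum(seg$S), sum(log$kind == "move"))
  expect_true(all(seg$S >= seg$N))
  expect_true(all(seg$N >= seg$R))
})

test_that("events after the final task completion are ignored", {
  w <- manor_world()
  base <- perfect_manor_log()
  extra <- script_log(list(
    list("move", "D"), list("move", "E"), list("move", "B")))
  extra$ts <- sprintf("2020-01-01T01:%02d:00Z", seq_len(nrow(extra)))
  extra$seq <- max(base$seq) + seq_len(nrow(extra))
  full <- event_log(rbind(as.data.frame(base), as.data.frame(extra)))
  expect_equal(segment_tasks(full, w$graph, w$tasks),
               segment_tasks(base, w$graph, w$tasks))
  expect_equal(segment_objectives(full, w$graph, w$tasks),
               segment_objectives(base, w$graph, w$tasks))
})
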