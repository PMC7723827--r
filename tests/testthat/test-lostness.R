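test_that("the lostness formula reproduces direct arithmetic", {
  expect_equal(lostness(5, 5, 5)$value, 0)
  r <- lostness(2, 10, 4)
  expect_equal(r$value, 0.61)
  expect_equal(r$repetition, 0.36)
  expect_equal(r$detour, 0.25)
  r <- lostness(3, 6, 3)
  expect_equal(r$value, 0.25)
  expect_equal(r$detour, 0)
})

test_that("lostness rejects degenerate and inconsistent counts", {
  expect_error(lostness(1, 0, 0), "degenerate segment")
  expect_error(lostness(0, 3, 2), "degenerate segment")
  expect_error(lostness(2, 3, 4), "N \\(unique entries\\) exceeds S")
  expect_error(lostness(4, 5, 3), "R \\(minimum entries\\) exceeds N")
  tol <- lostness(4, 5, 3, strict = FALSE)
  expect_true(tol$forced_revisit)
  expect_equal(tol$value, (3 / 5 - 1)^2 + (4 / 3 - 1)^2)
})

test_that("lostness is zero iff the path is perfect, and bounded by 2", {
  # exhaustive over a small lattice of valid triples
  for (S in 1:12) for (N in 1:S) for (R in 1:N) {
    L <- lostness(R, S, N)$value
    expect_gte(L, 0)
    expect_lt(L, 2)
    if (R == N && N == S) expect_equal(L, 0) else expect_gt(L, 0)
  }
})

test_that("lostness is monotone in repetition and in detours", {
  # more total entries with the same unique set: strictly more lost
  L_S <- vapply(6:15, function(S) lostness(3, S, 5)$value, 0)
  expect_true(all(diff(L_S) > 0))
  # shorter minimum route with the same behavior: strictly more lost
  L_R <- vapply(5:1, function(R) lostness(R, 10, 5)$value, 0)
  expect_true(all(diff(L_R) > 0))
})

test_that("global lostness is the objectives-weighted mean", {
  g <- global_lostness(c(0.2, 0.5), c(2, 4))
  expect_equal(g$L_G, 0.4)
  expect_equal(global_lostness(0.3, 7)$L_G, 0.3)
  # equal weights collapse to the plain mean
  expect_equal(global_lostness(c(0.1, 0.5, 0.9), c(3, 3, 3))$L_G, 0.5)
  expect_error(global_lostness(numeric(0), numeric(0)), "no completed tasks")
})

test_that("global lostness is a convex combination of per-task values", {
  set.seed(42)
  for (rep in 1:50) {
    k <- sample(1:6, 1L)
    L <- runif(k, 0, 2)
    x <- sample(1:5, k, replace = TRUE)
    g <- global_lostness(L, x)
    expect_gte(g$L_G, min(L))
    expect_lte(g$L_G, max(L))
    expect_equal(sum(g$per_task$weight), 1)
  }
})

test_that("local lostness applies the formula to summed counts", {
  segs <- data.frame(R = c(1, 2), S = c(4, 6), N = c(2, 3))
  r <- local_lostness(segs)
  expect_equal(r$L_L, 0.41)
  expect_equal(unname(r$summed), c(3, 10, 5))
  # perfect path segments stay perfect in the sum
  expect_equal(local_lostness(data.frame(R = c(2, 3), S = c(2, 3),
                                         N = c(2, 3)))$L_L, 0)
  # single segment agrees with the plain formula
  expect_equal(local_lostness(data.frame(R = 2, S = 9, N = 4))$L_L,
               lostness(2, 9, 4)$value)
})

test_that("summed-counts identity holds on random segment lists", {
  set.seed(7)
  for (rep in 1:200) {
    k <- sample(1:8, 1L)
    S <- sample(1:30, k, replace = TRUE)
    N <- vapply(S, function(s) sample.int(s, 1L), 0L)
    R <- vapply(N, function(n) sample.int(n, 1L), 0L)
    segs <- data.frame(R = R, S = S, N = N)
    expect_equal(local_lostness(segs)$L_L,
                 lostness(sum(R), sum(S), sum(N), strict = FALSE)$value)
  }
})

test_that("degenerate segments contribute zeros but are flagged, not scored", {
  segs <- data.frame(R = c(2, 0), S = c(4, 0), N = c(3, 0),
                     objective = c("o1", "o2"))
  r <- local_lostness(segs)
  expect_equal(r$L_L, lostness(2, 4, 3)$value)
  expect_true(is.na(r$per_objective$value[2L]))
  expect_true(r$per_objective$degenerate[2L])
  expect_error(local_lostness(data.frame(R = 0, S = 0, N = 0)),
               "no navigation")
})

test_that("player_report is exact on scripted playthroughs", {
  w <- manor_world()
  rep <- player_report(perfect_manor_log(), w$graph, w$tasks)
  expect_equal(rep$local$L_L, 0)
  expect_true(rep$complete)
  expect_equal(nrow(rep$diagnostics), 0L)
  # T1's minimum route re-enters hub B (A->X1->X3 passes B twice), so even
  # perfect play scores (4/5-1)^2 + (5/4-1)^2 on that task; T2 is clean
  expect_equal(rep$global$per_task$L, c(0.04 + 0.0625, 0))
  expect_equal(rep$global$L_G, (0.1025 * 2) / 3)
  expect_equal(rep$global$per_task$forced_revisit, c(TRUE, FALSE))

  # maximally wandering scripted walk: both measures strictly positive
  log <- script_log(list(
    list("task_start", NA, "T1"),
    list("move", "B"), list("move", "A"), list("move", "B"),
    list("move", "C"), list("move", "B"), list("move", "A"),
    list("move", "B"), list("move", "X1"),
    list("objective_complete", "X1", NA, "T1_o1"),
    list("move", "B"), list("move", "A"), list("move", "B"),
    list("move", "E"), list("move", "D"), list("move", "E"),
    list("move", "X3"),
    list("objective_complete", "X3", NA, "T1_o2"),
    list("task_complete", NA, "T1")))
  rep2 <- player_report(log, w$graph, w$tasks)
  expect_gt(rep2$global$L_G, 0)
  expect_gt(rep2$local$L_L, 0)
  expect_false(rep2$complete)  # T2 never done
})

test_that("partial completion is reported with the incompleteness flag", {
  w <- manor_world()
  log <- perfect_manor_log()
  cut <- event_log(as.data.frame(log)[1:11, ])  # through T1 only
  rep <- player_report(cut, w$graph, w$tasks)
  expect_false(rep$complete)
  expect_equal(nrow(rep$task_segments), 1L)
  expect_equal(rep$global$per_task$task, "T1")
  expect_equal(nrow(rep$local$per_objective), 2L)
})
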