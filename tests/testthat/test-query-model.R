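# Flowchart structure, validation, topological order

# the six-node example flowchart: A -> {B, C}, B -> {D, E}, C -> {F}
six_node_task <- function(select_f = FALSE) {
  nodes <- list(
    flowchart_node("A", "patient_state", criteria = list("ICD9=155.0")),
    flowchart_node("B", "action", criteria = list("ICG is within 15 to 40")),
    flowchart_node("C", "action", criteria = list('Ascites=="Controllable"')),
    flowchart_node("D", "action", criteria = list("ICG is within 15 to 30")),
    flowchart_node("E", "action", criteria = list("ICG is within 30 to 40")),
    flowchart_node("F", "action", selected = select_f,
                   criteria = list('Treatment=="Alcohol injection"')))
  query_task("six nodes", nodes,
             list(c("A", "B"), c("A", "C"), c("B", "D"), c("B", "E"),
                  c("C", "F")))
}

test_that("the six-node flowchart validates cleanly", {
  expect_equal(nrow(validate_task(six_node_task())), 0)
})

test_that("structural violations are reported as data, one per rule", {
  # entry node given a parent (cycle back from a child)
  t1 <- query_task("bad", list(
    flowchart_node("A", "patient_state"),
    flowchart_node("B", "action")),
    list(c("A", "B"), c("B", "A")))
  v1 <- validate_task(t1)
  expect_true("acyclic" %in% v1$rule)

  # two parentless nodes
  t2 <- query_task("two roots", list(
    flowchart_node("A", "patient_state"),
    flowchart_node("B", "patient_state")))
  expect_true("single-entry" %in% validate_task(t2)$rule)

  # ME decision with an incomplete priority permutation
  t3 <- query_task("bad me", list(
    flowchart_node("A", "patient_state"),
    flowchart_node("d", "decision", mutually_exclusive = TRUE,
                   child_priorities = c("x")),
    flowchart_node("x", "action"), flowchart_node("y", "action")),
    list(c("A", "d"), c("d", "x"), c("d", "y")))
  v3 <- validate_task(t3)
  expect_equal(v3$rule[v3$node_id == "d"], "me-priorities")

  # branch with a single child; criteria on a router node
  t4 <- query_task("bad branch", list(
    flowchart_node("A", "patient_state"),
    flowchart_node("b", "branch", criteria = list("ICD9=155.0")),
    flowchart_node("x", "action")),
    list(c("A", "b"), c("b", "x")))
  v4 <- validate_task(t4)
  expect_setequal(v4$rule, c("branch-fanout", "router-criteria"))
  # the router-criteria rule is relaxable
  expect_false("router-criteria" %in%
                 validate_task(t4, allow_router_criteria = TRUE)$rule)

  # a second parent on an action node
  t5 <- query_task("fan-in", list(
    flowchart_node("A", "patient_state"), flowchart_node("B", "action"),
    flowchart_node("C", "action")),
    list(c("A", "B"), c("A", "C"), c("B", "C")))
  expect_true("single-parent" %in% validate_task(t5)$rule)
})

test_that("validate_task is idempotent and side-effect free", {
  t <- six_node_task()
  before <- write_task(t)
  v1 <- validate_task(t)
  v2 <- validate_task(t)
  expect_identical(v1, v2)
  expect_true(task_identical(read_task(before), read_task(write_task(t))))
})

test_that("topological order respects the six-node edges", {
  ord <- topological_order(six_node_task())
  pos <- match(c("A", "B", "C", "D", "E", "F"), ord)
  expect_true(pos[1] < pos[2] && pos[1] < pos[3])
  expect_true(pos[2] < pos[4] && pos[2] < pos[5])
  expect_true(pos[3] < pos[6])
})

test_that("a single-node task orders as itself and cycles are named", {
  t <- query_task("solo", list(flowchart_node("only", "patient_state")))
  expect_equal(topological_order(t), "only")
  cyc <- query_task("cyc", list(
    flowchart_node("A", "patient_state"), flowchart_node("B", "action"),
    flowchart_node("C", "action")),
    list(c("A", "B"), c("B", "C"), c("C", "B")))
  expect_error(topological_order(cyc), "cycle detected.*B.*C")
})

test_that("a two-parent synchronization node sorts after both parents", {
  # 5-node diamond: entry -> {left, right} -> sync -> tail
  diamond <- query_task("diamond", list(
    flowchart_node("entry", "patient_state"),
    flowchart_node("left", "action"),
    flowchart_node("right", "action"),
    flowchart_node("sync", "synchronization"),
    flowchart_node("tail", "action")),
    list(c("entry", "left"), c("entry", "right"), c("left", "sync"),
         c("right", "sync"), c("sync", "tail")))
  ord <- topological_order(diamond)
  # exhaustive oracle: every permutation that respects the edges
  edges <- list(c("entry", "left"), c("entry", "right"), c("left", "sync"),
                c("right", "sync"), c("sync", "tail"))
  perms <- combinat_perms <- NULL
  ids <- task_node_ids(diamond)
  all_perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  valid <- Filter(function(p) {
    all(vapply(edges, function(e) match(e[1], p) < match(e[2], p), logical(1)))
  }, all_perms(ids))
  expect_true(any(vapply(valid, identical, logical(1), ord)))
  expect_true(match("sync", ord) > max(match(c("left", "right"), ord)))
})

test_that("topological order permutes the ids and respects edges on random DAGs", {
  set.seed(99)
  for (i in 1:25) {
    task <- random_task(sample(3:8, 1))
    ord <- topological_order(task)
    expect_setequal(ord, task_node_ids(task))
    for (k in seq_len(nrow(task$edges))) {
      expect_lt(match(task$edges$from[k], ord), match(task$edges$to[k], ord))
    }
  }
})
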