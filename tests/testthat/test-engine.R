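# SQL-backed execution engine

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

test_that("patient lists shrink down the flowchart; unselected nodes are zero", {
  repo <- generate_repository(generator_config(200, seed = 42))
  rep <- execute_task(six_node_task(), repo, liver_mapping())
  pls <- node_sizes(rep)
  expect_equal(pls[["F"]], 0L)
  expect_false(rep$results[["F"]]$executed)
  expect_true(all(patient_list(rep, "D") %in% patient_list(rep, "B")))
  expect_true(all(patient_list(rep, "B") %in% patient_list(rep, "A")))
  expect_lte(pls[["D"]], pls[["B"]])
  expect_lte(pls[["B"]], pls[["A"]])
  expect_lte(pls[["C"]], pls[["A"]])
})

test_that("an empty repository yields all-zero patient lists", {
  rep <- execute_task(six_node_task(), toy_repo(), liver_mapping())
  expect_true(all(node_sizes(rep) == 0))
  expect_true(all(vapply(rep$results[c("A", "B", "C", "D", "E")],
                         `[[`, logical(1), "executed")))
})

test_that("a universal criterion retrieves every patient", {
  repo <- generate_repository(generator_config(50, seed = 9))
  task <- query_task("all", list(
    flowchart_node("n", "patient_state", criteria = list("ICD9=155.0"))))
  rep <- execute_task(task, repo, liver_mapping())
  expect_equal(patient_list(rep, "n"), repository_patients(repo))
})

test_that("hand-checkable toy cohort resolves correctly", {
  repo <- toy_liver_repo()
  task <- query_task("toy", list(
    flowchart_node("icd", "patient_state", criteria = list("ICD9=155.0")),
    flowchart_node("icg", "action", criteria = list("ICG is within 15 to 40"))),
    list(c("icd", "icg")))
  rep <- execute_task(task, repo, liver_mapping())
  expect_equal(patient_list(rep, "icd"), c("p1", "p2"))
  expect_equal(patient_list(rep, "icg"), "p1")   # p3 has ICG 10 but no code
})

test_that("at-least thresholds are exact at the boundary", {
  # q1 meets exactly 2 of the 5 grade-B conditions, q2 exactly 1
  repo <- toy_repo(laboratory = rbind(
    lab_row("q1", "Ascites", str = "Controllable"),     # hit
    lab_row("q1", "ICG", num = 20),                     # hit
    lab_row("q1", "Prothrombin activity", num = 90),
    lab_row("q1", "Serum albumin", num = 4.5),
    lab_row("q1", "Serum bilirubin", num = 1.0),
    lab_row("q2", "Ascites", str = "None"),
    lab_row("q2", "ICG", num = 20),                     # only hit
    lab_row("q2", "Prothrombin activity", num = 90),
    lab_row("q2", "Serum albumin", num = 4.5),
    lab_row("q2", "Serum bilirubin", num = 1.0)))
  node <- flowchart_node("b", "action",
                         criteria = list(degree_criterion_text("B")))
  res <- execute_node(node, c("q1", "q2"), repo, liver_mapping())
  expect_equal(res$patient_list, "q1")
})

test_that("a patient with no row for an atom's item never satisfies it", {
  repo <- toy_repo(
    diagnosis = data.frame(Personal_ID = "p9", ICD9_Code = "155.0",
                           stringsAsFactors = FALSE))
  node <- flowchart_node("n", "action",
                         criteria = list("ICG is within 0 to 100"))
  res <- execute_node(node, "p9", repo, liver_mapping())
  expect_equal(res$size, 0L)
})

test_that("criteria on one node intersect patient-wise across rows", {
  # two diagnosis rows on one patient satisfy a conjunction of two codes
  repo <- toy_repo(diagnosis = data.frame(
    Personal_ID = c("p1", "p1", "p2"),
    ICD9_Code = c("733.00", "820.0", "733.00"), stringsAsFactors = FALSE))
  m <- mapping_table(list(
    mapping_entry("ICD", "direct", "Diagnosis", "ICD9_Code", "text")))
  node <- flowchart_node("n", "patient_state",
                         criteria = list("ICD=733.00 and ICD=820.0"))
  res <- execute_node(node, c("p1", "p2"), repo, m)
  expect_equal(res$patient_list, "p1")
})

test_that("mutually exclusive resolution assigns by priority", {
  parent <- flowchart_node("d", "decision", mutually_exclusive = TRUE,
                           child_priorities = c("c", "b", "a"))
  parent$children <- c("a", "b", "c")
  out <- resolve_mutually_exclusive(parent, list(
    a = c("p1", "p2", "p3"), b = c("p1", "p2"), c = c("p1")))
  expect_equal(out$c, "p1")                 # meets all three -> highest priority
  expect_equal(out$b, "p2")
  expect_equal(out$a, "p3")                 # meets only a
  expect_length(intersect(out$a, union(out$b, out$c)), 0)
})

test_that("the engine resolves ME children disjointly before descendants", {
  repo <- generate_repository(generator_config(150, seed = 21))
  task <- liver_degree_task(mutually_exclusive = TRUE)
  rep <- execute_task(task, repo, liver_mapping())
  pls <- lapply(c("degree_a", "degree_b", "degree_c"), patient_list,
                report = rep)
  expect_length(Reduce(intersect, pls), 0)
  expect_length(intersect(pls[[1]], pls[[2]]), 0)
  expect_length(intersect(pls[[1]], pls[[3]]), 0)
  expect_length(intersect(pls[[2]], pls[[3]]), 0)
  # with complete laboratory data the three degrees tile the parent exactly
  expect_setequal(unlist(pls), patient_list(rep, "degree_decision"))
  # and degree C (top priority) keeps its non-ME patient list unchanged
  rep0 <- execute_task(liver_degree_task(), repo, liver_mapping())
  expect_equal(patient_list(rep, "degree_c"), patient_list(rep0, "degree_c"))
})

test_that("without the ME setting a patient may sit in several degrees", {
  repo <- generate_repository(generator_config(400, seed = 13))
  rep <- execute_task(liver_degree_task(), repo, liver_mapping())
  sizes <- node_sizes(rep)[c("degree_a", "degree_b", "degree_c")]
  expect_gt(sum(sizes), node_sizes(rep)[["degree_decision"]])
})

test_that("synchronization intersects concurrent paths (union on request)", {
  repo <- toy_liver_repo()
  diamond <- query_task("diamond", list(
    flowchart_node("entry", "patient_state"),
    flowchart_node("left", "action", criteria = list("ICD9=155.0")),
    flowchart_node("right", "action",
                   criteria = list("ICG is within 15 to 40")),
    flowchart_node("sync", "synchronization")),
    list(c("entry", "left"), c("entry", "right"), c("left", "sync"),
         c("right", "sync")))
  rep_i <- execute_task(diamond, repo, liver_mapping())
  expect_equal(patient_list(rep_i, "sync"), "p1")
  rep_u <- execute_task(diamond, repo, liver_mapping(),
                        sync_combine = "union")
  expect_equal(patient_list(rep_u, "sync"), c("p1", "p2"))
})

test_that("descendants of unselected nodes prune by default, inherit on request", {
  repo <- toy_liver_repo()
  task <- query_task("chain", list(
    flowchart_node("icd", "patient_state", criteria = list("ICD9=155.0")),
    flowchart_node("mid", "action", criteria = list('Ascites=="Controllable"')),
    flowchart_node("leaf", "action",
                   criteria = list("ICG is within 0 to 100"))),
    list(c("icd", "mid"), c("mid", "leaf")))
  sel <- c("icd", "leaf")
  pruned <- execute_task(task, repo, liver_mapping(), selection = sel)
  expect_false(pruned$results[["leaf"]]$executed)
  expect_equal(node_sizes(pruned)[["leaf"]], 0L)
  inherited <- execute_task(task, repo, liver_mapping(), selection = sel,
                            unselected = "inherit")
  expect_true(inherited$results[["leaf"]]$executed)
  expect_equal(patient_list(inherited, "leaf"), c("p1", "p2"))
})

test_that("reports carry coherent distributions and phase accounting", {
  repo <- generate_repository(generator_config(120, seed = 2))
  rep <- execute_task(liver_degree_task(TRUE), repo, liver_mapping())
  d <- rep$distributions[["degree_decision"]]
  expect_equal(d$count,
               unname(node_sizes(rep)[c("degree_a", "degree_b", "degree_c")]))
  expect_lt(abs(sum(d$percentage) - 100), 0.02)  # ME children partition
  pr <- phase_report(rep)
  expect_equal(pr$seconds[4],
               rep$phase_timing$sql_operations +
                 rep$phase_timing$criteria_verification +
                 rep$phase_timing$other, tolerance = 1e-6)
  expect_lt(abs(sum(pr$percentage[1:3]) - 100), 0.05)
})

test_that("invalid tasks and unknown selections are refused", {
  repo <- toy_liver_repo()
  bad <- query_task("bad", list(flowchart_node("a", "patient_state"),
                                flowchart_node("b", "patient_state")))
  expect_error(execute_task(bad, repo, liver_mapping()), "invalid task")
  expect_error(execute_task(six_node_task(), repo, liver_mapping(),
                            selection = c("A", "Z")),
               "unknown node")
  expect_error(execute_task(six_node_task(), "/nonexistent/db.sqlite",
                            liver_mapping()),
               "not found")
})
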