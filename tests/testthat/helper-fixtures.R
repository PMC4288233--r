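# Shared test fixtures: a hand-checkable toy repository, random criterion
# ASTs and random (valid) query tasks compatible with the liver mapping.

toy_repo <- function(diagnosis = NULL, laboratory = NULL, treatment = NULL) {
  empty_diag <- data.frame(Personal_ID = character(),
                           ICD9_Code = character(),
                           stringsAsFactors = FALSE)
  empty_lab <- data.frame(Personal_ID = character(), Item_Name = character(),
                          Result_String = character(),
                          Result_Number = numeric(),
                          stringsAsFactors = FALSE)
  empty_trt <- data.frame(Personal_ID = character(),
                          Treatment_Name = character(),
                          stringsAsFactors = FALSE)
  structure(list(Diagnosis = if (is.null(diagnosis)) empty_diag else diagnosis,
                 Laboratory = if (is.null(laboratory)) empty_lab else laboratory,
                 Treatment = if (is.null(treatment)) empty_trt else treatment),
            class = "clinical_repository")
}

lab_row <- function(id, item, num = NA_real_, str = NA_character_) {
  data.frame(Personal_ID = id, Item_Name = item, Result_String = str,
             Result_Number = num, stringsAsFactors = FALSE)
}

# three patients: p1 has the code and controllable ascites, p2 only the
# code, p3 neither
toy_liver_repo <- function() {
  toy_repo(
    diagnosis = data.frame(Personal_ID = c("p1", "p2"),
                           ICD9_Code = c("155.0", "155.0"),
                           stringsAsFactors = FALSE),
    laboratory = rbind(
      lab_row("p1", "Ascites", str = "Controllable"),
      lab_row("p2", "Ascites", str = "None"),
      lab_row("p3", "Ascites", str = "Uncontrollable"),
      lab_row("p1", "ICG", num = 20),
      lab_row("p2", "ICG", num = 50),
      lab_row("p3", "ICG", num = 10)),
    treatment = data.frame(Personal_ID = c("p1", "p2", "p3"),
                           Treatment_Name = c("Radiofrequency ablation",
                                              "Alcohol injection",
                                              "Radiofrequency ablation"),
                           stringsAsFactors = FALSE))
}

# ---- random criterion ASTs (parseable subset: code_eq/str_eq/within) -------

random_atom <- function() {
  item <- sample(c("ICD9", "Ascites", "ICG", "Prothrombin_Activity",
                   "Serum_Albumin", "Serum_Bilirubin", "Treatment"), 1)
  if (item == "ICD9") {
    return(criterion_atom(item, "code_eq",
                          sample(c("155.0", "155.2", "820.0"), 1)))
  }
  if (item == "Ascites") {
    return(criterion_atom(item, "str_eq",
                          sample(c("None", "Controllable", "Uncontrollable"), 1)))
  }
  if (item == "Treatment") {
    return(criterion_atom(item, "str_eq", sample(liver_treatments(), 1)))
  }
  bounds <- sort(round(runif(2, 0, 100), 1))
  criterion_atom(item, "within", low = bounds[1], high = bounds[2])
}

random_criterion <- function(depth = 2) {
  if (depth <= 0 || runif(1) < 0.4) return(random_atom())
  kind <- sample(c("and", "or", "at_least"), 1)
  if (kind == "at_least") {
    n <- sample(2:5, 1)
    return(criterion_at_least(sample(n, 1),
                              replicate(n, random_atom(), simplify = FALSE)))
  }
  n <- sample(2:3, 1)
  parts <- replicate(n, random_criterion(depth - 1), simplify = FALSE)
  if (kind == "and") criterion_and(parts) else criterion_or(parts)
}

# ---- random valid query tasks ----------------------------------------------

random_node_criteria <- function() {
  k <- sample(0:2, 1, prob = c(0.3, 0.5, 0.2))
  replicate(k, random_criterion(1), simplify = FALSE)
}

# grows a random valid flowchart: a single entry, action/decision chains,
# branch nodes with two children, occasional two-parent synchronization
random_task <- function(n_extra = 6, me_prob = 0.5) {
  counter <- 0L
  new_id <- function() { counter <<- counter + 1L; sprintf("n%02d", counter) }
  specs <- list()
  add <- function(id, class, criteria = list()) {
    specs[[id]] <<- list(id = id, class = class, criteria = criteria)
  }
  edges <- list()
  entry <- new_id()
  add(entry, sample(c("patient_state", "action"), 1), random_node_criteria())
  pool <- entry                                # nodes that may take children
  for (i in seq_len(n_extra)) {
    kind <- sample(c("chain", "branchpair", "sync"), 1,
                   prob = c(0.6, 0.25, 0.15))
    if (kind == "chain") {
      parent <- sample(pool, 1)
      id <- new_id()
      add(id, sample(c("action", "decision", "patient_state"), 1),
          random_node_criteria())
      edges[[length(edges) + 1L]] <- c(parent, id)
      pool <- c(pool, id)
    } else if (kind == "branchpair") {
      parent <- sample(pool, 1)
      b <- new_id()
      add(b, "branch")
      edges[[length(edges) + 1L]] <- c(parent, b)
      for (j in 1:2) {
        ch <- new_id()
        add(ch, "action", random_node_criteria())
        edges[[length(edges) + 1L]] <- c(b, ch)
        pool <- c(pool, ch)
      }
    } else if (length(pool) >= 2) {
      parents <- sample(pool, 2)
      s <- new_id()
      add(s, "synchronization")
      for (p in parents) edges[[length(edges) + 1L]] <- c(s = p, t = s)
      pool <- c(pool, s)
    }
  }
  # children per node (needed to set mutually-exclusive priorities)
  kids <- lapply(specs, function(s) character())
  for (e in edges) kids[[e[[1]]]] <- c(kids[[e[[1]]]], e[[2]])
  nodes <- lapply(specs, function(s) {
    me <- s$class == "decision" && length(kids[[s$id]]) >= 2 &&
      runif(1) < me_prob
    flowchart_node(s$id, s$class, criteria = s$criteria,
                   mutually_exclusive = me,
                   child_priorities = if (me) sample(kids[[s$id]]) else
                     character())
  })
  task <- query_task(sprintf("random task %d", sample.int(1e6, 1)),
                     unname(nodes), edges)
  stopifnot(nrow(validate_task(task)) == 0)
  task
}

random_selection <- function(task) {
  ids <- task_node_ids(task)
  keep <- ids[runif(length(ids)) < 0.85]
  union(keep, task$entry_node_id)
}
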