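#' @title Brute-force in-memory oracle
#'
#' @description
#' An independent re-implementation of the retrieval semantics that never
#' touches SQL or the translation path: criteria are evaluated by direct
#' filtering of the repository's in-memory rows, and the flowchart
#' propagation, mutually-exclusive resolution and at-least thresholds are
#' re-coded from the semantics alone. Running the engine and the oracle
#' over the same task and repository and comparing patient lists node by
#' node is the package's accuracy check — the machine stand-in for a
#' manually collected gold standard.
#' @name oracle
NULL

# patients whose rows directly satisfy one atom; no SQL, no shared
# translation code — plain data-frame filtering
.oracle_atom_satisfiers <- function(atom, repo, mapping) {
  entry <- mapping$entries[[atom$item]]
  if (is.null(entry)) {
    stop(sprintf("mapping not predefined for item '%s'", atom$item),
         call. = FALSE)
  }
  df <- repo[[entry$table]]
  if (is.null(df)) {
    stop(sprintf("repository has no table '%s'", entry$table), call. = FALSE)
  }
  if (entry$mode == "indirect") {
    df <- df[!is.na(df[[entry$discriminator_column]]) &
             df[[entry$discriminator_column]] == entry$discriminator_value, ,
             drop = FALSE]
  }
  v <- df[[entry$value_column]]
  hit <- switch(atom$op,
    within = !is.na(v) & v >= atom$low & v <= atom$high,
    str_eq = !is.na(v) & as.character(v) == atom$value,
    num_eq = !is.na(v) & suppressWarnings(as.numeric(v)) == atom$value,
    code_eq = if (entry$value_type == "number") {
      !is.na(v) & suppressWarnings(as.numeric(v)) ==
        suppressWarnings(as.numeric(atom$value))
    } else {
      !is.na(v) & as.character(v) == as.character(atom$value)
    }
  )
  unique(df$Personal_ID[hit])
}

.oracle_criterion_satisfiers <- function(crit, repo, mapping) {
  if (inherits(crit, "criterion_atom")) {
    return(.oracle_atom_satisfiers(crit, repo, mapping))
  }
  if (inherits(crit, "criterion_at_least")) {
    sets <- lapply(crit$atoms, .oracle_atom_satisfiers, repo, mapping)
    counts <- table(unlist(sets))
    return(names(counts)[counts >= crit$k])
  }
  sets <- lapply(crit$parts, .oracle_criterion_satisfiers, repo, mapping)
  if (inherits(crit, "criterion_and")) return(Reduce(intersect, sets))
  unique(unlist(sets))
}

#' Evaluate a query task by brute force, in memory
#'
#' Same contract and report schema as [execute_task()], computed without
#' any SQL: every criterion is checked by filtering the repository's data
#' frames row by row. Intended as the independent reference the engine is
#' verified against, not as a fast path.
#'
#' @param task a valid [query_task()]
#' @param repo a `clinical_repository` (plain data frames)
#' @param mapping a [mapping_table()]
#' @param selection,unselected,sync_combine as in [execute_task()]
#' @return a `query_report`
#' @export
evaluate_in_memory <- function(task, repo, mapping,
                               selection = selected_nodes(task),
                               unselected = c("prune", "inherit"),
                               sync_combine = c("intersect", "union")) {
  unselected <- match.arg(unselected)
  sync_combine <- match.arg(sync_combine)
  stopifnot(inherits(repo, "clinical_repository"))
  t_start <- proc.time()[[3L]]
  viol <- validate_task(task)
  if (nrow(viol)) {
    stop(sprintf("invalid task '%s': %s", task$name,
                 paste(sprintf("[%s] %s", viol$rule, viol$message),
                       collapse = "; ")), call. = FALSE)
  }
  universe <- repository_patients(repo)
  ord <- topological_order(task)
  results <- stats::setNames(vector("list", length(ord)), ord)
  me_resolved <- list()

  node_satisfiers <- function(id, target) {
    n <- task$nodes[[id]]
    out <- target
    for (crit in n$criteria) {
      out <- intersect(out, .oracle_criterion_satisfiers(crit, repo, mapping))
    }
    sort(out)
  }

  inherited <- function(id) {
    n <- task$nodes[[id]]
    if (!length(n$parents)) return(universe)
    sets <- lapply(n$parents, function(p) {
      if (results[[p]]$executed) results[[p]]$patient_list else inherited(p)
    })
    if (n$node_class == "synchronization" && sync_combine == "union") {
      unique(unlist(sets))
    } else Reduce(intersect, sets)
  }

  resolve_group <- function(pid) {
    if (!is.null(me_resolved[[pid]])) return(invisible())
    parent <- task$nodes[[pid]]
    pool <- results[[pid]]$patient_list
    out <- list()
    for (child in parent$child_priorities) {
      if (!child %in% selection) { out[[child]] <- character(); next }
      hit <- node_satisfiers(child, pool)
      out[[child]] <- hit
      pool <- setdiff(pool, hit)
    }
    me_resolved[[pid]] <<- out
  }

  for (id in ord) {
    n <- task$nodes[[id]]
    if (!id %in% selection) { results[[id]] <- node_result(id); next }
    if (!length(n$parents)) {
      results[[id]] <- node_result(id, node_satisfiers(id, universe),
                                   executed = TRUE)
      next
    }
    parent_exec <- vapply(n$parents, function(p) results[[p]]$executed,
                          logical(1))
    if (!all(parent_exec) && unselected == "prune") {
      results[[id]] <- node_result(id)
      next
    }
    contributions <- list()
    criteria_done <- FALSE
    for (p in n$parents) {
      pn <- task$nodes[[p]]
      if (results[[p]]$executed && isTRUE(pn$mutually_exclusive)) {
        resolve_group(p)
        contributions[[p]] <- me_resolved[[p]][[id]]
        criteria_done <- TRUE
      } else if (results[[p]]$executed) {
        contributions[[p]] <- results[[p]]$patient_list
      } else {
        contributions[[p]] <- inherited(p)
      }
    }
    target <- if (n$node_class == "synchronization" &&
                  sync_combine == "union") {
      unique(unlist(contributions))
    } else Reduce(intersect, contributions)
    pl <- if (criteria_done) sort(target) else node_satisfiers(id, target)
    results[[id]] <- node_result(id, pl, executed = TRUE)
  }

  distributions <- list()
  for (id in ord) {
    n <- task$nodes[[id]]
    if (!n$node_class %in% c("decision", "branch")) next
    if (!results[[id]]$executed || length(n$children) < 2L) next
    distributions[[id]] <- distribution(results[[id]], results[n$children])
  }

  total <- proc.time()[[3L]] - t_start
  structure(list(
    task = task$name,
    selection = intersect(task_node_ids(task), selection),
    results = results,
    distributions = distributions,
    phase_timing = list(sql_operations = 0,
                        criteria_verification = total, other = 0,
                        total = total)
  ), class = "query_report")
}

#' Compare two query reports node by node
#'
#' A node matches when both reports agree on its executed flag and its
#' exact patient list. Accuracy is the percentage of executed nodes that
#' match; a task counts as answered correctly only when every node
#' matches.
#'
#' @param a,b `query_report` objects for the same task and selection
#' @return an object of class `accuracy_result` with fields `task`,
#'   `n_nodes`, `n_matching`, `accuracy` (0–100), `task_correct` and
#'   `mismatched_nodes`
#' @export
compare_reports <- function(a, b) {
  if (!identical(a$task, b$task)) {
    stop(sprintf("cannot compare reports for different tasks ('%s' vs '%s')",
                 a$task, b$task), call. = FALSE)
  }
  ids <- union(names(a$results), names(b$results))
  considered <- character()
  mism <- character()
  for (id in ids) {
    ra <- a$results[[id]]; rb <- b$results[[id]]
    if (is.null(ra) || is.null(rb)) { mism <- c(mism, id); next }
    if (!ra$executed && !rb$executed) next       # both skipped: not scored
    considered <- c(considered, id)
    if (!identical(ra$executed, rb$executed) ||
        !identical(ra$patient_list, rb$patient_list)) {
      mism <- c(mism, id)
    }
  }
  n <- length(considered)
  n_match <- n - sum(mism %in% considered)
  structure(list(task = a$task, n_nodes = n, n_matching = n_match,
                 accuracy = if (n) 100 * n_match / n else 100,
                 task_correct = length(mism) == 0L,
                 mismatched_nodes = mism),
            class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("<accuracy_result> task '%s': %d/%d nodes match (%.2f%%)\n",
              x$task, x$n_matching, x$n_nodes, x$accuracy))
  if (length(x$mismatched_nodes)) {
    cat("  mismatched:", paste(x$mismatched_nodes, collapse = ", "), "\n")
  }
  invisible(x)
}
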