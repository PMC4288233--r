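#' @title Query execution engine
#'
#' @description
#' The clinical data retriever: nodes are processed top-down in
#' topological order. For each selected node the patients satisfying its
#' parents' criteria — PL(PN(node)) — form the query target set; the
#' node's own criteria QC(node) are applied to that set and the surviving
#' patients form PL(node). A parentless node targets every patient in the
#' repository; an unselected node yields a zero-size result. Each atom of
#' every criterion runs as one SQL subquery, and the `and`/`or`/at-least
#' combinations plus the parent-set intersections are verified in the
#' host, which is what the three-phase timing (SQL operations / criteria
#' verification / other) accounts for.
#' @name engine
NULL

node_result <- function(node_id, patient_list = character(),
                        executed = FALSE) {
  patient_list <- sort(unique(as.character(patient_list)))
  structure(list(node_id = node_id, patient_list = patient_list,
                 size = length(patient_list), executed = executed),
            class = "node_result")
}

#' @export
print.node_result <- function(x, ...) {
  cat(sprintf("<node_result> %s: PLS=%d%s\n", x$node_id, x$size,
              if (x$executed) "" else " (not executed)"))
  invisible(x)
}

.set_intersect <- function(sets) {
  if (!length(sets)) return(character())
  Reduce(intersect, sets)
}

.set_union <- function(sets) {
  if (!length(sets)) return(character())
  unique(unlist(sets))
}

# run one sql_atom through DBI with bound parameters (never string-spliced)
.execute_sql_atom <- function(con, atom) {
  clauses <- character()
  params <- list()
  for (cond in atom$conditions) {
    if (cond$kind == "between") {
      clauses <- c(clauses, sprintf("%s BETWEEN ? AND ?", cond$column))
      params <- c(params, list(cond$low, cond$high))
    } else {
      clauses <- c(clauses, sprintf("%s = ?", cond$column))
      params <- c(params, list(cond$value))
    }
  }
  sql <- sprintf("SELECT %s FROM %s WHERE %s", .PATIENT_ID_COLUMN, atom$table,
                 paste(clauses, collapse = " AND "))
  unique(as.character(DBI::dbGetQuery(con, sql, params = params)[[1L]]))
}

.combine_sets <- function(combiner, atom_sets) {
  switch(combiner$kind,
    atom = atom_sets[[combiner$index]],
    and = .set_intersect(lapply(combiner$parts, .combine_sets, atom_sets)),
    or = .set_union(lapply(combiner$parts, .combine_sets, atom_sets)),
    at_least = {
      sets <- lapply(combiner$parts, .combine_sets, atom_sets)
      counts <- table(unlist(sets))
      names(counts)[counts >= combiner$k]
    }
  )
}

#' Resolve the children of a mutually-exclusive decision node
#'
#' Children are considered in priority order (highest first); each patient
#' is assigned to the first child whose criteria it satisfies and removed
#' from consideration for all lower-priority children. The resulting
#' lists are pairwise disjoint and their union is contained in the union
#' of the raw lists.
#'
#' @param parent the decision [flowchart_node()] with `mutually_exclusive`
#'   set and `child_priorities` a permutation of its children
#' @param child_results named list: child id to raw patient-id vector
#'   (patients within the parent's list satisfying that child's criteria)
#' @return named list (same child ids) of disjoint patient-id vectors
#' @export
resolve_mutually_exclusive <- function(parent, child_results) {
  if (!isTRUE(parent$mutually_exclusive)) {
    stop(sprintf("node '%s' is not mutually exclusive", parent$id),
         call. = FALSE)
  }
  prio <- parent$child_priorities
  if (!length(prio) || !setequal(prio, parent$children)) {
    stop(sprintf("node '%s': child_priorities must list every child", parent$id),
         call. = FALSE)
  }
  assigned <- character()
  out <- stats::setNames(vector("list", length(child_results)),
                         names(child_results))
  for (child in prio) {
    if (!child %in% names(child_results)) next
    res <- setdiff(child_results[[child]], assigned)
    assigned <- c(assigned, res)
    out[[child]] <- sort(res)
  }
  out
}

.as_repo_connection <- function(repo) {
  if (inherits(repo, "DBIConnection")) {
    return(list(con = repo, close = FALSE))
  }
  if (inherits(repo, "clinical_repository")) {
    con <- DBI::dbConnect(RSQLite::SQLite(), ":memory:")
    load_repository_into(repo, con)
    return(list(con = con, close = TRUE))
  }
  if (is.character(repo) && length(repo) == 1L) {
    if (!file.exists(repo)) {
      stop(sprintf("repository database not found: %s", repo), call. = FALSE)
    }
    return(list(con = DBI::dbConnect(RSQLite::SQLite(), repo), close = TRUE))
  }
  stop("repo must be a DBI connection, a clinical_repository, or a database path",
       call. = FALSE)
}

.sql_universe <- function(con) {
  tabs <- DBI::dbListTables(con)
  sel <- sprintf("SELECT DISTINCT %s FROM %s", .PATIENT_ID_COLUMN, tabs)
  sort(as.character(DBI::dbGetQuery(con, paste(sel, collapse = " UNION "))[[1L]]))
}

#' Execute a query task over a clinical repository
#'
#' @param task a valid [query_task()]
#' @param repo a DBI connection, a path to a SQLite repository file, or a
#'   `clinical_repository` (loaded into a temporary in-memory database)
#' @param mapping a [mapping_table()] resolving every data item used by
#'   the selected nodes
#' @param selection node ids to execute (default: the nodes whose
#'   `selected` flag is on, see [selected_nodes()]). Unselected nodes
#'   report `executed = FALSE` with an empty patient list.
#' @param unselected what happens below an unselected/skipped node:
#'   `"prune"` (default) skips all descendants; `"inherit"` lets a child
#'   target the nearest executed ancestor's patient list
#' @param sync_combine how a synchronization node combines its parents'
#'   patient lists: `"intersect"` (default, concurrent paths must all
#'   hold) or `"union"`
#' @return an object of class `query_report`: per-node results (PL/PLS),
#'   per-parent child distributions and the three-phase timing
#' @export
#' @examples
#' repo <- generate_repository(generator_config(25, seed = 7))
#' rep <- execute_task(liver_degree_task(), repo, liver_mapping())
#' node_sizes(rep)
execute_task <- function(task, repo, mapping,
                         selection = selected_nodes(task),
                         unselected = c("prune", "inherit"),
                         sync_combine = c("intersect", "union")) {
  unselected <- match.arg(unselected)
  sync_combine <- match.arg(sync_combine)
  t_start <- proc.time()[[3L]]

  viol <- validate_task(task)
  if (nrow(viol)) {
    stop(sprintf("invalid task '%s': %s", task$name,
                 paste(sprintf("[%s] %s", viol$rule, viol$message),
                       collapse = "; ")), call. = FALSE)
  }
  bad <- setdiff(selection, task_node_ids(task))
  if (length(bad)) {
    stop(sprintf("selection names unknown node(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }

  handle <- .as_repo_connection(repo)
  con <- handle$con
  if (handle$close) on.exit(DBI::dbDisconnect(con), add = TRUE)

  phase <- new.env(parent = emptyenv())
  phase$sql <- 0; phase$verify <- 0
  timed <- function(which, expr) {
    t0 <- proc.time()[[3L]]
    out <- force(expr)
    assign(which, get(which, envir = phase) + proc.time()[[3L]] - t0,
           envir = phase)
    out
  }

  # translate QC of every selected node up front ("other" phase work)
  plans <- translate_task(task, mapping, selection)

  # patient set satisfying one node's full criteria list, within `target`
  eval_node <- function(id, target) {
    nplans <- plans[[id]]
    if (!length(nplans)) return(sort(target))
    crit_sets <- lapply(nplans, function(plan) {
      atom_sets <- lapply(plan$atoms, function(a)
        timed("sql", .execute_sql_atom(con, a)))
      timed("verify", .combine_sets(plan$combiner, atom_sets))
    })
    timed("verify", sort(intersect(target, .set_intersect(crit_sets))))
  }

  ord <- topological_order(task)
  results <- stats::setNames(vector("list", length(ord)), ord)
  # per ME-parent: resolved (disjoint, criteria-applied) child contributions
  me_resolved <- list()
  universe <- NULL
  get_universe <- function() {
    if (is.null(universe)) universe <<- timed("sql", .sql_universe(con))
    universe
  }

  # patient list a child should inherit when its parent was not executed
  inherited_pl <- function(id) {
    n <- task$nodes[[id]]
    if (!length(n$parents)) return(get_universe())
    sets <- lapply(n$parents, function(p) {
      if (results[[p]]$executed) results[[p]]$patient_list else inherited_pl(p)
    })
    if (n$node_class == "synchronization" && sync_combine == "union") {
      .set_union(sets)
    } else .set_intersect(sets)
  }

  resolve_me_group <- function(pid) {
    if (!is.null(me_resolved[[pid]])) return(invisible())
    parent <- task$nodes[[pid]]
    pool <- results[[pid]]$patient_list
    out <- list()
    for (child in parent$child_priorities) {
      if (!child %in% selection) { out[[child]] <- character(); next }
      hit <- eval_node(child, pool)
      out[[child]] <- hit
      pool <- timed("verify", setdiff(pool, hit))
    }
    me_resolved[[pid]] <<- out
  }

  for (id in ord) {
    n <- task$nodes[[id]]
    if (!id %in% selection) {
      results[[id]] <- node_result(id)       # PLS = 0, not executed
      next
    }
    if (!length(n$parents)) {
      results[[id]] <- node_result(id, eval_node(id, get_universe()),
                                   executed = TRUE)
      next
    }
    parent_exec <- vapply(n$parents, function(p) results[[p]]$executed,
                          logical(1))
    if (!all(parent_exec) && unselected == "prune") {
      results[[id]] <- node_result(id)       # descendant of a skipped node
      next
    }
    contributions <- list()
    criteria_done <- FALSE
    for (p in n$parents) {
      pn <- task$nodes[[p]]
      if (results[[p]]$executed && isTRUE(pn$mutually_exclusive)) {
        resolve_me_group(p)
        contributions[[p]] <- me_resolved[[p]][[id]]
        criteria_done <- TRUE                # criteria applied in group pass
      } else if (results[[p]]$executed) {
        contributions[[p]] <- results[[p]]$patient_list
      } else {
        contributions[[p]] <- inherited_pl(p)
      }
    }
    target <- timed("verify", if (n$node_class == "synchronization" &&
                                  sync_combine == "union") {
      .set_union(contributions)
    } else .set_intersect(contributions))
    pl <- if (criteria_done && length(n$parents) == 1L) {
      sort(target)
    } else if (criteria_done) {
      timed("verify", sort(target))          # already filtered via ME parent
    } else {
      eval_node(id, target)
    }
    results[[id]] <- node_result(id, pl, executed = TRUE)
  }

  # child distributions for decision/branch parents
  distributions <- list()
  for (id in ord) {
    n <- task$nodes[[id]]
    if (!n$node_class %in% c("decision", "branch")) next
    if (!results[[id]]$executed || length(n$children) < 2L) next
    distributions[[id]] <- distribution(results[[id]],
                                        results[n$children])
  }

  total <- proc.time()[[3L]] - t_start
  other <- max(total - phase$sql - phase$verify, 0)
  structure(list(
    task = task$name,
    selection = intersect(task_node_ids(task), selection),
    results = results,
    distributions = distributions,
    phase_timing = list(sql_operations = phase$sql,
                        criteria_verification = phase$verify,
                        other = other, total = total)
  ), class = "query_report")
}

#' Execute one node against an explicit target set
#'
#' A patient enters the result iff it is in `target` and satisfies every
#' criterion of the node (the criteria list is a conjunction; an at-least
#' criterion holds iff the patient satisfies at least `k` of its atoms; a
#' patient with no row for an atom's item never satisfies that atom).
#'
#' @param node a [flowchart_node()]
#' @param target character vector of candidate patient ids
#' @param repo repository handle as in [execute_task()]
#' @param mapping a [mapping_table()]
#' @return a `node_result`
#' @export
execute_node <- function(node, target, repo, mapping) {
  handle <- .as_repo_connection(repo)
  con <- handle$con
  if (handle$close) on.exit(DBI::dbDisconnect(con), add = TRUE)
  sat <- target
  for (crit in node$criteria) {
    plan <- translate_criterion(crit, mapping)
    atom_sets <- lapply(plan$atoms, function(a) .execute_sql_atom(con, a))
    sat <- intersect(sat, .combine_sets(plan$combiner, atom_sets))
  }
  node_result(node$id, sat, executed = TRUE)
}

#' @export
print.query_report <- function(x, ...) {
  cat(sprintf("<query_report> task '%s'\n", x$task))
  for (r in x$results) {
    cat(sprintf("  %s: PLS=%d%s\n", r$node_id, r$size,
                if (r$executed) "" else " (not executed)"))
  }
  pt <- x$phase_timing
  cat(sprintf("  phases: SQL %.3fs, verification %.3fs, other %.3fs (total %.3fs)\n",
              pt$sql_operations, pt$criteria_verification, pt$other, pt$total))
  invisible(x)
}

#' Per-node patient-list sizes of a report
#'
#' @param report a `query_report`
#' @return named integer vector of PLS(node) in document order
#' @export
node_sizes <- function(report) {
  vapply(report$results, `[[`, integer(1), "size")
}

#' Patient list of one node
#'
#' @param report a `query_report`
#' @param node_id node id
#' @return character vector (sorted patient ids)
#' @export
patient_list <- function(report, node_id) {
  r <- report$results[[node_id]]
  if (is.null(r)) stop(sprintf("no result for node '%s'", node_id), call. = FALSE)
  r$patient_list
}
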