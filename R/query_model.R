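#' @title Flowchart query model
#'
#' @description
#' A query task is a directed acyclic flowchart of typed nodes, each of the
#' five GLIF3.5 step classes used for cohort querying: `action`, `decision`,
#' `branch`, `synchronization` and `patient_state`. Every node may hold an
#' ordered list of criteria (its QC); the engine propagates patient lists
#' (PL) down the flowchart, so a node's result is always a subset of its
#' parents' results.
#' @name query_model
NULL

.NODE_CLASSES <- c("action", "decision", "branch", "synchronization",
                   "patient_state")

#' Construct a flowchart node
#'
#' @param id unique node identifier (non-empty string)
#' @param node_class one of `"action"`, `"decision"`, `"branch"`,
#'   `"synchronization"`, `"patient_state"`
#' @param name display name; defaults to the id
#' @param criteria the node's query criteria QC(node): a list of
#'   `criterion` objects and/or criterion strings (strings are parsed)
#' @param selected whether the node participates in query execution
#' @param mutually_exclusive decision-node mode: each patient is assigned
#'   to at most one child, the highest-priority child whose criteria it
#'   satisfies
#' @param child_priorities child ids ordered highest priority first
#'   (required when `mutually_exclusive`)
#' @return an object of class `flowchart_node`
#' @export
#' @examples
#' flowchart_node("n1", "patient_state", criteria = list("ICD9=155.0"))
flowchart_node <- function(id, node_class, name = id, criteria = list(),
                           selected = TRUE, mutually_exclusive = FALSE,
                           child_priorities = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  node_class <- match.arg(node_class, .NODE_CLASSES)
  if (inherits(criteria, "criterion")) criteria <- list(criteria)
  criteria <- lapply(criteria, function(cr) {
    if (is.character(cr)) {
      parsed <- parse_criterion(cr)
      attr(parsed, "source") <- cr          # verbatim text, kept for round-trips
      parsed
    } else cr
  })
  ok <- vapply(criteria, inherits, logical(1), "criterion")
  if (!all(ok)) stop("criteria must be criterion objects or strings", call. = FALSE)
  structure(list(
    id = id, name = as.character(name), node_class = node_class,
    criteria = criteria, selected = isTRUE(selected),
    mutually_exclusive = isTRUE(mutually_exclusive),
    child_priorities = as.character(child_priorities),
    parents = character(), children = character()
  ), class = "flowchart_node")
}

#' Construct a query task
#'
#' Wires nodes together with `edges` (parent/child pairs); parent and child
#' link lists on each node are derived from the edge list in document
#' order. The entry point is the unique parentless node.
#'
#' @param name task name
#' @param nodes list of [flowchart_node()] objects (document order matters:
#'   it breaks ties in [topological_order()])
#' @param edges two-column data frame or matrix with columns `from`, `to`
#'   (node ids), or a list of `c(from, to)` pairs
#' @return an object of class `query_task`
#' @export
query_task <- function(name, nodes, edges = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  ids <- vapply(nodes, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate node id: %s", ids[duplicated(ids)][1L]), call. = FALSE)
  }
  names(nodes) <- ids
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE)
  } else if (is.list(edges) && !is.data.frame(edges)) {
    edges <- data.frame(from = vapply(edges, `[`, character(1), 1L),
                        to = vapply(edges, `[`, character(1), 2L),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  }
  names(edges) <- c("from", "to")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  for (k in seq_len(nrow(edges))) {
    f <- edges$from[k]; t <- edges$to[k]
    if (!f %in% ids || !t %in% ids) {
      stop(sprintf("edge %s -> %s references an unknown node", f, t),
           call. = FALSE)
    }
    nodes[[f]]$children <- c(nodes[[f]]$children, t)
    nodes[[t]]$parents <- c(nodes[[t]]$parents, f)
  }
  entry <- ids[vapply(nodes, function(n) length(n$parents) == 0L, logical(1))]
  structure(list(name = name, nodes = nodes, edges = edges,
                 entry_node_id = if (length(entry) == 1L) entry else NA_character_),
            class = "query_task")
}

#' @export
print.query_task <- function(x, ...) {
  cat(sprintf("<query_task> %s: %d nodes, %d edges\n",
              x$name, length(x$nodes), nrow(x$edges)))
  for (n in x$nodes) {
    cat(sprintf("  [%s] %s (%s)%s%s: %d criteria\n",
                n$id, n$name, n$node_class,
                if (n$selected) "" else " [unselected]",
                if (n$mutually_exclusive) " [mutually exclusive]" else "",
                length(n$criteria)))
  }
  invisible(x)
}

#' Node ids of a query task
#' @param task a [query_task()]
#' @return character vector of node ids in document order
#' @export
task_node_ids <- function(task) {
  names(task$nodes)
}

#' Node ids flagged as selected
#'
#' The default node selection for execution: every node whose `selected`
#' flag is on.
#'
#' @param task a [query_task()]
#' @return character vector of node ids
#' @export
selected_nodes <- function(task) {
  ids <- task_node_ids(task)
  ids[vapply(task$nodes, `[[`, logical(1), "selected")]
}

#' Validate a query task
#'
#' Checks the structural invariants of the flowchart model and returns the
#' violations as data, not exceptions:
#' * the graph is acyclic and every node is reachable from the entry node;
#' * there is exactly one parentless (entry) node, of class `patient_state`
#'   or `action`;
#' * `branch` nodes have at least 2 children, `synchronization` nodes at
#'   least 2 parents, all other nodes at most 1 parent;
#' * `branch`/`synchronization` nodes carry no criteria (they route only;
#'   relax with `allow_router_criteria = TRUE`);
#' * `child_priorities` of a mutually-exclusive decision node is a
#'   permutation of its children.
#'
#' @param task a [query_task()]
#' @param allow_router_criteria allow criteria on branch/synchronization
#'   nodes
#' @return a data frame with columns `node_id`, `rule`, `message`
#'   (zero rows when the task is valid), of class `validation_report`
#' @export
validate_task <- function(task, allow_router_criteria = FALSE) {
  v <- list()
  flag <- function(node_id, rule, message) {
    v[[length(v) + 1L]] <<- data.frame(node_id = node_id, rule = rule,
                                       message = message,
                                       stringsAsFactors = FALSE)
  }
  ids <- task_node_ids(task)
  roots <- ids[vapply(task$nodes, function(n) length(n$parents) == 0L,
                      logical(1))]
  if (length(roots) != 1L) {
    flag(NA_character_, "single-entry",
         sprintf("expected exactly one parentless entry node, found %d",
                 length(roots)))
  }
  if (!is.na(task$entry_node_id)) {
    entry <- task$nodes[[task$entry_node_id]]
    if (length(entry$parents) > 0L) {
      flag(entry$id, "entry-has-parent", "entry node must have no parents")
    }
    if (!entry$node_class %in% c("patient_state", "action")) {
      flag(entry$id, "entry-class",
           sprintf("entry node class is '%s', expected patient_state or action",
                   entry$node_class))
    }
  }
  for (n in task$nodes) {
    if (n$node_class == "branch" && length(n$children) < 2L) {
      flag(n$id, "branch-fanout", "branch node must have >= 2 children")
    }
    if (n$node_class == "synchronization" && length(n$parents) < 2L) {
      flag(n$id, "synchronization-fanin",
           "synchronization node must have >= 2 parents")
    }
    if (n$node_class != "synchronization" && length(n$parents) > 1L) {
      flag(n$id, "single-parent",
           sprintf("node of class '%s' must have <= 1 parent", n$node_class))
    }
    if (!allow_router_criteria &&
        n$node_class %in% c("branch", "synchronization") &&
        length(n$criteria) > 0L) {
      flag(n$id, "router-criteria",
           sprintf("%s nodes route only and must carry no criteria",
                   n$node_class))
    }
    if (n$mutually_exclusive) {
      if (n$node_class != "decision") {
        flag(n$id, "me-on-non-decision",
             "mutually_exclusive is meaningful on decision nodes only")
      }
      if (!setequal(n$child_priorities, n$children) ||
          length(n$child_priorities) != length(n$children) ||
          anyDuplicated(n$child_priorities) > 0L) {
        flag(n$id, "me-priorities",
             "child_priorities must be a permutation of the node's children")
      }
    }
  }
  ord <- tryCatch(topological_order(task), error = function(e) NULL)
  if (is.null(ord)) {
    flag(NA_character_, "acyclic", "flowchart contains a cycle")
  } else if (length(roots) == 1L) {
    reach <- .reachable_from(task, roots)
    un <- setdiff(ids, reach)
    for (u in un) {
      flag(u, "unreachable", "node not reachable from the entry node")
    }
  }
  out <- if (length(v)) do.call(rbind, v) else
    data.frame(node_id = character(), rule = character(),
               message = character(), stringsAsFactors = FALSE)
  class(out) <- c("validation_report", class(out))
  out
}

.reachable_from <- function(task, start) {
  seen <- character()
  queue <- start
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    queue <- c(queue, task$nodes[[cur]]$children)
  }
  seen
}

#' Topological order of a query task's nodes
#'
#' Kahn's algorithm with deterministic tie-breaking: among nodes whose
#' parents have all been emitted, the one declared first in the task wins.
#' Execution proceeds in this order, from the top layer of the flowchart
#' to the bottom layers.
#'
#' @param task a [query_task()]
#' @return character vector of node ids, every node after all its parents
#' @export
topological_order <- function(task) {
  ids <- task_node_ids(task)
  indeg <- vapply(task$nodes, function(n) length(n$parents), integer(1))
  out <- character()
  remaining <- ids
  while (length(remaining)) {
    ready <- remaining[indeg[remaining] == 0L]
    if (!length(ready)) {
      stop(sprintf("cycle detected among nodes: %s",
                   paste(remaining, collapse = ", ")), call. = FALSE)
    }
    nxt <- ready[1L]                       # document order
    out <- c(out, nxt)
    remaining <- setdiff(remaining, nxt)
    for (ch in task$nodes[[nxt]]$children) indeg[ch] <- indeg[ch] - 1L
  }
  out
}
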