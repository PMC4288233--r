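#' @title Task XML interchange
#'
#' @description
#' Query tasks are exchanged as XML documents in a small versioned
#' dialect (conventional extension `.fbdqm.xml`; schema shipped at
#' `extdata/fbdqm-task.xsd`). The dialect models the information a
#' GLIF3.5 flowchart export carries for querying — node class, criterion
#' strings, edges, selection flags and mutually-exclusive child
#' priorities — and nothing else. It is a stand-in dialect: real
#' Protégé/GLIF3.5 RDF or project exports are *not* parsed.
#'
#' ```xml
#' <queryTask version="1.0" name="...">
#'   <node id="icd" name="..." class="patient_state" selected="true"
#'         mutuallyExclusive="false">
#'     <criterion>ICD9=155.0</criterion>
#'     <priority>degree_c</priority>   <!-- ME decision nodes only -->
#'   </node>
#'   <edge from="icd" to="degree_decision"/>
#' </queryTask>
#' ```
#' Criterion text is stored verbatim (whitespace-preserving); files are
#' UTF-8.
#' @name task_io
NULL

.TASK_DIALECT_VERSION <- "1.0"

.xml_bool <- function(x) if (isTRUE(x)) "true" else "false"

.parse_bool <- function(x, default = FALSE) {
  if (is.na(x) || !nzchar(x)) return(default)
  tolower(x) %in% c("true", "1", "yes")
}

#' Read a query task from its XML document
#'
#' The returned task has passed [validate_task()]; a structurally invalid
#' document fails with the violations in the error message. Criterion
#' strings are parsed with [parse_criterion()]; an unparseable criterion
#' fails naming the node and the offending text.
#'
#' @param path path to a `.fbdqm.xml` file (or an `xml2::xml_document`)
#' @return a [query_task()]
#' @export
#' @examples
#' task <- read_task(fixture_paths()[["degree_task"]])
#' length(task$nodes)
read_task <- function(path) {
  doc <- if (inherits(path, "xml_document")) path else {
    tryCatch(xml2::read_xml(path), error = function(e) {
      stop(sprintf("malformed task XML: %s", conditionMessage(e)),
           call. = FALSE)
    })
  }
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "queryTask") {
    stop(sprintf("schema error: expected <queryTask> root, found <%s>",
                 xml2::xml_name(root)), call. = FALSE)
  }
  ver <- xml2::xml_attr(root, "version")
  if (!is.na(ver) && ver != .TASK_DIALECT_VERSION) {
    stop(sprintf("unsupported task dialect version '%s'", ver), call. = FALSE)
  }
  name <- xml2::xml_attr(root, "name")
  if (is.na(name)) name <- ""

  nodes <- lapply(xml2::xml_find_all(root, "./node"), function(nd) {
    id <- xml2::xml_attr(nd, "id")
    if (is.na(id) || !nzchar(id)) {
      stop("schema error: <node> without id attribute", call. = FALSE)
    }
    cls <- xml2::xml_attr(nd, "class")
    if (is.na(cls) || !cls %in% .NODE_CLASSES) {
      stop(sprintf("schema error: unknown node class '%s' on node '%s'",
                   cls, id), call. = FALSE)
    }
    nm <- xml2::xml_attr(nd, "name")
    if (is.na(nm)) nm <- id
    crit_text <- xml2::xml_text(xml2::xml_find_all(nd, "./criterion"))
    criteria <- lapply(crit_text, function(txt) {
      tryCatch(parse_criterion(txt), error = function(e) {
        stop(sprintf("node '%s': cannot parse criterion \"%s\": %s",
                     id, txt, conditionMessage(e)), call. = FALSE)
      })
    })
    for (i in seq_along(criteria)) attr(criteria[[i]], "source") <- crit_text[i]
    flowchart_node(
      id, cls, name = nm, criteria = criteria,
      selected = .parse_bool(xml2::xml_attr(nd, "selected"), TRUE),
      mutually_exclusive = .parse_bool(xml2::xml_attr(nd, "mutuallyExclusive")),
      child_priorities = xml2::xml_text(xml2::xml_find_all(nd, "./priority")))
  })

  edge_nodes <- xml2::xml_find_all(root, "./edge")
  edges <- data.frame(from = xml2::xml_attr(edge_nodes, "from"),
                      to = xml2::xml_attr(edge_nodes, "to"),
                      stringsAsFactors = FALSE)
  if (nrow(edges) && (anyNA(edges$from) || anyNA(edges$to))) {
    stop("schema error: <edge> requires from and to attributes", call. = FALSE)
  }
  task <- query_task(name, nodes, edges)
  viol <- validate_task(task)
  if (nrow(viol)) {
    stop(sprintf("task '%s' fails validation:\n%s", name,
                 paste(sprintf("  - [%s] %s: %s", viol$rule,
                               ifelse(is.na(viol$node_id), "<task>",
                                      viol$node_id),
                               viol$message), collapse = "\n")),
         call. = FALSE)
  }
  task
}

#' Write a query task to XML
#'
#' Inverse of [read_task()]: reading the written document reproduces the
#' task (node set, edges, criteria, flags, priorities). Criterion text is
#' emitted verbatim when the criterion was parsed from text, canonical
#' rendering otherwise.
#'
#' @param task a valid [query_task()]
#' @param path output path (conventionally `*.fbdqm.xml`); `NULL` returns
#'   the `xml2::xml_document` instead of writing
#' @return `path` (or the document), invisibly
#' @export
write_task <- function(task, path = NULL) {
  doc <- xml2::xml_new_root("queryTask", version = .TASK_DIALECT_VERSION,
                            name = task$name)
  for (n in task$nodes) {
    nd <- xml2::xml_add_child(doc, "node", id = n$id, name = n$name,
                              class = n$node_class,
                              selected = .xml_bool(n$selected),
                              mutuallyExclusive = .xml_bool(n$mutually_exclusive))
    for (cr in n$criteria) {
      src <- attr(cr, "source")
      if (is.null(src)) src <- render_criterion(cr)
      xml2::xml_add_child(nd, "criterion", src)
    }
    for (p in n$child_priorities) xml2::xml_add_child(nd, "priority", p)
  }
  for (k in seq_len(nrow(task$edges))) {
    xml2::xml_add_child(doc, "edge", from = task$edges$from[k],
                        to = task$edges$to[k])
  }
  if (is.null(path)) return(invisible(doc))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Structural equality of two query tasks
#'
#' Compares names, node sets (id, class, display name, selection and
#' mutually-exclusive flags, child priorities), edges, and criteria ASTs.
#'
#' @param a,b [query_task()] objects
#' @return `TRUE` or `FALSE`
#' @export
task_identical <- function(a, b) {
  if (!identical(a$name, b$name)) return(FALSE)
  if (!identical(task_node_ids(a), task_node_ids(b))) return(FALSE)
  if (!identical(a$edges$from, b$edges$from) ||
      !identical(a$edges$to, b$edges$to)) return(FALSE)
  for (id in task_node_ids(a)) {
    na <- a$nodes[[id]]; nb <- b$nodes[[id]]
    if (!identical(na$node_class, nb$node_class) ||
        !identical(na$name, nb$name) ||
        !identical(na$selected, nb$selected) ||
        !identical(na$mutually_exclusive, nb$mutually_exclusive) ||
        !identical(na$child_priorities, nb$child_priorities) ||
        length(na$criteria) != length(nb$criteria)) return(FALSE)
    if (length(na$criteria) &&
        !all(mapply(criterion_equal, na$criteria, nb$criteria))) return(FALSE)
  }
  TRUE
}
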