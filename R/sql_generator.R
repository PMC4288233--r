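#' @title Criterion-to-SQL translation
#'
#' @description
#' A criterion is translated into a *query plan*: one simple SQL subquery
#' per atom (each a `SELECT Personal_ID FROM <table> WHERE ...` against a
#' single table), plus a combination tree evaluated in the host over the
#' returned patient-id sets — intersection for `and`, union for `or`, a
#' count threshold for `at least k of`. Splitting complex criteria into
#' simple SQL units plus host-side verification is what keeps the SQL
#' dialect down to ANSI `SELECT`/`WHERE`/`BETWEEN` and gives the engine
#' its separate "SQL operations" and "criteria verification" phases.
#' @name sql_generator
NULL

.PATIENT_ID_COLUMN <- "Personal_ID"

.check_identifier <- function(x, what) {
  if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", x)) {
    stop(sprintf("invalid SQL identifier for %s: '%s'", what, x), call. = FALSE)
  }
  x
}

.sql_quote_text <- function(v) {
  sprintf("'%s'", gsub("'", "''", v))
}

.condition_sql <- function(cond) {
  switch(cond$kind,
    eq_text = sprintf("%s=%s", cond$column, .sql_quote_text(cond$value)),
    eq_num  = sprintf("%s=%s", cond$column, fmt_num(cond$value)),
    between = sprintf("%s between %s and %s",
                      cond$column, cond$low_text, cond$high_text)
  )
}

.make_sql_atom <- function(atom, entry) {
  .check_identifier(entry$table, "table")
  .check_identifier(entry$value_column, "value column")
  conds <- list()
  if (atom$op == "within") {
    if (entry$value_type != "number") {
      stop(sprintf("translation error: numeric range on text-typed item '%s'",
                   atom$item), call. = FALSE)
    }
    conds[[1L]] <- list(kind = "between", column = entry$value_column,
                        low = atom$low, high = atom$high,
                        low_text = atom$low_text, high_text = atom$high_text)
  } else if (atom$op == "str_eq") {
    if (entry$value_type != "text") {
      stop(sprintf("translation error: string equality on number-typed item '%s'",
                   atom$item), call. = FALSE)
    }
    conds[[1L]] <- list(kind = "eq_text", column = entry$value_column,
                        value = atom$value)
  } else if (atom$op == "num_eq") {
    if (entry$value_type != "number") {
      stop(sprintf("translation error: numeric equality on text-typed item '%s'",
                   atom$item), call. = FALSE)
    }
    conds[[1L]] <- list(kind = "eq_num", column = entry$value_column,
                        value = atom$value)
  } else {                                         # code_eq
    if (entry$value_type == "number") {
      v <- suppressWarnings(as.numeric(atom$value))
      if (is.na(v)) {
        stop(sprintf("translation error: non-numeric value '%s' for number-typed item '%s'",
                     atom$value, atom$item), call. = FALSE)
      }
      conds[[1L]] <- list(kind = "eq_num", column = entry$value_column,
                          value = v)
    } else {
      conds[[1L]] <- list(kind = "eq_text", column = entry$value_column,
                          value = as.character(atom$value))
    }
  }
  if (entry$mode == "indirect") {
    .check_identifier(entry$discriminator_column, "discriminator column")
    conds[[length(conds) + 1L]] <- list(kind = "eq_text",
                                        column = entry$discriminator_column,
                                        value = entry$discriminator_value)
  }
  sql <- sprintf("select %s from %s where %s", .PATIENT_ID_COLUMN, entry$table,
                 paste(vapply(conds, .condition_sql, character(1)),
                       collapse = " and "))
  structure(list(table = entry$table, conditions = conds, sql = sql,
                 source_atom = atom),
            class = "sql_atom")
}

#' @export
print.sql_atom <- function(x, ...) {
  cat("<sql_atom> ", x$sql, "\n", sep = "")
  invisible(x)
}

#' Translate a criterion into a query plan
#'
#' Each atom becomes one SQL subquery selecting patient identifiers:
#' a directly mapped item constrains its value column only
#' (`... where ICD9_Code='155.0'`), an indirectly mapped item additionally
#' constrains the discriminator column
#' (`... where Result_Number between 15 and 40 and Item_Name='ICG'`).
#' `and`/`or`/`at least` never reach the SQL layer; they live in the
#' plan's combiner and are verified in the host.
#'
#' @param criterion a `criterion` (see [parse_criterion()])
#' @param mapping a [mapping_table()] resolving every item in the criterion
#' @return an object of class `query_plan` with elements `atoms` (list of
#'   `sql_atom`) and `combiner` (tree with leaves indexing into `atoms`)
#' @export
#' @examples
#' m <- liver_mapping()
#' translate_criterion(parse_criterion("ICD9=155.0"), m)
translate_criterion <- function(criterion, mapping) {
  atoms <- list()
  build <- function(x) {
    if (inherits(x, "criterion_atom")) {
      entry <- resolve_item(x$item, mapping)
      atoms[[length(atoms) + 1L]] <<- .make_sql_atom(x, entry)
      return(list(kind = "atom", index = length(atoms)))
    }
    if (inherits(x, "criterion_at_least")) {
      leaves <- lapply(x$atoms, build)
      return(list(kind = "at_least", k = x$k, parts = leaves))
    }
    kind <- if (inherits(x, "criterion_and")) "and" else "or"
    list(kind = kind, parts = lapply(x$parts, build))
  }
  combiner <- build(criterion)
  structure(list(atoms = atoms, combiner = combiner,
                 source_criterion = criterion),
            class = "query_plan")
}

#' @export
print.query_plan <- function(x, ...) {
  cat(sprintf("<query_plan> %d SQL subqueries for: %s\n",
              length(x$atoms), render_criterion(x$source_criterion)))
  for (i in seq_along(x$atoms)) cat(sprintf("  %d. %s\n", i, x$atoms[[i]]$sql))
  invisible(x)
}

#' Display SQL of a plan's subqueries
#'
#' @param plan a `query_plan`
#' @return character vector, one rendered SQL statement per atom
#' @export
plan_sql <- function(plan) {
  vapply(plan$atoms, `[[`, character(1), "sql")
}

#' Translate every selected node of a task
#'
#' @param task a [query_task()]
#' @param mapping a [mapping_table()]
#' @param selection optional character vector of node ids to translate
#'   (default: all nodes)
#' @return named list (by node id) of lists of `query_plan`, one plan per
#'   criterion in the node
#' @export
translate_task <- function(task, mapping, selection = task_node_ids(task)) {
  plans <- lapply(task$nodes[intersect(task_node_ids(task), selection)],
                  function(n) lapply(n$criteria, translate_criterion, mapping))
  plans
}

#' Count translated SQL subqueries
#'
#' The total number of simplified SQL criteria a set of plans will execute
#' — one per criterion atom; host-combined forms add none.
#'
#' @param plans a `query_plan`, a list of plans, or nested lists of plans
#'   (as returned by [translate_task()])
#' @return integer total
#' @export
count_sql_criteria <- function(plans) {
  if (inherits(plans, "query_plan")) return(length(plans$atoms))
  if (!is.list(plans)) stop("expected query plans", call. = FALSE)
  if (!length(plans)) return(0L)
  sum(vapply(plans, count_sql_criteria, integer(1)))
}
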