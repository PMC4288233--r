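#' @title Liver-cancer fixture tasks and mapping
#'
#' @description
#' The three query tasks the package ships for the liver-cancer cohort,
#' plus their mapping table:
#' \describe{
#'   \item{degree of liver damage}{ICD-9 155.0 inclusion node, a
#'     criterion-free degree decision node, and three degree children
#'     (A/B/C), each an at-least-2-of-5 criterion over the five
#'     liver-function items in that grade's ranges — 4 criteria total,
#'     translating to 16 SQL subqueries}
#'   \item{its mutually-exclusive variant}{same flowchart with the
#'     decision node's mutually-exclusive setting on, priorities
#'     C > B > A (the most severe grade wins)}
#'   \item{treatments for liver cancer}{ICD node, a branch node, and five
#'     treatment children with one equality criterion each — 6 criteria,
#'     6 SQL subqueries}
#' }
#' XML copies of the three tasks and JSON/CSV copies of the mapping ship
#' under `inst/extdata/`.
#' @name fixtures
NULL

# query-side item name for each stored laboratory item
.LAB_ITEM_KEYS <- c("Ascites" = "Ascites", "ICG" = "ICG",
                    "Prothrombin activity" = "Prothrombin_Activity",
                    "Serum albumin" = "Serum_Albumin",
                    "Serum bilirubin" = "Serum_Bilirubin")

#' Mapping table for the liver fixtures
#'
#' Seven entries: `ICD9` direct to `Diagnosis.ICD9_Code`; the five
#' laboratory items indirect through `Laboratory.Item_Name` (ascites on
#' the string result column, the four numeric items on the number
#' column); `Treatment` direct to `Treatment.Treatment_Name`.
#'
#' @return a [mapping_table()]
#' @export
liver_mapping <- function() {
  lab <- function(item, label, type, col) {
    mapping_entry(item, "indirect", "Laboratory", col, type,
                  discriminator_column = "Item_Name",
                  discriminator_value = label)
  }
  mapping_table(list(
    mapping_entry("ICD9", "direct", "Diagnosis", "ICD9_Code", "text"),
    lab("Ascites", "Ascites", "text", "Result_String"),
    lab("ICG", "ICG", "number", "Result_Number"),
    lab("Prothrombin_Activity", "Prothrombin activity", "number",
        "Result_Number"),
    lab("Serum_Albumin", "Serum albumin", "number", "Result_Number"),
    lab("Serum_Bilirubin", "Serum bilirubin", "number", "Result_Number"),
    mapping_entry("Treatment", "direct", "Treatment", "Treatment_Name",
                  "text")
  ))
}

#' At-least criterion text for one damage grade
#'
#' Builds `at least k of (...)` over the five liver-function items with
#' that grade's value ranges. The grade-B text reproduces the classical
#' mid ranges verbatim (ascites controllable, ICG 15–40, prothrombin
#' 50–80, albumin 3.0–3.5, bilirubin 2.0–3.0).
#'
#' @param grade `"A"`, `"B"` or `"C"`
#' @param partitions per-item partitions
#'   (default [default_liver_partitions()])
#' @param k threshold (default 2; with five items and three grades every
#'   patient reaches 2 in some grade)
#' @return criterion string
#' @export
degree_criterion_text <- function(grade,
                                  partitions = default_liver_partitions(),
                                  k = 2) {
  if (identical(grade, "B") &&
      identical(partitions, default_liver_partitions()) && k == 2) {
    # canonical spelling, decimals as conventionally printed
    return(paste0(
      'at least 2 of (Ascites=="Controllable", ICG is within 15 to 40, ',
      "Prothrombin_Activity is within 50 to 80, ",
      "Serum_Albumin is within 3.0 to 3.5, ",
      "Serum_Bilirubin is within 2.0 to 3.0)"))
  }
  parts <- vapply(names(partitions), function(label) {
    p <- partitions[[label]]
    key <- .LAB_ITEM_KEYS[[label]]
    if (p$kind == "text") {
      sprintf('%s=="%s"', key, p[[grade]])
    } else {
      sprintf("%s is within %s to %s", key, fmt_num(p[[grade]][1]),
              fmt_num(p[[grade]][2]))
    }
  }, character(1))
  sprintf("at least %d of (%s)", k, paste(parts, collapse = ", "))
}

#' The degree-of-liver-damage fixture task
#'
#' @param mutually_exclusive apply the mutually-exclusive setting on the
#'   degree decision node, with priorities C > B > A
#' @param partitions per-item grade partitions
#' @return a [query_task()] with 5 nodes and 4 edges
#' @export
#' @examples
#' liver_degree_task()
liver_degree_task <- function(mutually_exclusive = FALSE,
                              partitions = default_liver_partitions()) {
  name <- if (mutually_exclusive) {
    "degree of liver damage (mutually exclusive)"
  } else "degree of liver damage"
  nodes <- list(
    flowchart_node("icd", "patient_state", name = "Liver cancer diagnosis",
                   criteria = list("ICD9=155.0")),
    flowchart_node("degree_decision", "decision", name = "degree decision",
                   mutually_exclusive = mutually_exclusive,
                   child_priorities = if (mutually_exclusive) {
                     c("degree_c", "degree_b", "degree_a")
                   } else character()),
    flowchart_node("degree_a", "action", name = "Degree A",
                   criteria = list(degree_criterion_text("A", partitions))),
    flowchart_node("degree_b", "action", name = "Degree B",
                   criteria = list(degree_criterion_text("B", partitions))),
    flowchart_node("degree_c", "action", name = "Degree C",
                   criteria = list(degree_criterion_text("C", partitions)))
  )
  query_task(name, nodes, edges = list(
    c("icd", "degree_decision"),
    c("degree_decision", "degree_a"),
    c("degree_decision", "degree_b"),
    c("degree_decision", "degree_c")))
}

#' The treatments-for-liver-cancer fixture task
#'
#' @return a [query_task()] with 7 nodes and 6 edges: the ICD inclusion
#'   node, a branch node, and one node per treatment
#' @export
liver_treatment_task <- function() {
  trts <- liver_treatments()
  ids <- c("lt", "tace", "rfa", "ai", "sr")
  nodes <- c(
    list(flowchart_node("icd", "patient_state",
                        name = "Liver cancer diagnosis",
                        criteria = list("ICD9=155.0")),
         flowchart_node("treatment_branch", "branch",
                        name = "treatment branch")),
    mapply(function(id, trt) {
      flowchart_node(id, "action", name = trt,
                     criteria = list(sprintf('Treatment=="%s"', trt)))
    }, ids, trts, SIMPLIFY = FALSE)
  )
  edges <- c(list(c("icd", "treatment_branch")),
             lapply(ids, function(id) c("treatment_branch", id)))
  query_task("treatments for liver cancer", nodes, edges)
}

#' Paths of the shipped fixture files
#'
#' @return named character vector of the XML task files, the mapping
#'   files and the task-dialect schema shipped under `extdata/`
#' @export
fixture_paths <- function() {
  f <- function(x) system.file("extdata", x, package = "fbdqm")
  c(degree_task = f("degree_of_liver_damage.fbdqm.xml"),
    degree_task_me = f("degree_of_liver_damage_me.fbdqm.xml"),
    treatment_task = f("treatments_for_liver_cancer.fbdqm.xml"),
    mapping_json = f("liver_mapping.json"),
    mapping_csv = f("liver_mapping.csv"),
    task_schema = f("fbdqm-task.xsd"))
}
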