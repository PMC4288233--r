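#' @title Result representation
#'
#' @description
#' Machine-readable renderings of a `query_report`: per-parent child
#' distributions (count and two-decimal percentage per child), the
#' three-phase timing table, JSON export/import of whole reports,
#' per-node patient-list CSVs and optional pie charts.
#' @name reporting
NULL

# round-half-up to `digits` decimals (the conventional reading of
# percentages like 12.90); R's round() is half-even
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Distribution of a parent's patients over its children
#'
#' Percentage is `100 * count / PLS(parent)`, rounded half-up to two
#' decimals; over mutually-exclusive children (a partition of the parent)
#' the percentages sum to 100 up to rounding. A parent with an empty
#' patient list yields all-zero percentages and sets the
#' `zero_denominator` attribute.
#'
#' @param parent a `node_result`
#' @param children list of `node_result`s, in child document order
#' @return data frame with columns `child_id`, `count`, `percentage`
#'   (numeric) and `label` (formatted like `"129/1000 (12.90%)"`)
#' @export
#' @examples
#' p <- fbdqm:::node_result("p", sprintf("x%04d", 1:1000), TRUE)
#' a <- fbdqm:::node_result("a", sprintf("x%04d", 1:129), TRUE)
#' distribution(p, list(a))
distribution <- function(parent, children) {
  denom <- parent$size
  counts <- vapply(children, `[[`, integer(1), "size")
  ids <- vapply(children, `[[`, character(1), "node_id")
  if (denom > 0) {
    pct <- round_half_up(100 * counts / denom)
  } else {
    pct <- rep(0, length(counts))
  }
  out <- data.frame(child_id = ids, count = counts, percentage = pct,
                    label = sprintf("%d/%d (%s%%)", counts, denom,
                                    sprintf("%.2f", pct)),
                    stringsAsFactors = FALSE)
  attr(out, "zero_denominator") <- denom == 0
  out
}

#' Three-phase timing table of a report
#'
#' Rows `SQL operations`, `Criteria verification`, `Other tasks` and
#' `Total`, each with seconds and percentage of total. An all-zero run
#' reports zero percentages and sets the `zero_total` attribute.
#'
#' @param report a `query_report`
#' @return data frame with columns `phase`, `seconds`, `percentage`
#' @export
phase_report <- function(report) {
  pt <- report$phase_timing
  secs <- c(pt$sql_operations, pt$criteria_verification, pt$other, pt$total)
  if (pt$total > 0) {
    pct <- round_half_up(100 * secs / pt$total)
  } else {
    pct <- rep(0, 4L)
  }
  out <- data.frame(
    phase = c("SQL operations", "Criteria verification", "Other tasks",
              "Total"),
    seconds = secs, percentage = pct, stringsAsFactors = FALSE)
  attr(out, "zero_total") <- pt$total == 0
  out
}

.REPORT_SCHEMA_VERSION <- "1.0"

#' Export a query report as JSON
#'
#' The JSON document carries per-node counts and patient lists, the child
#' distributions with their formatted percentages, and the phase timings;
#' [import_report()] reads it back into an equal in-memory report.
#'
#' @param report a `query_report`
#' @param path output `.json` path
#' @return `path`, invisibly
#' @export
export_report <- function(report, path) {
  doc <- list(
    schema_version = .REPORT_SCHEMA_VERSION,
    task = report$task,
    selection = as.list(report$selection),
    results = lapply(unname(report$results), function(r) list(
      node_id = r$node_id, executed = r$executed, size = r$size,
      patient_list = as.list(r$patient_list))),
    distributions = lapply(report$distributions, function(d)
      lapply(seq_len(nrow(d)), function(i) list(
        child_id = d$child_id[i], count = d$count[i],
        percentage = sprintf("%.2f", d$percentage[i])))),
    phase_timing = report$phase_timing
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Import a query report from JSON
#'
#' @param path a file written by [export_report()]
#' @return a `query_report`
#' @export
import_report <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$schema_version, .REPORT_SCHEMA_VERSION)) {
    stop(sprintf("unsupported report schema version '%s'",
                 doc$schema_version), call. = FALSE)
  }
  results <- lapply(doc$results, function(r)
    node_result(r$node_id,
                as.character(unlist(r$patient_list)),
                isTRUE(r$executed)))
  names(results) <- vapply(results, `[[`, character(1), "node_id")
  distributions <- lapply(doc$distributions, function(d) {
    out <- data.frame(
      child_id = vapply(d, `[[`, character(1), "child_id"),
      count = vapply(d, function(e) as.integer(e$count), integer(1)),
      percentage = vapply(d, function(e) as.numeric(e$percentage), numeric(1)),
      stringsAsFactors = FALSE)
    out$label <- sprintf("%d/%d (%s%%)", out$count, NA_integer_,
                         sprintf("%.2f", out$percentage))
    out
  })
  # rebuild labels with the parent denominators
  for (pid in names(distributions)) {
    denom <- results[[pid]]$size
    d <- distributions[[pid]]
    d$label <- sprintf("%d/%d (%s%%)", d$count, denom,
                       sprintf("%.2f", d$percentage))
    attr(d, "zero_denominator") <- denom == 0
    distributions[[pid]] <- d
  }
  structure(list(
    task = doc$task,
    selection = as.character(unlist(doc$selection)),
    results = results,
    distributions = distributions,
    phase_timing = lapply(doc$phase_timing, as.numeric)
  ), class = "query_report")
}

#' Write per-node patient lists as CSV
#'
#' One `<node_id>.csv` per node with a single `Personal_ID` column; a
#' node with an empty list yields a header-only file.
#'
#' @param report a `query_report`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_patient_lists <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (r in report$results) {
    utils::write.csv(data.frame(Personal_ID = r$patient_list,
                                stringsAsFactors = FALSE),
                     file.path(dir, paste0(r$node_id, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Write pie charts of child distributions
#'
#' One PNG per decision/branch parent in the report's distributions.
#'
#' @param report a `query_report`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_distribution_charts <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (pid in names(report$distributions)) {
    d <- report$distributions[[pid]]
    if (!sum(d$count)) next
    grDevices::png(file.path(dir, paste0(pid, ".png")), width = 640,
                   height = 480)
    graphics::pie(d$count,
                  labels = sprintf("%s %s", d$child_id, d$label),
                  main = sprintf("%s: child distribution", pid))
    grDevices::dev.off()
  }
  invisible(dir)
}
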