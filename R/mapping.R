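#' @title Knowledge-to-data mapping
#'
#' @description
#' Query-task data items are abstract names (`ICD9`, `Serum_Albumin`);
#' the mapping table bridges each one to a repository column. Two modes,
#' following the direct/indirect distinction of knowledge-data ontological
#' mapping (KDOM) as used here:
#' \describe{
#'   \item{direct}{the item binds to the values of one column
#'     (e.g. `ICD9` to `Diagnosis.ICD9_Code`)}
#'   \item{indirect}{the item binds through a value column plus a
#'     discriminator column naming the item (e.g. `Serum_Albumin` to
#'     `Laboratory.Result_Number` where `Item_Name = 'Serum albumin'`)}
#' }
#' Mapping is strictly one-item-to-one-item: a duplicate item key is a
#' load-time error, and resolving an unmapped item fails loudly rather
#' than returning an empty result.
#' @name mapping
NULL

#' Construct one mapping entry
#'
#' @param item data-item name used in criteria (unique key)
#' @param mode `"direct"` or `"indirect"`
#' @param table repository table name
#' @param value_column column holding the comparable value
#' @param value_type `"text"` or `"number"`
#' @param discriminator_column,discriminator_value column naming the item
#'   and the stored item label (indirect mode only)
#' @return an object of class `mapping_entry`
#' @export
mapping_entry <- function(item, mode, table, value_column, value_type,
                          discriminator_column = NULL,
                          discriminator_value = NULL) {
  mode <- match.arg(mode, c("direct", "indirect"))
  value_type <- match.arg(value_type, c("text", "number"))
  stopifnot(is.character(item), nzchar(item),
            is.character(table), nzchar(table),
            is.character(value_column), nzchar(value_column))
  if (mode == "direct") {
    if (!is.null(discriminator_column) || !is.null(discriminator_value)) {
      stop("direct mapping must not carry discriminator fields", call. = FALSE)
    }
  } else {
    if (is.null(discriminator_column) || is.null(discriminator_value) ||
        !nzchar(discriminator_column) || !nzchar(discriminator_value)) {
      stop("indirect mapping requires discriminator_column and discriminator_value",
           call. = FALSE)
    }
  }
  structure(list(item = item, mode = mode, table = table,
                 value_column = value_column, value_type = value_type,
                 discriminator_column = discriminator_column,
                 discriminator_value = discriminator_value),
            class = "mapping_entry")
}

#' Construct a mapping table from entries
#'
#' @param entries list of [mapping_entry()] objects
#' @return an object of class `mapping_table`
#' @export
mapping_table <- function(entries = list()) {
  items <- vapply(entries, `[[`, character(1), "item")
  if (anyDuplicated(items)) {
    stop(sprintf("one-item-to-one-item violated: duplicate mapping for item '%s'",
                 items[duplicated(items)][1L]), call. = FALSE)
  }
  names(entries) <- items
  structure(list(entries = entries), class = "mapping_table")
}

#' @export
print.mapping_table <- function(x, ...) {
  cat(sprintf("<mapping_table> %d items\n", length(x$entries)))
  for (e in x$entries) {
    tgt <- sprintf("%s.%s", e$table, e$value_column)
    if (e$mode == "indirect") {
      tgt <- sprintf("%s where %s='%s'", tgt, e$discriminator_column,
                     e$discriminator_value)
    }
    cat(sprintf("  %s (%s, %s) -> %s\n", e$item, e$mode, e$value_type, tgt))
  }
  invisible(x)
}

#' Resolve a data item to its mapping entry
#'
#' @param item data-item name
#' @param mapping a [mapping_table()]
#' @return the unique [mapping_entry()] for `item`
#' @export
resolve_item <- function(item, mapping) {
  e <- mapping$entries[[item]]
  if (is.null(e)) {
    stop(sprintf("mapping not predefined for item '%s'", item), call. = FALSE)
  }
  e
}

.MAPPING_FIELDS <- c("item", "mode", "table", "value_column", "value_type",
                     "discriminator_column", "discriminator_value")

#' Read a mapping table from JSON or CSV
#'
#' JSON is the canonical format: an array of objects with fields `item`,
#' `mode`, `table`, `value_column`, `value_type` and (indirect mode only)
#' `discriminator_column`, `discriminator_value`. CSV uses the same field
#' names as header; empty cells stand for absent discriminator fields.
#' The format is inferred from the file extension.
#'
#' @param path path to a `.json` or `.csv` mapping file
#' @return a [mapping_table()]
#' @export
load_mapping <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    missing <- setdiff(setdiff(.MAPPING_FIELDS,
                               c("discriminator_column", "discriminator_value")),
                       names(df))
    if (length(missing)) {
      stop(sprintf("mapping CSV missing required column(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    recs <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  } else {
    stop("mapping file must be .json or .csv", call. = FALSE)
  }
  entries <- lapply(recs, function(r) {
    req <- c("item", "mode", "table", "value_column", "value_type")
    miss <- req[!vapply(req, function(f)
      !is.null(r[[f]]) && nzchar(as.character(r[[f]])), logical(1))]
    if (length(miss)) {
      stop(sprintf("mapping record missing required field(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    dc <- r$discriminator_column
    dv <- r$discriminator_value
    if (!is.null(dc) && (is.na(dc) || !nzchar(dc))) dc <- NULL
    if (!is.null(dv) && (is.na(dv) || !nzchar(dv))) dv <- NULL
    mapping_entry(r$item, r$mode, r$table, r$value_column, r$value_type,
                  discriminator_column = dc, discriminator_value = dv)
  })
  mapping_table(entries)
}

#' Write a mapping table to JSON or CSV
#'
#' Inverse of [load_mapping()]: `load_mapping(write_mapping(m, path))`
#' reproduces `m`.
#'
#' @param mapping a [mapping_table()]
#' @param path output path ending in `.json` or `.csv`
#' @return `path`, invisibly
#' @export
write_mapping <- function(mapping, path) {
  recs <- lapply(mapping$entries, function(e) {
    r <- e[.MAPPING_FIELDS]
    r[vapply(r, is.null, logical(1))] <- NULL
    r
  })
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unname(recs), path, auto_unbox = TRUE, pretty = TRUE)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- do.call(rbind, lapply(unname(recs), function(r) {
      row <- lapply(.MAPPING_FIELDS, function(f)
        if (is.null(r[[f]])) "" else as.character(r[[f]]))
      names(row) <- .MAPPING_FIELDS
      as.data.frame(row, stringsAsFactors = FALSE)
    }))
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    stop("mapping file must be .json or .csv", call. = FALSE)
  }
  invisible(path)
}
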