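#' @title Synthetic liver-cancer repository
#'
#' @description
#' A seeded generator for the clinical repository the fixture query tasks
#' run against: a cohort of liver-cancer patients, each holding one
#' diagnosis row (ICD-9 155.0), one laboratory result for each of the five
#' liver-function items used by the damage grading (ascites, ICG retention,
#' prothrombin activity, serum albumin, serum bilirubin), and exactly one
#' of five treatments. Each laboratory item's value space is partitioned
#' into three damage-grade ranges (A/B/C); a patient's grade for an item is
#' drawn independently per item (uniform over the three grades by default)
#' and the value uniformly within that grade's range. With five items and
#' three grades, the pigeonhole principle guarantees every patient has at
#' least two items in some common grade, so the at-least-2-of-5 degree
#' criteria always cover the full cohort.
#' @name synthetic_data
NULL

.LAB_ITEMS <- c("Ascites", "ICG", "Prothrombin activity", "Serum albumin",
                "Serum bilirubin")

.TREATMENTS <- c("Liver transplantation",
                 "Transarterial embolization and chemoembolization",
                 "Radiofrequency ablation",
                 "Alcohol injection",
                 "Surgical resection")

#' Default damage-grade partitions for the five liver-function items
#'
#' Grade-B ranges are the classical mid ranges of the liver-damage grading
#' (ICG 15–40 %, prothrombin activity 50–80 %, serum albumin 3.0–3.5 g/dL,
#' serum bilirubin 2.0–3.0 mg/dL, ascites controllable), inclusive at both
#' ends. Grade A is the favourable side (no ascites, bilirubin below 2.0,
#' albumin above 3.5, ICG below 15, prothrombin above 80), grade C the
#' unfavourable extreme. Numeric outer bounds are finite so that uniform
#' sampling is well defined; together the three ranges partition each
#' item's value space.
#'
#' @return named list (by stored laboratory item name) of per-item
#'   partitions; numeric items carry `A`/`B`/`C` ranges `c(low, high)`
#'   (grade B closed, A/C open at the shared boundary), the ascites item
#'   carries the three labels
#' @export
default_liver_partitions <- function() {
  list(
    "Ascites" = list(kind = "text", A = "None", B = "Controllable",
                     C = "Uncontrollable"),
    "ICG" = list(kind = "number", A = c(0, 15), B = c(15, 40), C = c(40, 100),
                 direction = "low_good"),
    "Prothrombin activity" = list(kind = "number", A = c(80, 100),
                                  B = c(50, 80), C = c(0, 50),
                                  direction = "high_good"),
    "Serum albumin" = list(kind = "number", A = c(3.5, 6.0), B = c(3.0, 3.5),
                           C = c(1.0, 3.0), direction = "high_good"),
    "Serum bilirubin" = list(kind = "number", A = c(0.1, 2.0), B = c(2.0, 3.0),
                             C = c(3.0, 30.0), direction = "low_good")
  )
}

#' Classify a laboratory value into a damage grade
#'
#' The grade-B range is inclusive at both ends (matching the inclusive
#' `is within` semantics of the criteria language); a value on a shared
#' boundary therefore classifies as B.
#'
#' @param partitions per-item partitions, see [default_liver_partitions()]
#' @param item stored laboratory item name (e.g. `"ICG"`)
#' @param value numeric value, or the label for the ascites item
#' @return `"A"`, `"B"` or `"C"`
#' @export
grade_of_value <- function(partitions, item, value) {
  p <- partitions[[item]]
  if (is.null(p)) stop(sprintf("no partition for item '%s'", item), call. = FALSE)
  if (p$kind == "text") {
    g <- c("A", "B", "C")[match(value, c(p$A, p$B, p$C))]
    if (is.na(g)) stop(sprintf("unknown label '%s' for item '%s'", value, item),
                       call. = FALSE)
    return(g)
  }
  value <- as.numeric(value)
  if (value >= p$B[1] && value <= p$B[2]) return("B")
  if (value >= p$A[1] && value <= p$A[2]) return("A")
  "C"
}

#' Generator configuration
#'
#' @param n_patients number of patients to generate
#' @param seed integer seed; identical configurations generate identical
#'   repositories, row for row
#' @param grade_probabilities probability over grades A/B/C used
#'   independently for every item (default uniform)
#' @param treatment_probabilities probability over the five treatments
#'   (default uniform)
#' @param partitions per-item grade partitions
#'   (default [default_liver_partitions()])
#' @param icd_code diagnosis code given to every patient
#' @param dropout probability that any single laboratory row is omitted
#'   (missing-data knob; default 0 = complete data)
#' @return an object of class `generator_config`
#' @export
generator_config <- function(n_patients, seed = 1L,
                             grade_probabilities = c(A = 1, B = 1, C = 1) / 3,
                             treatment_probabilities = NULL,
                             partitions = default_liver_partitions(),
                             icd_code = "155.0", dropout = 0) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 1L) {
    stop("n_patients must be a positive integer", call. = FALSE)
  }
  if (length(grade_probabilities) != 3L || any(grade_probabilities < 0) ||
      abs(sum(grade_probabilities) - 1) > 1e-8) {
    stop("grade_probabilities must be 3 non-negative numbers summing to 1",
         call. = FALSE)
  }
  if (is.null(treatment_probabilities)) {
    treatment_probabilities <- stats::setNames(rep(1 / 5, 5), .TREATMENTS)
  }
  if (any(treatment_probabilities < 0) ||
      abs(sum(treatment_probabilities) - 1) > 1e-8) {
    stop("treatment_probabilities must be non-negative and sum to 1",
         call. = FALSE)
  }
  for (nm in names(partitions)) {
    p <- partitions[[nm]]
    if (p$kind == "number") {
      for (g in c("A", "B", "C")) {
        if (length(p[[g]]) != 2L || p[[g]][1] > p[[g]][2]) {
          stop(sprintf("invalid %s range for item '%s'", g, nm), call. = FALSE)
        }
      }
    }
  }
  if (dropout < 0 || dropout >= 1) {
    stop("dropout must be in [0, 1)", call. = FALSE)
  }
  structure(list(n_patients = n_patients, seed = as.integer(seed),
                 grade_probabilities = grade_probabilities,
                 treatment_probabilities = treatment_probabilities,
                 partitions = partitions, icd_code = icd_code,
                 dropout = dropout),
            class = "generator_config")
}

#' Generate a synthetic clinical repository
#'
#' Three tables as plain data frames:
#' `Diagnosis(Personal_ID, ICD9_Code)`,
#' `Laboratory(Personal_ID, Item_Name, Result_String, Result_Number)`
#' (exactly one of the two result columns populated per row) and
#' `Treatment(Personal_ID, Treatment_Name)`. The generator is fully
#' reproducible from the configuration's seed and restores the caller's
#' RNG state.
#'
#' @param cfg a [generator_config()]
#' @return an object of class `clinical_repository`: a list of the three
#'   data frames
#' @export
#' @examples
#' repo <- generate_repository(generator_config(10, seed = 42))
#' nrow(repo$Laboratory)   # 10 patients x 5 items = 50
generate_repository <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)

  n <- cfg$n_patients
  ids <- sprintf("P%06d", seq_len(n))
  diagnosis <- data.frame(Personal_ID = ids, ICD9_Code = cfg$icd_code,
                          stringsAsFactors = FALSE)
  lab_list <- vector("list", length(cfg$partitions))
  for (j in seq_along(cfg$partitions)) {
    item <- names(cfg$partitions)[j]
    p <- cfg$partitions[[item]]
    grades <- sample(c("A", "B", "C"), n, replace = TRUE,
                     prob = cfg$grade_probabilities)
    if (p$kind == "text") {
      lab_list[[j]] <- data.frame(
        Personal_ID = ids, Item_Name = item,
        Result_String = unlist(p[c("A", "B", "C")])[match(grades, c("A", "B", "C"))],
        Result_Number = NA_real_, stringsAsFactors = FALSE)
    } else {
      vals <- numeric(n)
      for (g in c("A", "B", "C")) {
        idx <- which(grades == g)
        if (length(idx)) vals[idx] <- stats::runif(length(idx),
                                                   p[[g]][1], p[[g]][2])
      }
      lab_list[[j]] <- data.frame(
        Personal_ID = ids, Item_Name = item, Result_String = NA_character_,
        Result_Number = vals, stringsAsFactors = FALSE)
    }
  }
  laboratory <- do.call(rbind, lab_list)
  laboratory <- laboratory[order(laboratory$Personal_ID,
                                 match(laboratory$Item_Name,
                                       names(cfg$partitions))), ]
  rownames(laboratory) <- NULL
  if (cfg$dropout > 0) {
    keep <- stats::runif(nrow(laboratory)) >= cfg$dropout
    laboratory <- laboratory[keep, , drop = FALSE]
    rownames(laboratory) <- NULL
  }
  treatment <- data.frame(
    Personal_ID = ids,
    Treatment_Name = sample(names(cfg$treatment_probabilities), n,
                            replace = TRUE,
                            prob = cfg$treatment_probabilities),
    stringsAsFactors = FALSE)
  structure(list(Diagnosis = diagnosis, Laboratory = laboratory,
                 Treatment = treatment),
            class = "clinical_repository")
}

#' @export
print.clinical_repository <- function(x, ...) {
  cat(sprintf("<clinical_repository> %d patients; %d diagnosis, %d laboratory, %d treatment rows\n",
              length(repository_patients(x)), nrow(x$Diagnosis),
              nrow(x$Laboratory), nrow(x$Treatment)))
  invisible(x)
}

#' All distinct patient ids across repository tables
#'
#' @param repo a `clinical_repository`
#' @return sorted character vector of patient ids
#' @export
repository_patients <- function(repo) {
  sort(unique(c(repo$Diagnosis$Personal_ID, repo$Laboratory$Personal_ID,
                repo$Treatment$Personal_ID)))
}

#' Write a repository to a single-file SQLite database
#'
#' @param repo a `clinical_repository`
#' @param path database file path (`":memory:"` is not allowed here; use
#'   [repository_connect()] with an existing connection instead)
#' @return `path`, invisibly
#' @export
write_repository_db <- function(repo, path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  load_repository_into(repo, con)
  invisible(path)
}

#' Load repository tables into an existing DBI connection
#'
#' @param repo a `clinical_repository`
#' @param con a DBI connection
#' @return `con`, invisibly
#' @export
load_repository_into <- function(repo, con) {
  for (tbl in c("Diagnosis", "Laboratory", "Treatment")) {
    DBI::dbWriteTable(con, tbl, repo[[tbl]], overwrite = TRUE)
  }
  invisible(con)
}

#' Open a repository database
#'
#' @param path SQLite file produced by [write_repository_db()]
#' @return a DBI connection (caller closes with [DBI::dbDisconnect()])
#' @export
repository_connect <- function(path) {
  DBI::dbConnect(RSQLite::SQLite(), path)
}

#' Export repository tables as CSV
#'
#' One file per table (`Diagnosis.csv`, `Laboratory.csv`, `Treatment.csv`)
#' with headers exactly the schema column names.
#'
#' @param repo a `clinical_repository`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_repository_csv <- function(repo, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tbl in c("Diagnosis", "Laboratory", "Treatment")) {
    utils::write.csv(repo[[tbl]], file.path(dir, paste0(tbl, ".csv")),
                     row.names = FALSE, na = "")
  }
  invisible(dir)
}

#' Read repository tables from CSV
#'
#' @param dir directory holding `Diagnosis.csv`, `Laboratory.csv`,
#'   `Treatment.csv` as written by [write_repository_csv()]
#' @return a `clinical_repository`
#' @export
read_repository_csv <- function(dir) {
  rd <- function(tbl, classes) {
    utils::read.csv(file.path(dir, paste0(tbl, ".csv")),
                    stringsAsFactors = FALSE, colClasses = classes,
                    na.strings = "")
  }
  structure(list(
    Diagnosis = rd("Diagnosis", c(Personal_ID = "character",
                                  ICD9_Code = "character")),
    Laboratory = rd("Laboratory", c(Personal_ID = "character",
                                    Item_Name = "character",
                                    Result_String = "character",
                                    Result_Number = "numeric")),
    Treatment = rd("Treatment", c(Personal_ID = "character",
                                  Treatment_Name = "character"))
  ), class = "clinical_repository")
}

#' The five stored laboratory item names
#' @return character vector
#' @export
liver_lab_items <- function() .LAB_ITEMS

#' The five treatment names
#' @return character vector
#' @export
liver_treatments <- function() .TREATMENTS
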