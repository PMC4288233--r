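---
title: "Flowchart-based cohort querying: model, semantics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flowchart-based cohort querying: model, semantics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbdqm)
```

## The problem

Cohort identification — "which patients in this repository satisfy this
set of clinical criteria?" — is routine in clinical research, but writing
it directly in SQL demands knowledge of table layouts and produces
monolithic queries whose intermediate results are invisible. fbdqm
implements an alternative: the query is a *flowchart* of small steps, each
step holding a few human-readable criteria, and the engine executes the
flowchart node by node, so every intermediate patient set is a first-class
result that can be counted, listed and compared.

The node vocabulary follows the step classes of GLIF3.5, the clinical
guideline interchange format, repurposed for querying: `patient_state`
(a clinical state, also the flowchart entry), `action`, `decision`
(criteria-driven choice between children, optionally mutually exclusive),
and the `branch`/`synchronization` pair for concurrent paths. Using a
guideline formalism for queries keeps tasks shareable and lets one model
both simple inclusion cascades and classification rules.

## Execution semantics

Write `QC(v)` for the criteria of node `v`, `PL(v)` for its retrieved
patient list and `PLS(v) = |PL(v)|` for its size. Nodes execute in
topological order (ties broken by document order, so runs are
reproducible):

* a parentless node targets every distinct patient id in the repository;
* any other selected node targets the combination of its parents' lists —
  the intersection, for a multi-parent `synchronization` node (a
  configurable union is available, but concurrent paths are conjunctive
  by default);
* `PL(v)` is the subset of the target satisfying every criterion in
  `QC(v)` (the criteria list is a conjunction); a criterion-free node
  passes its target through;
* an unselected node executes nothing and reports `PLS = 0`. Descendants
  of unselected nodes are pruned by default; the
  `unselected = "inherit"` option instead lets them target the nearest
  executed ancestor's list.

Monotonicity follows: along every executed edge,
`PLS(child) <= PLS(parent)`.

Criteria operate on *patient sets*, not rows: `ICD=733.00 and ICD=820.0`
is satisfied by a patient carrying the two codes on two different
diagnosis rows. This is the only reading under which multi-condition
cohort definitions (e.g. osteoporosis plus hip fracture) make sense on
one-row-per-fact tables.

### The criterion language

Atoms: `item=value` (code equality; code text such as `155.0` is never
numerically normalised — numeric comparison happens only when the mapping
declares the item number-typed), `item=="string"`, and
`item is within a to b` (inclusive at both ends, matching SQL `BETWEEN`).
Compound forms: infix `and`/`or` (case-insensitive), parentheses, and
`at least k of (a1, ..., an)` over simple atoms. Curly and straight
quotes are both accepted.

Three forms are rejected with explicit errors rather than guessed at:
negation, value-set shorthand (`ICD=155.0 OR 155.2` — each disjunct needs
its own item), and nesting of one at-least inside another. Silent
mis-reads of clinical criteria are worse than hard failures.

### Mapping and SQL generation

A mapping table bridges each abstract data item to a repository column,
either *directly* (one value column: `ICD9` to `Diagnosis.ICD9_Code`) or
*indirectly* (a value column plus a discriminator column naming the item:
`Serum_Albumin` to `Laboratory.Result_Number` where
`Item_Name = 'Serum albumin'`). Mapping is strictly one-item-to-one-item;
duplicates and unmapped items are hard errors. Logical combinations are
deliberately *not* encoded in the mapping: they live in the query plan's
combiner (binary logical mapping realised in the host), keeping the
mapping table a plain dictionary.

Each criterion atom translates to exactly one SQL subquery of the form
`select Personal_ID from <table> where <value condition> [and
<discriminator>]` — ANSI `SELECT`/`WHERE`/`BETWEEN` only, so any
conforming engine works (the reference store is single-file SQLite via
DBI/RSQLite). `and`/`or`/at-least never reach SQL; they are evaluated in
the host over the returned id sets. Display SQL is rendered with single
quotes; execution always uses bound parameters. This split is also what
the three-phase timing measures: time inside the database driver
(`sql_operations`), host-side set combination and threshold checks
(`criteria_verification`), and everything else — parsing, translation,
report assembly (`other`, computed as the remainder so the three phases
account for the total exactly). Absolute times are hardware- and
backend-dependent and are not a reproduction target; the accounting
structure is.

### Mutually exclusive decisions

A decision node may declare its children mutually exclusive with an
explicit priority order. Children are then evaluated highest priority
first against the parent's list; every patient is assigned to the first
child whose criteria it satisfies and is removed from the pool before
lower-priority children are evaluated (which also saves verification
work). The resolution happens before any grandchild executes, so
descendants always see the disjoint lists. Unselected children are
skipped and absorb no patients. Without the setting, a patient may appear
in several children.

## The synthetic cohort

The generator emulates the study conditions the fixture tasks were
designed for: `n` liver-cancer patients, each with

* one `Diagnosis` row, ICD-9 155.0 (primary liver malignancy);
* one `Laboratory` row per each of five liver-function items — ascites
  (string-valued), ICG retention (%), prothrombin activity (%), serum
  albumin (g/dL), serum bilirubin (mg/dL);
* exactly one `Treatment` row drawn uniformly from liver transplantation,
  TACE, RFA, alcohol injection and surgical resection.

Each item's value space is partitioned into three liver-damage grades.
The grade-B ranges are the classical mid ranges (controllable ascites,
ICG 15–40, prothrombin 50–80, albumin 3.0–3.5, bilirubin 2.0–3.0),
inclusive at both ends; grade A is the favourable side and grade C the
unfavourable extreme. The outer bounds (ICG up to 100, prothrombin down
to 0, albumin 1.0–6.0, bilirubin 0.1–30) are a declared convention chosen
to be physiologically generous while keeping uniform sampling well
defined — they matter only through the fact that they partition the value
space.

Sampling: per patient and per item, a grade is drawn independently and
uniformly over A/B/C, then the value uniformly within that grade's range.
Two consequences drive the fixture arithmetic:

* **Pigeonhole completeness** — with 5 items and 3 grades, at least one
  grade holds ≥ 2 items, so every patient satisfies at least one degree's
  at-least-2-of-5 criterion; under the mutually exclusive setting the
  three degree counts therefore sum to exactly `n`.
* **Per-degree hit rate** — the probability that a fixed grade holds at
  least 2 of 5 items is the Binomial(5, 1/3) upper tail
  `1 − (2/3)^5 − 5·(1/3)·(2/3)^4 = 131/243 ≈ 0.539`, so without the
  setting each degree count concentrates around `0.539·n` (and the three
  counts sum to well over `n`), while each treatment count concentrates
  around `n/5`.

What the generator does **not** emulate: longitudinal records, repeated
measurements, demographics, correlated organ dysfunction (real grades of
the five items are strongly correlated; independence is a deliberate
simplification that maximises criterion overlap and thus stresses the
mutually-exclusive resolution), or missingness mechanisms beyond an
optional uniform laboratory dropout (default 0). Passing tests on this
cohort therefore demonstrate *retrieval correctness* — the engine
computes exactly the sets its semantics define — not clinical realism.

## Verification strategy

The package carries its own gold standard: `evaluate_in_memory()`
re-implements the execution semantics by direct data-frame filtering,
sharing no code with the parser-to-SQL-to-DBI path. `compare_reports()`
scores node-exact patient-list agreement (a task counts as correct only
when every node matches — stricter than task-level counting). The test
suite runs engine-vs-oracle on the three fixture tasks at cohort sizes 10
to 10,000 and on randomised flowcharts, selections, mutually-exclusive
flags and dropout rates; `scripts/acceptance.R` recomputes the same
agreement from scratch, with sizes 10/100/1000/10000 as the study
conditions (they finish in seconds on one CPU).

## Numerical and design choices

* **Percentages** are rounded half-up to two decimals (a displayed
  `12.90%` means exactly that), formatted with a decimal point regardless
  of locale; over a partition they sum to 100 within ±0.02.
* **Boundary values** classify into grade B (its range is closed), and
  the degree criteria share boundary points with neighbouring grades;
  generated values hit a shared boundary with probability zero, and the
  criteria — not the generator — define membership during retrieval.
* **Ordering**: patient lists are sorted ascending; node declaration
  order breaks topological ties; reports are therefore byte-stable for a
  given seed.
* **Entry node**: the unique parentless node; its class is validated to
  be `patient_state` or `action` but criteria evaluation itself is
  class-agnostic. A decision node may carry its own criteria in addition
  to routing between children (the shipped degree decision carries none
  and simply passes its parent's cohort through).
* **Fan-in**: only `synchronization` nodes may have multiple parents;
  every flowchart this model targets is tree-like with explicit
  join nodes.
* **No deduplication** of identical atoms across nodes: translated
  subquery counts are a meaningful, auditable quantity (the degree task
  yields 16, the treatments task 6), and caching would silently change
  the SQL-phase accounting.
* **XML dialect**: tasks travel as a small versioned dialect
  (`.fbdqm.xml`, schema in `extdata/fbdqm-task.xsd`) carrying exactly
  what the engine consumes — node class, verbatim criterion strings,
  edges, selection, priorities. Native Protégé/GLIF exports are not
  parsed; the dialect is a documented stand-in.

## Known limitations

* One-item-to-one-item mapping only; no temporal abstraction or
  classification-hierarchy mapping, no temporal operators in criteria.
* No negation and no value-set enumeration in the criterion language
  (both rejected explicitly).
* Cohort output is patient identifiers and counts per node, not
  per-patient clinical datasets.
* The engine is sequential and deterministic by contract; no streaming
  or concurrency.
* SQLite is the reference backend; other DBI backends should work for
  the generated ANSI subqueries but are not exercised by the tests.
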