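Package: fbdqm
Title: Flowchart-Based Cohort Querying over Clinical Repositories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Executes flowchart-based data-querying models (FBDQM) for
    cohort identification in relational clinical repositories. Query tasks
    are directed acyclic flowcharts of GLIF3.5-style nodes (action,
    decision, branch, synchronization, patient state), each holding
    criterion expressions such as code equalities, string equalities,
    inclusive numeric ranges and at-least-k-of-n conditions. Criteria are
    parsed into a typed AST, translated through a knowledge-to-data mapping
    table into one SQL subquery per atom, and executed node by node with
    patient-set intersection semantics, mutually-exclusive decision
    resolution, child-distribution reporting and three-phase timing.
    Includes a seeded synthetic clinical-data generator emulating a
    liver-cancer cohort (ICD-9 155.0 diagnoses, five liver-function
    laboratory items partitioned into three damage grades, five
    treatments), an independent brute-force in-memory oracle for accuracy
    verification, and XML/JSON/CSV interchange for tasks, mappings and
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
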