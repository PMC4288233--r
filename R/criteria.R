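#' @title Criterion expression language
#'
#' @description
#' Query criteria attached to flowchart nodes are written in a small
#' expression language: code/string equalities (`ICD9=155.0`,
#' `Ascites=="Controllable"`), inclusive numeric ranges
#' (`ICG is within 15 to 40`), infix `and` / `or` (patient-level set
#' semantics), parenthesised grouping, and the at-least form
#' `at least 2 of (c1, c2, ...)` over simple atoms. [parse_criterion()]
#' turns such a string into a typed AST; [render_criterion()] prints the
#' canonical text form back.
#'
#' Deliberately unsupported, and rejected with explicit errors rather than
#' silently mis-read: negation (`not`), value-set shorthand
#' (`ICD=155.0 OR 155.2` — each disjunct needs its own item), and nesting
#' of one at-least inside another.
#' @name criteria
NULL

.ATOM_OPS <- c("code_eq", "str_eq", "num_eq", "within")

# minimal numeric formatter for canonical rendering (no scientific notation)
fmt_num <- function(x) {
  format(x, scientific = FALSE, trim = TRUE, digits = 15)
}

#' Construct a criterion atom
#'
#' Atoms are the leaves of a criterion AST and each one translates to
#' exactly one SQL subquery. `op` is one of:
#' \describe{
#'   \item{code_eq}{equality against a code-like value kept verbatim as text
#'     (ICD codes such as `"155.0"` are never numerically normalised);
#'     compared numerically at translation time only when the mapping entry
#'     declares the item number-typed}
#'   \item{str_eq}{equality against a quoted string}
#'   \item{num_eq}{numeric equality (programmatic construction only; the
#'     surface syntax cannot distinguish it from code_eq)}
#'   \item{within}{inclusive numeric range `low <= x <= high`}
#' }
#'
#' @param item data-item name (resolved later via the mapping table)
#' @param op one of `"code_eq"`, `"str_eq"`, `"num_eq"`, `"within"`
#' @param value comparison value (text for code_eq/str_eq, number for num_eq)
#' @param low,high inclusive range bounds (within only), `low <= high`
#' @return an object of class `criterion_atom` / `criterion`
#' @export
#' @examples
#' criterion_atom("ICD9", "code_eq", "155.0")
#' criterion_atom("ICG", "within", low = 15, high = 40)
criterion_atom <- function(item, op, value = NULL, low = NULL, high = NULL) {
  stopifnot(is.character(item), length(item) == 1L, nzchar(item))
  op <- match.arg(op, .ATOM_OPS)
  a <- list(item = item, op = op)
  if (op == "within") {
    if (is.null(low) || is.null(high)) {
      stop("'within' atom requires low and high", call. = FALSE)
    }
    low <- as.numeric(low); high <- as.numeric(high)
    if (is.na(low) || is.na(high) || low > high) {
      stop("'within' atom requires numeric low <= high", call. = FALSE)
    }
    a$low <- low
    a$high <- high
    a$low_text <- fmt_num(low)
    a$high_text <- fmt_num(high)
  } else {
    if (is.null(value)) stop("equality atom requires a value", call. = FALSE)
    a$value <- if (op == "num_eq") as.numeric(value) else as.character(value)
  }
  structure(a, class = c("criterion_atom", "criterion"))
}

#' Construct an at-least-k-of-n criterion
#'
#' Satisfied by a patient iff at least `k` of the member atoms hold for
#' that patient. Members must be simple atoms (no nested at-least, no
#' and/or), mirroring how the form is used in practice.
#'
#' @param k threshold, `1 <= k <= length(atoms)`
#' @param atoms list of [criterion_atom()] objects, at least 2
#' @return an object of class `criterion_at_least` / `criterion`
#' @export
criterion_at_least <- function(k, atoms) {
  k <- as.integer(k)
  if (!is.list(atoms) || length(atoms) < 2L) {
    stop("'at least' requires a list of >= 2 atoms", call. = FALSE)
  }
  if (!all(vapply(atoms, inherits, logical(1), "criterion_atom"))) {
    stop("'at least' members must be simple atoms", call. = FALSE)
  }
  if (is.na(k) || k < 1L || k > length(atoms)) {
    stop("'at least' threshold k must satisfy 1 <= k <= number of atoms",
         call. = FALSE)
  }
  structure(list(k = k, atoms = atoms),
            class = c("criterion_at_least", "criterion"))
}

.criterion_junction <- function(parts, what) {
  if (!is.list(parts) || length(parts) < 2L) {
    stop(sprintf("'%s' requires >= 2 parts", what), call. = FALSE)
  }
  if (!all(vapply(parts, inherits, logical(1), "criterion"))) {
    stop(sprintf("'%s' parts must be criteria", what), call. = FALSE)
  }
  structure(list(parts = parts),
            class = c(sprintf("criterion_%s", what), "criterion"))
}

#' Conjunction / disjunction of criteria
#'
#' Both operate on patient sets: `and` is set intersection of the patients
#' satisfying each part, `or` is set union. In particular
#' `ICD=733.00 and ICD=820.0` is satisfiable by a patient holding two
#' diagnosis rows — `and` is not row-level conjunction.
#'
#' @param parts list of at least two criteria
#' @return an object of class `criterion_and` (resp. `criterion_or`)
#' @export
criterion_and <- function(parts) .criterion_junction(parts, "and")

#' @rdname criterion_and
#' @export
criterion_or <- function(parts) .criterion_junction(parts, "or")

#' List the atom leaves of a criterion
#'
#' The number of atoms equals the number of SQL subqueries the translator
#' will emit for the criterion.
#'
#' @param x a criterion
#' @return list of `criterion_atom` objects, in left-to-right order
#' @export
criterion_atoms <- function(x) {
  if (inherits(x, "criterion_atom")) return(list(x))
  if (inherits(x, "criterion_at_least")) return(x$atoms)
  if (inherits(x, "criterion_and") || inherits(x, "criterion_or")) {
    return(do.call(c, lapply(x$parts, criterion_atoms)))
  }
  stop("not a criterion", call. = FALSE)
}

#' @export
print.criterion <- function(x, ...) {
  cat("<criterion> ", render_criterion(x), "\n", sep = "")
  invisible(x)
}

## ---- tokenizer -------------------------------------------------------------

.QUOTE_CHARS <- c('"', "“", "”")

criterion_tokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1L
  push <- function(type, value, pos) {
    toks[[length(toks) + 1L]] <<- list(type = type, value = value, pos = pos)
  }
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% .QUOTE_CHARS) {
      j <- i + 1L
      while (j <= n && !(chars[j] %in% .QUOTE_CHARS)) j <- j + 1L
      if (j > n) {
        stop(sprintf("criterion syntax error at position %d: unterminated string", i),
             call. = FALSE)
      }
      val <- if (j - i > 1L) paste0(chars[(i + 1L):(j - 1L)], collapse = "") else ""
      push("STRING", val, i)
      i <- j + 1L
      next
    }
    if (grepl("^[0-9]$", ch) ||
        (ch == "." && i < n && grepl("^[0-9]$", chars[i + 1L]))) {
      j <- i
      while (j <= n && grepl("^[0-9.]$", chars[j])) j <- j + 1L
      push("NUMBER", paste0(chars[i:(j - 1L)], collapse = ""), i)
      i <- j
      next
    }
    if (grepl("^[A-Za-z_]$", ch)) {
      j <- i
      while (j <= n && grepl("^[A-Za-z0-9_]$", chars[j])) j <- j + 1L
      push("WORD", paste0(chars[i:(j - 1L)], collapse = ""), i)
      i <- j
      next
    }
    if (ch == "=" && i < n && chars[i + 1L] == "=") {
      push("EQEQ", "==", i); i <- i + 2L; next
    }
    if (ch == "=") { push("EQ", "=", i); i <- i + 1L; next }
    if (ch == "(") { push("LPAREN", "(", i); i <- i + 1L; next }
    if (ch == ")") { push("RPAREN", ")", i); i <- i + 1L; next }
    if (ch == ",") { push("COMMA", ",", i); i <- i + 1L; next }
    stop(sprintf("criterion syntax error at position %d: unexpected character '%s'",
                 i, ch), call. = FALSE)
  }
  toks
}

## ---- recursive-descent parser ---------------------------------------------

.parser_state <- function(toks, text) {
  env <- new.env(parent = emptyenv())
  env$toks <- toks
  env$pos <- 1L
  env$text <- text
  env
}

.peek <- function(st, offset = 0L) {
  i <- st$pos + offset
  if (i <= length(st$toks)) st$toks[[i]] else NULL
}

.advance <- function(st) {
  t <- .peek(st)
  st$pos <- st$pos + 1L
  t
}

.is_kw <- function(tok, word) {
  !is.null(tok) && tok$type == "WORD" && tolower(tok$value) == word
}

.expect <- function(st, type, what) {
  t <- .peek(st)
  if (is.null(t) || t$type != type) {
    pos <- if (is.null(t)) nchar(st$text) + 1L else t$pos
    stop(sprintf("criterion syntax error at position %d: expected %s", pos, what),
         call. = FALSE)
  }
  .advance(st)
}

#' Parse a criterion expression string
#'
#' @param text a non-empty criterion string, e.g. `"ICD9=155.0"` or
#'   `'at least 2 of (Ascites=="Controllable", ICG is within 15 to 40)'`.
#'   Straight and curly quotes are both accepted around string literals;
#'   keywords (`and`, `or`, `is within ... to`, `at least ... of`) are
#'   case-insensitive.
#' @return a `criterion` AST
#' @seealso [render_criterion()], [criterion_atom()]
#' @export
#' @examples
#' parse_criterion("ICD9=155.0")
#' parse_criterion("gender=male and ICD=733.00 and ICD=820.0")
parse_criterion <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop("criterion text must be a non-empty string", call. = FALSE)
  }
  st <- .parser_state(criterion_tokenize(text), text)
  out <- .parse_or(st)
  left <- .peek(st)
  if (!is.null(left)) {
    stop(sprintf("criterion syntax error at position %d: unexpected '%s'",
                 left$pos, left$value), call. = FALSE)
  }
  out
}

.parse_or <- function(st) {
  parts <- list(.parse_and(st))
  while (.is_kw(.peek(st), "or")) {
    .advance(st)
    parts[[length(parts) + 1L]] <- .parse_and(st)
  }
  if (length(parts) == 1L) parts[[1L]] else criterion_or(parts)
}

.parse_and <- function(st) {
  parts <- list(.parse_primary(st))
  while (.is_kw(.peek(st), "and")) {
    .advance(st)
    parts[[length(parts) + 1L]] <- .parse_primary(st)
  }
  if (length(parts) == 1L) parts[[1L]] else criterion_and(parts)
}

.parse_primary <- function(st, in_at_least = FALSE) {
  t <- .peek(st)
  if (is.null(t)) {
    stop(sprintf("criterion syntax error at position %d: unexpected end of input",
                 nchar(st$text) + 1L), call. = FALSE)
  }
  if (.is_kw(t, "not")) {
    stop(sprintf("negation unsupported (at position %d)", t$pos), call. = FALSE)
  }
  if (t$type %in% c("NUMBER", "STRING")) {
    # a bare value where a criterion is expected: the value-set shorthand
    stop(sprintf(paste0("unsupported valueset enumeration at position %d: ",
                        "'%s' has no item; write each alternative as ",
                        "item=value joined by 'or'"),
                 t$pos, t$value), call. = FALSE)
  }
  if (t$type == "LPAREN") {
    .advance(st)
    inner <- .parse_or(st)
    .expect(st, "RPAREN", "')'")
    return(inner)
  }
  if (.is_kw(t, "at") && .is_kw(.peek(st, 1L), "least")) {
    if (in_at_least) {
      stop(sprintf("nested 'at least' unsupported (at position %d)", t$pos),
           call. = FALSE)
    }
    return(.parse_at_least(st))
  }
  if (t$type == "WORD") return(.parse_atom(st))
  stop(sprintf("criterion syntax error at position %d: unexpected '%s'",
               t$pos, t$value), call. = FALSE)
}

.parse_at_least <- function(st) {
  .advance(st); .advance(st)                      # 'at' 'least'
  ktok <- .expect(st, "NUMBER", "a threshold after 'at least'")
  k <- suppressWarnings(as.integer(ktok$value))
  oftok <- .peek(st)
  if (!.is_kw(oftok, "of")) {
    pos <- if (is.null(oftok)) nchar(st$text) + 1L else oftok$pos
    stop(sprintf("criterion syntax error at position %d: expected 'of'", pos),
         call. = FALSE)
  }
  .advance(st)
  .expect(st, "LPAREN", "'('")
  atoms <- list()
  repeat {
    t <- .peek(st)
    if (.is_kw(t, "at") && .is_kw(.peek(st, 1L), "least")) {
      stop(sprintf("nested 'at least' unsupported (at position %d)", t$pos),
           call. = FALSE)
    }
    atoms[[length(atoms) + 1L]] <- .parse_primary(st, in_at_least = TRUE)
    if (!inherits(atoms[[length(atoms)]], "criterion_atom")) {
      stop("'at least' members must be simple atoms", call. = FALSE)
    }
    nxt <- .peek(st)
    if (!is.null(nxt) && nxt$type == "COMMA") { .advance(st); next }
    break
  }
  .expect(st, "RPAREN", "')'")
  criterion_at_least(k, atoms)
}

.parse_atom <- function(st) {
  itok <- .advance(st)                            # WORD
  t <- .peek(st)
  if (.is_kw(t, "is") && .is_kw(.peek(st, 1L), "within")) {
    .advance(st); .advance(st)
    lo <- .expect(st, "NUMBER", "a number after 'within'")
    totok <- .peek(st)
    if (!.is_kw(totok, "to")) {
      pos <- if (is.null(totok)) nchar(st$text) + 1L else totok$pos
      stop(sprintf("criterion syntax error at position %d: expected 'to'", pos),
           call. = FALSE)
    }
    .advance(st)
    hi <- .expect(st, "NUMBER", "a number after 'to'")
    a <- criterion_atom(itok$value, "within",
                        low = as.numeric(lo$value), high = as.numeric(hi$value))
    a$low_text <- lo$value                        # keep source spelling (e.g. "3.0")
    a$high_text <- hi$value
    return(a)
  }
  if (!is.null(t) && t$type == "EQEQ") {
    .advance(st)
    v <- .peek(st)
    if (is.null(v) || v$type != "STRING") {
      pos <- if (is.null(v)) nchar(st$text) + 1L else v$pos
      stop(sprintf("criterion syntax error at position %d: expected a quoted string after '=='",
                   pos), call. = FALSE)
    }
    .advance(st)
    return(criterion_atom(itok$value, "str_eq", v$value))
  }
  if (!is.null(t) && t$type == "EQ") {
    .advance(st)
    v <- .peek(st)
    if (is.null(v) || !(v$type %in% c("NUMBER", "WORD", "STRING"))) {
      pos <- if (is.null(v)) nchar(st$text) + 1L else v$pos
      stop(sprintf("criterion syntax error at position %d: expected a value after '='",
                   pos), call. = FALSE)
    }
    .advance(st)
    op <- if (v$type == "STRING") "str_eq" else "code_eq"
    return(criterion_atom(itok$value, op, v$value))
  }
  pos <- if (is.null(t)) nchar(st$text) + 1L else t$pos
  stop(sprintf("criterion syntax error at position %d: expected '=', '==' or 'is within' after item '%s'",
               pos, itok$value), call. = FALSE)
}

## ---- renderer --------------------------------------------------------------

#' Render a criterion AST to its canonical text form
#'
#' Canonical form uses straight double quotes, lowercase connectives and
#' single spacing, and is a fixed point of [parse_criterion()]:
#' `parse_criterion(render_criterion(x))` is structurally equal to `x`
#' (except for `num_eq` atoms, whose surface form is indistinguishable
#' from `code_eq`).
#'
#' @param x a criterion
#' @return a single string
#' @export
render_criterion <- function(x) {
  if (inherits(x, "criterion_atom")) {
    return(switch(x$op,
      code_eq = sprintf("%s=%s", x$item, x$value),
      num_eq  = sprintf("%s=%s", x$item, fmt_num(x$value)),
      str_eq  = sprintf('%s=="%s"', x$item, x$value),
      within  = sprintf("%s is within %s to %s", x$item, x$low_text, x$high_text)
    ))
  }
  if (inherits(x, "criterion_at_least")) {
    return(sprintf("at least %d of (%s)", x$k,
                   paste(vapply(x$atoms, render_criterion, character(1)),
                         collapse = ", ")))
  }
  wrap <- function(p) {
    s <- render_criterion(p)
    if (inherits(p, "criterion_and") || inherits(p, "criterion_or")) {
      s <- paste0("(", s, ")")
    }
    s
  }
  if (inherits(x, "criterion_and")) {
    return(paste(vapply(x$parts, wrap, character(1)), collapse = " and "))
  }
  if (inherits(x, "criterion_or")) {
    return(paste(vapply(x$parts, wrap, character(1)), collapse = " or "))
  }
  stop("not a criterion", call. = FALSE)
}

# structural equality up to the display-text of numbers
criterion_equal <- function(a, b) {
  if (!identical(class(a), class(b))) return(FALSE)
  if (inherits(a, "criterion_atom")) {
    if (!identical(a$item, b$item) || !identical(a$op, b$op)) return(FALSE)
    if (a$op == "within") {
      return(isTRUE(all.equal(c(a$low, a$high), c(b$low, b$high))))
    }
    return(identical(as.character(a$value), as.character(b$value)))
  }
  if (inherits(a, "criterion_at_least")) {
    if (a$k != b$k || length(a$atoms) != length(b$atoms)) return(FALSE)
    return(all(mapply(criterion_equal, a$atoms, b$atoms)))
  }
  if (length(a$parts) != length(b$parts)) return(FALSE)
  all(mapply(criterion_equal, a$parts, b$parts))
}
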