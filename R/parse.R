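# Compact textual rule format (.krt), UTF-8, line-oriented:
#   RULE <name>
#   DISP <joint> <X|Y|Z> <ABS>=|>=|<=> <metres> WITHIN <seconds> [AS "<clause>"]
#   ANGLE <joint> <ABS>=|>=|<=> <degrees> WITHIN <seconds> [AS "<clause>"]
# with operators AND, OR, THEN (precedence AND > OR > THEN), parentheses for
# grouping and '#' comments. Newlines are insignificant outside comments.
# The optional AS label carries the plain-English clause rendered for the
# rule, so published phrasing survives a serialization round trip.

tokenize_krt <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  toks <- list()
  pat <- '"[^"]*"|\\(|\\)|[^[:space:]()]+'
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    # strip comments (labels never contain '#')
    line <- sub("#.*$", "", line)
    m <- gregexpr(pat, line)[[1]]
    if (m[1] == -1) next
    vals <- regmatches(line, gregexpr(pat, line))[[1]]
    for (k in seq_along(vals)) {
      toks[[length(toks) + 1]] <- list(value = vals[k], line = ln,
                                       col = m[k])
    }
  }
  toks
}

abort_syntax <- function(message, tok = NULL) {
  loc <- if (is.null(tok)) "at end of input" else {
    sprintf("at line %d, column %d ('%s')", tok$line, tok$col, tok$value)
  }
  rlang::abort(paste0("rule syntax error ", loc, ": ", message),
               class = c("fms_syntax_error", "fms_validation_error"))
}

new_token_cursor <- function(tokens) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens
  env$pos <- 1L
  env
}

peek_tok <- function(cur) {
  if (cur$pos > length(cur$tokens)) NULL else cur$tokens[[cur$pos]]
}

next_tok <- function(cur) {
  tok <- peek_tok(cur)
  if (!is.null(tok)) cur$pos <- cur$pos + 1L
  tok
}

expect_tok <- function(cur, what) {
  tok <- next_tok(cur)
  if (is.null(tok)) abort_syntax(paste0("expected ", what))
  tok
}

parse_number_tok <- function(cur, what) {
  tok <- expect_tok(cur, what)
  val <- suppressWarnings(as.numeric(tok$value))
  if (is.na(val)) abort_syntax(paste0("expected ", what), tok)
  val
}

#' Parse a rule from its compact textual form
#'
#' See the package vignette for the grammar. Operator precedence is
#' AND > OR > THEN (AND binds tightest); parentheses override. Syntax errors
#' report line and column.
#'
#' @param text Rule text (single string, possibly multi-line).
#' @return An `fms_rule`.
#' @export
#' @examples
#' parse_rule('RULE NOD\nDISP head Y ABS>= 0.05 WITHIN 1.0')
parse_rule <- function(text) {
  cur <- new_token_cursor(tokenize_krt(paste(text, collapse = "\n")))
  hdr <- expect_tok(cur, "'RULE' header")
  if (toupper(hdr$value) != "RULE") abort_syntax("expected 'RULE' header", hdr)
  name <- expect_tok(cur, "rule name")$value
  expr <- parse_then_expr(cur)
  extra <- peek_tok(cur)
  if (!is.null(extra)) abort_syntax("unexpected trailing input", extra)
  movement_rule(name, expr)
}

parse_then_expr <- function(cur) {
  left <- parse_or_expr(cur)
  while (!is.null(peek_tok(cur)) && toupper(peek_tok(cur)$value) == "THEN") {
    next_tok(cur)
    left <- rule_then(left, parse_or_expr(cur))
  }
  left
}

parse_or_expr <- function(cur) {
  children <- list(parse_and_expr(cur))
  while (!is.null(peek_tok(cur)) && toupper(peek_tok(cur)$value) == "OR") {
    next_tok(cur)
    children[[length(children) + 1]] <- parse_and_expr(cur)
  }
  if (length(children) == 1) children[[1]] else new_expr("or", children)
}

parse_and_expr <- function(cur) {
  children <- list(parse_primary(cur))
  while (!is.null(peek_tok(cur)) && toupper(peek_tok(cur)$value) == "AND") {
    next_tok(cur)
    children[[length(children) + 1]] <- parse_primary(cur)
  }
  if (length(children) == 1) children[[1]] else new_expr("and", children)
}

parse_primary <- function(cur) {
  tok <- peek_tok(cur)
  if (is.null(tok)) abort_syntax("expected a condition or '('")
  if (tok$value == "(") {
    next_tok(cur)
    expr <- parse_then_expr(cur)
    closing <- next_tok(cur)
    if (is.null(closing) || closing$value != ")") {
      abort_syntax("unbalanced parenthesis: expected ')'",
                   closing %||% tok)
    }
    return(expr)
  }
  if (toupper(tok$value) %in% c("DISP", "ANGLE")) return(parse_leaf(cur))
  abort_syntax("expected DISP, ANGLE or '('", tok)
}

krt_cmp <- c("ABS>=" = "abs_ge", ">=" = "signed_ge", "<=" = "signed_le")

parse_leaf <- function(cur) {
  kind_tok <- next_tok(cur)
  kind <- toupper(kind_tok$value)
  joint_tok <- expect_tok(cur, "joint name")
  if (!joint_tok$value %in% skeleton_joints()) {
    abort_syntax("unknown joint name", joint_tok)
  }
  axis <- NULL
  if (kind == "DISP") {
    axis_tok <- expect_tok(cur, "axis X, Y or Z")
    axis <- tolower(axis_tok$value)
    if (!axis %in% c("x", "y", "z")) abort_syntax("expected axis X, Y or Z", axis_tok)
  }
  cmp_tok <- expect_tok(cur, "comparator ABS>=, >= or <=")
  cmp <- unname(krt_cmp[toupper(cmp_tok$value)])
  if (is.na(cmp)) abort_syntax("expected comparator ABS>=, >= or <=", cmp_tok)
  threshold <- parse_number_tok(cur, "numeric threshold")
  within_tok <- expect_tok(cur, "'WITHIN'")
  if (toupper(within_tok$value) != "WITHIN") {
    abort_syntax("expected 'WITHIN'", within_tok)
  }
  window <- parse_number_tok(cur, "numeric window (seconds)")
  if (window <= 0) abort_syntax("window must be positive", within_tok)
  english <- NULL
  nxt <- peek_tok(cur)
  if (!is.null(nxt) && toupper(nxt$value) == "AS") {
    next_tok(cur)
    lab_tok <- expect_tok(cur, 'quoted label after AS')
    if (!grepl('^".*"$', lab_tok$value)) {
      abort_syntax("expected a quoted label after AS", lab_tok)
    }
    english <- substr(lab_tok$value, 2, nchar(lab_tok$value) - 1)
  }
  if (kind == "DISP") {
    disp_condition(joint_tok$value, axis, cmp, threshold, window, english)
  } else {
    angle_condition(joint_tok$value, cmp, threshold, window, english)
  }
}

# ---- serialization ----------------------------------------------------------

expr_prec <- function(x) {
  if (is_condition(x)) return(4L)
  switch(x$op, and = 3L, or = 2L, then = 1L)
}

serialize_leaf <- function(cond) {
  cmp_txt <- names(krt_cmp)[match(cond$cmp, krt_cmp)]
  head_txt <- if (cond$kind == "disp") {
    sprintf("DISP %s %s %s %s WITHIN %s", cond$joint, toupper(cond$axis),
            cmp_txt, as.character(cond$threshold),
            as.character(cond$window_s))
  } else {
    sprintf("ANGLE %s %s %s WITHIN %s", cond$joint, cmp_txt,
            as.character(cond$threshold), as.character(cond$window_s))
  }
  if (!is.null(cond$english)) {
    if (grepl('"', cond$english, fixed = TRUE)) {
      abort_validation("plain-English labels must not contain double quotes")
    }
    head_txt <- paste0(head_txt, ' AS "', cond$english, '"')
  }
  head_txt
}

serialize_expr <- function(x, parent_prec = 0L) {
  if (is_condition(x)) {
    return(serialize_leaf(x))
  }
  word <- toupper(x$op)
  # parenthesize children of lower precedence, and same-op nesting, so the
  # parsed tree is structurally identical to the serialized one
  parts <- vapply(x$children, function(ch) {
    txt <- serialize_expr(ch)
    needs_paren <- is_rule_expr(ch) &&
      (expr_prec(ch) < expr_prec(x) || ch$op == x$op)
    if (needs_paren) paste0("( ", txt, " )") else txt
  }, character(1))
  if (x$op == "then") {
    paste(parts[1], "THEN", parts[2])
  } else {
    paste(parts, collapse = paste0(" ", word, " "))
  }
}

#' Serialize a rule to its compact textual form
#'
#' `serialize_rule()` returns the text; `write_rule()` writes it to a `.krt`
#' file; `read_rule()` parses one back. `parse_rule(serialize_rule(r))`
#' reproduces `r` structurally.
#'
#' @param rule An `fms_rule`.
#' @return A string (one clause per line).
#' @export
serialize_rule <- function(rule) {
  if (!is_rule(rule)) abort_validation("rule must be an fms_rule")
  body <- serialize_expr(rule$expr)
  # one clause/operator per line for readability; quoted labels are masked so
  # operator words inside them are never split
  labels <- regmatches(body, gregexpr('"[^"]*"', body))[[1]]
  masked <- body
  for (i in seq_along(labels)) {
    masked <- sub('"[^"]*"', sprintf("\001%d\001", i), masked, fixed = FALSE)
  }
  masked <- gsub(" (AND|OR|THEN) ", "\n\\1\n", masked)
  for (i in seq_along(labels)) {
    masked <- sub(sprintf("\001%d\001", i), labels[i], masked, fixed = TRUE)
  }
  body <- masked
  paste0("RULE ", rule$name, "\n", body, "\n")
}

#' @rdname serialize_rule
#' @param path `.krt` file path.
#' @export
write_rule <- function(rule, path) {
  writeLines(serialize_rule(rule), path, sep = "")
  invisible(path)
}

#' @rdname serialize_rule
#' @export
read_rule <- function(path) {
  if (!file.exists(path)) {
    abort_validation(paste0("rule file not found: ", path))
  }
  parse_rule(paste(readLines(path, warn = FALSE), collapse = "\n"))
}
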