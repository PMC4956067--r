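#' Movement-rule conditions
#'
#' A condition constrains the motion of one joint inside a time window: the
#' displacement of the joint along one axis (or the change in the angle at
#' the joint) relative to the window's anchor frame must reach a threshold
#' within strictly less than `window_s` seconds. Comparators: `abs_ge`
#' (|change| >= threshold, the "changes at least" clause), `signed_ge`
#' (change >= threshold) and `signed_le` (change <= threshold, the "changes
#' less than" clause used with negative thresholds).
#'
#' @param joint One of [skeleton_joints()].
#' @param axis `"x"` (horizontal, player's right positive), `"y"` (vertical,
#'   up positive) or `"z"` (depth, away from camera positive).
#' @param cmp One of `"abs_ge"`, `"signed_ge"`, `"signed_le"`.
#' @param threshold Displacement threshold in metres (`disp_condition`) or
#'   degrees (`angle_condition`).
#' @param window_s Time window in seconds; the elapsed time from the anchor
#'   must be strictly less than this.
#' @param english Optional plain-English clause used verbatim by
#'   [render_english()]; when `NULL` a canonical template is used.
#' @return An `fms_condition` object.
#' @export
disp_condition <- function(joint, axis, cmp, threshold, window_s,
                           english = NULL) {
  new_condition("disp", joint, tolower(axis), cmp, threshold, window_s, english)
}

#' @rdname disp_condition
#' @details The angle at a joint is the angle (degrees) between the segments
#' from the joint to its parent and to its first child in the skeleton
#' hierarchy; terminal joints have no defined angle and an angle condition on
#' them is never satisfied. Angle conditions are accepted by the rule grammar
#' but not used by the built-in rules.
#' @export
angle_condition <- function(joint, cmp, threshold, window_s, english = NULL) {
  new_condition("angle", joint, NA_character_, cmp, threshold, window_s, english)
}

new_condition <- function(kind, joint, axis, cmp, threshold, window_s,
                          english = NULL) {
  if (!joint %in% skeleton_joints()) {
    abort_validation(paste0("unknown joint name: ", joint))
  }
  if (kind == "disp" && !axis %in% c("x", "y", "z")) {
    abort_validation("displacement conditions need axis x, y or z")
  }
  if (!cmp %in% c("abs_ge", "signed_ge", "signed_le")) {
    abort_validation(paste0("unknown comparator: ", cmp))
  }
  if (!is.finite(threshold)) abort_validation("threshold must be finite")
  if (!is.finite(window_s) || window_s <= 0) {
    abort_validation("window_s must be a positive number of seconds")
  }
  structure(
    list(kind = kind, joint = joint, axis = axis, cmp = cmp,
         threshold = as.numeric(threshold), window_s = as.numeric(window_s),
         english = english),
    class = "fms_condition"
  )
}

is_condition <- function(x) inherits(x, "fms_condition")

#' Combine conditions with Boolean operators
#'
#' Rule expressions are trees whose leaves are conditions and whose internal
#' nodes are AND, OR and IF-THEN. AND and OR take two or more children;
#' IF-THEN exactly two (antecedent, consequent). Within a match window an
#' IF-THEN node is true when its antecedent is unsatisfied (vacuously) or its
#' consequent is satisfied at or after the antecedent's satisfying frame; a
#' vacuously true antecedent alone never fires a match (a match needs at
#' least one satisfied condition).
#'
#' @param ... Two or more conditions or sub-expressions.
#' @return An `fms_rule_expr` node.
#' @export
rule_and <- function(...) new_expr("and", list(...))

#' @rdname rule_and
#' @export
rule_or <- function(...) new_expr("or", list(...))

#' @rdname rule_and
#' @param antecedent,consequent The two children of the IF-THEN node.
#' @export
rule_then <- function(antecedent, consequent) {
  new_expr("then", list(antecedent, consequent))
}

new_expr <- function(op, children) {
  if (op %in% c("and", "or") && length(children) < 2) {
    abort_validation(paste0(toupper(op), " needs at least two children"))
  }
  if (op == "then" && length(children) != 2) {
    abort_validation("IF-THEN needs exactly two children")
  }
  ok <- vapply(children, function(ch) is_condition(ch) || is_rule_expr(ch),
               logical(1))
  if (!all(ok)) abort_validation("rule expression children must be conditions or expressions")
  structure(list(op = op, children = children), class = "fms_rule_expr")
}

is_rule_expr <- function(x) inherits(x, "fms_rule_expr")

#' Define a named movement rule
#'
#' @param name Nonempty rule name, unique within a rule set.
#' @param expr A condition or rule expression.
#' @return An `fms_rule` object.
#' @export
#' @examples
#' r <- movement_rule("NOD", disp_condition("head", "y", "abs_ge", 0.03, 0.5))
#' render_english(r)
movement_rule <- function(name, expr) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    abort_validation("rule name must be a nonempty string")
  }
  if (!is_condition(expr) && !is_rule_expr(expr)) {
    abort_validation("expr must be a condition or rule expression")
  }
  structure(list(name = name, expr = expr), class = "fms_rule")
}

is_rule <- function(x) inherits(x, "fms_rule")

#' @export
print.fms_rule <- function(x, ...) {
  cat("<fms_rule ", x$name, ">\n", sep = "")
  cat(render_english(x), "\n", sep = "")
  invisible(x)
}

rule_leaves <- function(expr) {
  if (is_condition(expr)) return(list(expr))
  unlist(lapply(expr$children, rule_leaves), recursive = FALSE)
}

# structural equality, ignoring plain-English labels
#' Compare two rules structurally
#'
#' Two rules are identical when their names and expression trees (operators,
#' joints, axes, comparators, thresholds, windows) agree exactly;
#' plain-English labels are compared too when both rules carry them.
#'
#' @param a,b `fms_rule` objects.
#' @return Logical scalar.
#' @export
rule_identical <- function(a, b) {
  identical(strip_null_english(a), strip_null_english(b))
}

strip_null_english <- function(x) {
  if (is_condition(x)) {
    x$english <- x$english %||% NA_character_
    return(x)
  }
  if (is_rule_expr(x)) {
    x$children <- lapply(x$children, strip_null_english)
    return(x)
  }
  if (is_rule(x)) {
    x$expr <- strip_null_english(x$expr)
    return(x)
  }
  x
}

# ---- built-in rules ---------------------------------------------------------

#' The built-in jump and sidestep rules
#'
#' The final Boolean rules used for game-play analysis. A jump requires the
#' head, both ankles and the hip centre each to move vertically at least 5 cm
#' in under one second. A sidestep is either a right-lead branch (hip centre
#' and shoulder centre move horizontally at least 10 cm in under 0.5 s and
#' the right foot at least 30 cm in under 0.3 s) or a left-lead branch (the
#' mirrored foot clause on the left foot plus a signed clause requiring the
#' right foot to move at least 25 cm towards the player's left in under
#' 0.5 s). The left-right asymmetry of the published table is preserved
#' as-is.
#'
#' @return An `fms_rule`.
#' @export
#' @examples
#' cat(render_english(builtin_jump()))
builtin_jump <- function() {
  leaf <- function(joint, english) {
    disp_condition(joint, "y", "abs_ge", 0.05, 1.0, english = english)
  }
  movement_rule("JUMP", rule_and(
    leaf("head",
         "Vertical movement of the head changes at least 5cm in under 1 second"),
    leaf("ankle_left",
         "Vertical movement of the left ankle changes at least 5 cm in under 1 second"),
    leaf("ankle_right",
         "Vertical movement of the right ankle changes at least 5 cm in under 1 second"),
    leaf("hip_centre",
         "Vertical movement of the hip centre changes at least 5cm in under 1 second")
  ))
}

#' @rdname builtin_jump
#' @export
builtin_sidestep <- function() {
  hip <- function() disp_condition(
    "hip_centre", "x", "abs_ge", 0.10, 0.5,
    english = "Horizontal Movement of the hip centre changes at least 10 cm in under .5 seconds"
  )
  shoulder <- function() disp_condition(
    "shoulder_centre", "x", "abs_ge", 0.10, 0.5,
    english = "Horizontal movement of the shoulder centre changes at least 10 centimetres in under .5 seconds"
  )
  branch_right <- rule_and(
    hip(),
    disp_condition(
      "foot_right", "x", "abs_ge", 0.30, 0.3,
      english = "Horizontal movement of the right foot changes at least 30 centimetres in under .3 seconds"
    ),
    shoulder()
  )
  branch_left <- rule_and(
    hip(),
    disp_condition(
      "foot_left", "x", "abs_ge", 0.30, 0.3,
      english = "Horizontal movement of the left foot changes at least 30 centimetres in under .3 seconds"
    ),
    shoulder(),
    disp_condition(
      "foot_right", "x", "signed_le", -0.25, 0.5,
      english = "Horizontal movement of the right foot changes less than -25 centimetres in under .5 seconds"
    )
  )
  movement_rule("SIDESTEP", rule_or(branch_right, branch_left))
}

#' @rdname builtin_jump
#' @export
builtin_rules <- function() list(builtin_jump(), builtin_sidestep())

# ---- plain-English rendering ------------------------------------------------

joint_display_name <- function(joint) {
  parts <- strsplit(joint, "_", fixed = TRUE)[[1]]
  if (length(parts) == 2 && parts[2] %in% c("left", "right")) {
    paste(parts[2], parts[1])
  } else {
    paste(parts, collapse = " ")
  }
}

fmt_num <- function(x) {
  s <- format(x, trim = TRUE, scientific = FALSE)
  sub("^(-?)0[.]", "\\1.", s)  # table style: .5 rather than 0.5
}

condition_english <- function(cond) {
  if (!is.null(cond$english)) return(cond$english)
  w <- fmt_num(cond$window_s)
  secs <- if (cond$window_s == 1) "second" else "seconds"
  if (cond$kind == "disp") {
    axis_word <- c(x = "Horizontal", y = "Vertical", z = "Depth")[[cond$axis]]
    cm <- cond$threshold * 100
    if (cond$cmp == "signed_le") {
      sprintf("%s movement of the %s changes less than %s centimetres in under %s %s",
              axis_word, joint_display_name(cond$joint), fmt_num(cm), w, secs)
    } else {
      sprintf("%s movement of the %s changes at least %scm in under %s %s",
              axis_word, joint_display_name(cond$joint), fmt_num(cm), w, secs)
    }
  } else {
    verb <- if (cond$cmp == "signed_le") "changes less than" else "changes at least"
    sprintf("Angle at the %s %s %s degrees in under %s %s",
            joint_display_name(cond$joint), verb, fmt_num(cond$threshold),
            w, secs)
  }
}

render_expr_english <- function(expr) {
  if (is_condition(expr)) return(condition_english(expr))
  if (expr$op == "then") {
    c("IF", render_expr_english(expr$children[[1]]),
      "THEN", render_expr_english(expr$children[[2]]))
  } else {
    word <- toupper(expr$op)
    parts <- lapply(expr$children, render_expr_english)
    out <- parts[[1]]
    for (p in parts[-1]) out <- c(out, word, p)
    out
  }
}

#' Render a rule in plain English
#'
#' One clause per condition, with operator words (`AND`, `OR`, `IF`/`THEN`)
#' on their own lines between clauses — the same layout the rule-building
#' interface shows for verifying a rule's intent.
#'
#' @param rule An `fms_rule`.
#' @return A single string (lines separated by newlines).
#' @export
render_english <- function(rule) {
  expr <- if (is_rule(rule)) rule$expr else rule
  paste(render_expr_english(expr), collapse = "\n")
}
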