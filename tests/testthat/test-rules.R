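table2_jump_clauses <- c(
  "Vertical movement of the head changes at least 5cm in under 1 second",
  "AND",
  "Vertical movement of the left ankle changes at least 5 cm in under 1 second",
  "AND",
  "Vertical movement of the right ankle changes at least 5 cm in under 1 second",
  "AND",
  "Vertical movement of the hip centre changes at least 5cm in under 1 second"
)

table2_sidestep_clauses <- c(
  "Horizontal Movement of the hip centre changes at least 10 cm in under .5 seconds",
  "AND",
  "Horizontal movement of the right foot changes at least 30 centimetres in under .3 seconds",
  "AND",
  "Horizontal movement of the shoulder centre changes at least 10 centimetres in under .5 seconds",
  "OR",
  "Horizontal Movement of the hip centre changes at least 10 cm in under .5 seconds",
  "AND",
  "Horizontal movement of the left foot changes at least 30 centimetres in under .3 seconds",
  "AND",
  "Horizontal movement of the shoulder centre changes at least 10 centimetres in under .5 seconds",
  "AND",
  "Horizontal movement of the right foot changes less than -25 centimetres in under .5 seconds"
)

test_that("built-in rules have the published structure", {
  jump <- builtin_jump()
  expect_equal(jump$name, "JUMP")
  expect_equal(jump$expr$op, "and")
  leaves <- fmsdetect:::rule_leaves(jump$expr)
  expect_length(leaves, 4)
  expect_equal(vapply(leaves, function(l) l$joint, character(1)),
               c("head", "ankle_left", "ankle_right", "hip_centre"))
  expect_true(all(vapply(leaves, function(l) l$axis == "y", logical(1))))
  expect_true(all(vapply(leaves, function(l) l$threshold == 0.05, logical(1))))
  expect_true(all(vapply(leaves, function(l) l$window_s == 1, logical(1))))
  expect_true(all(vapply(leaves, function(l) l$cmp == "abs_ge", logical(1))))

  ss <- builtin_sidestep()
  expect_equal(ss$expr$op, "or")
  expect_length(ss$expr$children, 2)
  expect_length(fmsdetect:::rule_leaves(ss$expr$children[[1]]), 3)
  expect_length(fmsdetect:::rule_leaves(ss$expr$children[[2]]), 4)
  neg <- fmsdetect:::rule_leaves(ss$expr$children[[2]])[[4]]
  expect_equal(neg$joint, "foot_right")
  expect_equal(neg$cmp, "signed_le")
  expect_equal(neg$threshold, -0.25)
  expect_equal(neg$window_s, 0.5)
})

test_that("plain-English rendering reproduces the published clauses verbatim", {
  expect_identical(strsplit(render_english(builtin_jump()), "\n")[[1]],
                   table2_jump_clauses)
  expect_identical(strsplit(render_english(builtin_sidestep()), "\n")[[1]],
                   table2_sidestep_clauses)
})

test_that("the canonical template renders unlabelled conditions", {
  r <- movement_rule("NOD", disp_condition("head", "y", "abs_ge", 0.03, 0.5))
  expect_equal(render_english(r),
               "Vertical movement of the head changes at least 3cm in under .5 seconds")
  r2 <- movement_rule("LEAN", disp_condition("spine", "x", "signed_le",
                                             -0.12, 1))
  expect_equal(render_english(r2),
               "Horizontal movement of the spine changes less than -12 centimetres in under 1 second")
  # single-condition rules have no operator words
  expect_false(grepl("AND|OR|THEN", render_english(r)))
})

test_that("rule text parses with the documented precedence", {
  r <- parse_rule("RULE T\nDISP head Y ABS>= 0.05 WITHIN 1.0")
  expect_true(fmsdetect:::is_condition(r$expr))
  expect_equal(r$expr$joint, "head")
  expect_equal(r$expr$window_s, 1)

  # AND binds tighter than OR
  txt <- paste(
    "RULE P",
    "DISP head Y ABS>= 0.05 WITHIN 1 AND DISP spine Y ABS>= 0.05 WITHIN 1",
    "OR DISP hip_centre X >= 0.1 WITHIN 0.5"
  )
  p <- parse_rule(txt)
  expect_equal(p$expr$op, "or")
  expect_equal(p$expr$children[[1]]$op, "and")

  # OR binds tighter than THEN; THEN is left-associative
  q <- parse_rule(paste(
    "RULE Q",
    "DISP head Y ABS>= 0.05 WITHIN 1 THEN DISP spine Y ABS>= 0.05 WITHIN 1",
    "THEN DISP head X ABS>= 0.05 WITHIN 1"
  ))
  expect_equal(q$expr$op, "then")
  expect_equal(q$expr$children[[1]]$op, "then")

  # parentheses override
  g <- parse_rule(paste(
    "RULE G",
    "DISP head Y ABS>= 0.05 WITHIN 1 AND ( DISP spine Y ABS>= 0.05 WITHIN 1",
    "OR DISP hip_centre X >= 0.1 WITHIN 0.5 )"
  ))
  expect_equal(g$expr$op, "and")
  expect_equal(g$expr$children[[2]]$op, "or")

  # comments and angle leaves are accepted
  a <- parse_rule("RULE A\n# a comment\nANGLE knee_left <= -20 WITHIN 0.5")
  expect_equal(a$expr$kind, "angle")
  expect_true(is.na(a$expr$axis))
})

test_that("malformed rule text is rejected with located errors", {
  expect_error(parse_rule("RULE X\n( DISP head Y ABS>= 0.05 WITHIN 1"),
               class = "fms_syntax_error")
  err <- tryCatch(parse_rule("RULE X\nDISP noggin Y ABS>= 0.05 WITHIN 1"),
                  error = identity)
  expect_s3_class(err, "fms_syntax_error")
  expect_match(conditionMessage(err), "line 2")
  expect_error(parse_rule("RULE X\nDISP head Y ABS>= 0.05 WITHIN -1"),
               class = "fms_syntax_error")
  expect_error(parse_rule("DISP head Y ABS>= 0.05 WITHIN 1"),
               class = "fms_syntax_error")
  expect_error(parse_rule("RULE X\nDISP head Y ABS>= 0.05 WITHIN 1 BOGUS"),
               class = "fms_syntax_error")
})

test_that("serialization round-trips rules structurally", {
  for (r in list(builtin_jump(), builtin_sidestep())) {
    expect_true(rule_identical(parse_rule(serialize_rule(r)), r))
  }
  for (seed in 1:25) {
    r <- random_rule(seed)
    expect_true(rule_identical(parse_rule(serialize_rule(r)), r))
  }
  # file round trip
  tf <- tempfile(fileext = ".krt")
  write_rule(builtin_sidestep(), tf)
  expect_true(rule_identical(read_rule(tf), builtin_sidestep()))
})

test_that("shipped rule files reproduce the built-ins", {
  jump_path <- system.file("extdata", "rules", "jump.krt",
                           package = "fmsdetect")
  ss_path <- system.file("extdata", "rules", "sidestep.krt",
                         package = "fmsdetect")
  expect_true(nzchar(jump_path) && nzchar(ss_path))
  expect_true(rule_identical(read_rule(jump_path), builtin_jump()))
  expect_true(rule_identical(read_rule(ss_path), builtin_sidestep()))
})

test_that("condition and expression invariants are enforced", {
  expect_error(disp_condition("head", "y", "abs_ge", 0.05, 0),
               class = "fms_validation_error")
  expect_error(disp_condition("head", "w", "abs_ge", 0.05, 1),
               class = "fms_validation_error")
  expect_error(disp_condition("nope", "y", "abs_ge", 0.05, 1),
               class = "fms_validation_error")
  expect_error(disp_condition("head", "y", "abs_ge", Inf, 1),
               class = "fms_validation_error")
  c1 <- disp_condition("head", "y", "abs_ge", 0.05, 1)
  expect_error(rule_and(c1), class = "fms_validation_error")
  expect_error(fmsdetect:::new_expr("then", list(c1)),
               class = "fms_validation_error")
  expect_error(movement_rule("", c1), class = "fms_validation_error")
})
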