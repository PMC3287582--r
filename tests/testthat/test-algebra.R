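# Core algebra: construction, derivatives, termination, the trace oracle,
# guardedness, and rewriting to basic operators.

test_that("constructors enforce arity and parameter invariants", {
  a <- px_atom("PCR_exon7")
  expect_identical(a$kind, "atom")
  expect_identical(a$symbol$kind, "regular")
  expect_identical(px_atom("GO")$symbol$kind, "silent")
  expect_identical(px_atom("END")$symbol$kind, "terminal")
  s <- px_make("seq", px_atom("a"), px_atom("b"))
  expect_identical(npdl_serialize(s), "a . b")
  expect_error(px_rep(px_atom("a"), 0), "positive integer")
  expect_error(px_atom("7bad"), "identifier")
  expect_error(px_make("frobnicate", a), "unknown expression kind")
  expect_error(px_seq(px_atom("a"), "b"), "npdl_expr")
})

test_that("structural equality distinguishes shape, not behaviour", {
  e1 <- parse_expression("a . b + c")
  expect_true(px_equal(e1, px_alt(px_seq(px_atom("a"), px_atom("b")), px_atom("c"))))
  expect_false(px_equal(parse_expression("a + b"), parse_expression("b + a")))
})

test_that("enabled returns initial actions with guard-sensitive filtering", {
  expect_setequal(enabled(parse_expression("a . b"))$action, "a")
  expect_setequal(enabled(parse_expression("a || b"))$action, c("a", "b"))
  g <- parse_expression("(a % r) + b")
  expect_setequal(enabled(g, ctx = const_context(list(r = FALSE)))$action, "b")
  expect_setequal(enabled(g, ctx = const_context(list(r = TRUE)))$action, c("a", "b"))
  # negated guard enables iff the rule is false
  ng <- parse_expression("(a %! r) + b")
  expect_setequal(enabled(ng, ctx = const_context(list(r = FALSE)))$action, c("a", "b"))
  # guard consequence agrees with the oracle: r false leaves only the b-trace
  expect_trace_set(g, "b", ctx = const_context(list(r = FALSE)))
})

test_that("step computes the unique residual of an occurrence", {
  expect_identical(npdl_serialize(step(parse_expression("a . b"), "a")), "b")
  expect_identical(npdl_serialize(step(parse_expression("a || b"), "a")), "b")
  res <- step(parse_expression("(a || b) . c"), "b")
  expect_identical(npdl_serialize(res), "a . c")
  expect_trace_set(res, "a c")
  expect_error(step(parse_expression("a . b"), "b"), "not currently enabled")
  # identical labels at different occurrences are disambiguated by path
  en <- enabled(parse_expression("a || a"))
  expect_identical(nrow(en), 2L)
  expect_false(en$path[[1]] == en$path[[2]])
})

test_that("terminated reflects remaining obligatory work", {
  expect_false(terminated(parse_expression("a . b")))
  r1 <- step(parse_expression("a . b"), "a")
  expect_false(terminated(r1))
  expect_true(terminated(step(r1, "b")))
  # one-or-more repetition: terminated after a single pass
  expect_true(terminated(step(parse_expression("a ?*"), "a")))
  expect_false(terminated(parse_expression("a ?*")))
  expect_true("a" %in% traces(parse_expression("a ?*")))
})

test_that("the trace oracle enumerates bounded complete traces", {
  expect_trace_set(parse_expression("a . b"), "a b")
  expect_trace_set(parse_expression("a || b"), c("a b", "b a"))
  expect_trace_set(parse_expression("(a || b) . c"), c("a b c", "b a c"),
                   loop_bound = 1)
  expect_trace_set(parse_expression("a ?*"), c("a", "a a", "a a a"),
                   loop_bound = 3)
  # silent actions are elided, terminal actions appear in tail position
  expect_trace_set(parse_expression("a . GO . b . END"), "a b END")
  # recursion unrolls at most loop_bound times
  reg <- parse_program("define X = a + a . X ;")
  expect_identical(traces(px_ref("X"), reg, loop_bound = 3),
                   c("a", "a a", "a a a"))
  expect_error(traces(parse_expression("(a||b)||(c||d)"), max_states = 3),
               "state-space cap")
})

test_that("workflow pattern operators have their documented trace sets", {
  # multi-merge: continuation fires once per branch in every complete run
  mm <- traces(parse_expression("(a & b) . c"))
  expect_true(all(vapply(strsplit(mm, " "), function(s) sum(s == "c"), 1L) == 2L))
  # discriminator: continuation fires exactly once, after the first completion
  dc <- traces(parse_expression("(a ^ b) . c"))
  expect_identical(dc, sort(c("a c b", "a b c", "b c a", "b a c")))
  expect_true(all(vapply(strsplit(dc, " "), function(s) sum(s == "c"), 1L) == 1L))
  # interleaved parallel: the two no-overlap orders only
  expect_trace_set(parse_expression("a |* b"), c("a b", "b a"))
  expect_trace_set(parse_expression("(a . b) |* c"),
                   c("a b c", "c a b"))  # no overlap: "a c b" excluded
  # bare multi-merge / discriminator degenerate to parallel merge
  expect_trace_set(parse_expression("a & b"), c("a b", "b a"))
  expect_trace_set(parse_expression("a ^ b"), c("a b", "b a"))
})

test_that("guardedness validation accepts guarded and rejects unguarded recursion", {
  expect_silent(reg_validate(parse_program("define X = a + a . X ;")))
  expect_error(parse_program("define X = X + a ;"), "unguarded recursion")
  reg <- process_registry(list(A = px_seq(px_atom("a"), px_ref("A"))))
  expect_silent(reg_validate(reg))
  expect_error(reg_validate(process_registry(list(B = px_ref("C")))),
               "unresolved process reference")
  # nullable prefix does not guard: X ::= (a + ()) . X loops silently
  bad <- process_registry(list(X = px_seq(px_alt(px_atom("a"), px_nil()),
                                          px_ref("X"))))
  expect_error(reg_validate(bad), "unguarded recursion")
})

test_that("rewrite_extended eliminates extended operators and preserves traces", {
  r <- rewrite_extended(parse_expression("a ?3"))
  expect_identical(npdl_serialize(r$expr), "a . (a . a)")
  r2 <- rewrite_extended(parse_expression("a ?*"))
  expect_identical(r2$expr$kind, "name_ref")
  def <- reg_get(r2$registry, r2$expr$ref_name)
  expect_identical(npdl_serialize(def),
                   sprintf("a + a . %s", r2$expr$ref_name))
  expect_identical(traces(r2$expr, r2$registry, loop_bound = 3),
                   c("a", "a a", "a a a"))
  # ?f is replaced by ?* for analysis
  rf <- rewrite_extended(parse_expression("a ?f(n_repeats)"))
  expect_identical(traces(rf$expr, rf$registry, loop_bound = 2),
                   traces(parse_expression("a ?*"), loop_bound = 2))
  # discriminator/multi-merge/ipar with continuation
  for (src in c("(a & b) . c", "(a ^ b) . c", "a |* b", "(a . b |* c) . d")) {
    e <- parse_expression(src)
    rr <- rewrite_extended(e)
    expect_true(is_basic(rr$expr))
    expect_true(trace_equivalent(e, rr$expr, rr$registry, loop_bound = 2),
                label = paste("rewrite preserves traces of", src))
  }
  # guards preserved by default, stripped on request
  rg <- rewrite_extended(parse_expression("(a % r) ?2"))
  expect_identical(npdl_serialize(rg$expr), "a % r . a % r")
  rs <- rewrite_extended(parse_expression("(a % r) ?2"), strip_guards = TRUE)
  expect_identical(npdl_serialize(rs$expr), "a . a")
})

test_that("algebraic laws hold under trace equivalence (seeded random operands)", {
  for (i in 1:25) {
    a <- draw_law_operand(100 + i)
    b <- draw_law_operand(300 + i)
    cc <- draw_law_operand(500 + i)
    expect_true(trace_equivalent(px_alt(a, b), px_alt(b, a)))
    expect_true(trace_equivalent(px_alt(px_alt(a, b), cc), px_alt(a, px_alt(b, cc))))
    expect_true(trace_equivalent(px_alt(a, a), a))
    expect_true(trace_equivalent(px_par(a, b), px_par(b, a)))
    expect_true(trace_equivalent(px_par(px_par(a, b), cc), px_par(a, px_par(b, cc))))
    expect_true(trace_equivalent(px_seq(px_seq(a, b), cc), px_seq(a, px_seq(b, cc))))
    expect_true(trace_equivalent(px_seq(a, px_alt(b, cc)),
                                 px_alt(px_seq(a, b), px_seq(a, cc))))
  }
})

test_that("derivative walk and oracle agree on small expressions", {
  # every maximal enabled/step path yields an oracle trace and vice versa
  exprs <- list(parse_expression("(a || b) . c"),
                parse_expression("a . (b + c)"),
                parse_expression("(a ^ b) . c"),
                parse_expression("(a & b) . c"))
  for (e in exprs) {
    reached <- character(0)
    walk <- function(x, acc) {
      en <- enabled(x)
      if (terminated(x)) reached <<- c(reached, paste(acc, collapse = " "))
      for (i in seq_len(nrow(en))) {
        nxt <- step(x, en$path[[i]])
        lab <- if (en$kind[[i]] == "silent") acc else c(acc, en$action[[i]])
        walk(nxt, lab)
      }
    }
    walk(e, character(0))
    expect_setequal(unique(reached), traces(e))
  }
})

test_that("terminal-position validator flags misplaced END", {
  expect_silent(px_validate(parse_expression("(a || b) . END")))
  expect_error(px_validate(parse_expression("END . a")), "non-tail position")
  expect_error(px_validate(px_ref("nope")), "unresolved process reference")
})
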