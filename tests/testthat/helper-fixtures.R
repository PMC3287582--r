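# Shared fixtures: the SMA worked example and small property-test utilities.

sma_catalog <- function() {
  procedure_catalog(data.frame(
    name = c("DNA_extraction", "PCR_exon7", "PCR_exon8", "analysis"),
    description = c("extract DNA from patient sample", "PCR of SMN1 exon 7",
                    "PCR of SMN1 exon 8", "analyse PCR products"),
    technique = c("extraction", "PCR", "PCR", "analysis"),
    reagents = "primer;polymerase;buffer", stringsAsFactors = FALSE))
}

sma_def <- function() {
  test_definition("SMA", procedures = data.frame(
    name = c("PCR_exon7", "PCR_exon8"), order = c(1L, 1L)),
    description = "SMN1 exon 7/8 deletion screen",
    duration_days = 7, cost = 150)
}

sma_registry <- function() {
  reg <- process_registry()
  build_expression(sma_def(), reg, sma_catalog())
  reg
}

# Does the expression contain any extended (non-basic) operator?
has_extended <- function(e) {
  found <- FALSE
  rec <- function(x) {
    if (x$kind %in% c("ipar", "mmerge", "disc", "rep_star", "rep_n", "rep_f"))
      found <<- TRUE
    if (!is.null(x$left)) rec(x$left)
    if (!is.null(x$right)) rec(x$right)
  }
  rec(e)
  found
}

# Deterministically draw a random expression satisfying `accept`, skipping
# (by advancing the derived seed) draws that fail it or whose enumeration
# exceeds the state cap used by the caller.
draw_expression <- function(seed, accept = function(e) TRUE, ...) {
  s <- seed
  repeat {
    e <- gen_expression(s, ...)
    if (accept(e)) return(e)
    s <- s + 7919L
  }
}

expect_trace_set <- function(expr, expected, ...) {
  expect_identical(traces(expr, ...), sort(unique(expected)))
}

# Operand policy for algebraic-law checks: the continuation-scoped workflow
# operators & and ^ are context-sensitive at the top of a seq operand (that
# is what makes them workflow patterns rather than algebra operators), so law
# operands are drawn with compositional tops; the unrolled size bound keeps
# exhaustive interleaving enumeration well inside the caps.
draw_law_operand <- function(seed) {
  draw_expression(seed, max_depth = 2,
                  accept = function(e)
                    !e$kind %in% c("mmerge", "disc") && expr_size(e) <= 4)
}

# A law assertion that skips (returns NA) when exhaustive enumeration of a
# composed operand pair exceeds the caps; the caller counts checked cases.
law_holds <- function(x, y) {
  tryCatch(trace_equivalent(x, y, max_states = 20000, max_traces = 20000),
           error = function(err) NA)
}
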