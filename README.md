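# npdl — process-algebra workflow engine for genetic-testing management

`npdl` is a laboratory-information-management core for genetic-testing
laboratories, built on a small ACP-style process algebra. A test protocol —
which procedures to run, in what order, what may run in parallel, what must
succeed before the test is complete — is represented as a closed algebraic
expression. The engine interprets that expression to release work to
technicians, track per-sample execution, and decide when a test is done; a
bounded trace-enumeration oracle makes the algebraic claims checkable.

It is aimed at developers of process-aware LIMS and at anyone who wants a
small, fully testable reference implementation of workflow-pattern semantics
(sequence, choice, parallel merge, interleaved parallel routing, multi-merge,
discriminator, bounded/unbounded repetition, guarded execution) with an
executable equivalence checker.

## The core idea

End users define a test as procedures with execution-order numbers.
Procedures sharing an order run in parallel (`||`); ascending orders run in
sequence (`.`). Each procedure `p` compiles to

```
(p ?*) . (GO % ok_p)
```

— perform `p` at least once (repeatable as needed), then pass a silent gate
`GO` that opens only when `p`'s last recorded outcome is ok. The whole test
ends with the terminal action `END`, whose release marks completion. For the
spinal-muscular-atrophy (SMA) deletion screen — PCR of SMN1 exons 7 and 8,
both at order 1 — the compiler produces

```
(PCR_exon7 ?* . GO % ok_PCR_exon7 || PCR_exon8 ?* . GO % ok_PCR_exon8) . END
```

Observational equivalence is weak trace equivalence (silent `GO` elided):
`traces()` enumerates all complete traces with every loop unrolled at most
`loop_bound` times, and `trace_equivalent()` compares two expressions —
which is also how the package proves that `rewrite_extended()`, which
eliminates the extended operators in favour of `.`, `+`, `||` and recursion,
preserves meaning.

## Worked example

```r
library(npdl)

catalog <- procedure_catalog(c("PCR_exon7", "PCR_exon8"))
sma <- test_definition("SMA", procedures = data.frame(
  name = c("PCR_exon7", "PCR_exon8"), order = c(1, 1)))
reg <- process_registry()
built <- build_expression(sma, reg, catalog)
npdl_serialize(built$expr)
#> [1] "(PCR_exon7 ?* . GO % ok_PCR_exon7 || PCR_exon8 ?* . GO % ok_PCR_exon8) . END"

traces(built$expr, reg, loop_bound = 1)
#> [1] "PCR_exon7 PCR_exon8 END" "PCR_exon8 PCR_exon7 END"

inst <- instantiate("SMA", reg)
released(inst)$action                      # both PCRs released in parallel
#> [1] "PCR_exon7" "PCR_exon8"

report(inst, "PCR_exon7", "complete", "failed")
released(inst)$action                      # failed gate: exon 7 still on offer
#> [1] "PCR_exon7" "PCR_exon8"

report(inst, "PCR_exon8", "complete", "ok")
inst$lifecycle                             # END is gated on ok_PCR_exon7
#> [1] "running"

report(inst, "PCR_exon7", "complete", "ok")
inst$lifecycle                             # gates open, END auto-fires
#> [1] "finished"
tail(inst$log[, c("action", "status", "outcome")], 3)
#>      action        status outcome
#> 7 PCR_exon7     completed      ok
#> 8       END     completed      ok
#> 9       SMA test_finished    <NA>
```

The two trace strings are the only valid single-pass executions of the test:
either PCR first, then the other, then `END` exactly once at the tail. The
event log is event-sourced — replaying it on a fresh instance reproduces the
state bit-for-bit — and persists, together with patients, samples, orders
and work queues, in a file-backed relational store (`repo_new()`,
`work_queue()`; schema in `inst/sql/schema.sql`).

A command-line interface wrapping the same functions ships in
`inst/cli/npdl.R` (`define-test`, `order-test`, `queue --procedure "PCR*"`,
`report`, `traces`, `equiv`, `demo-sma`, ...); `demo_sma()` runs the whole
scenario above in one call.

## Package layout

- `R/expr.R`, `R/semantics.R`, `R/rewrite.R` — the algebra: AST,
  derivative semantics, bounded trace oracle, rewriting to basic operators.
- `R/parse.R`, `R/serialize.R` — the `.npdl` textual syntax.
- `R/engine.R`, `R/context.R` — instance lifecycle, rules/facts, event log.
- `R/builder.R` — user test definitions → canonical expressions.
- `R/repository.R` — relational store and the two work-queue views.
- `R/generators.R`, `R/cli.R`, `R/config.R` — synthetic workloads, CLI,
  configuration.
- `vignettes/process-algebra-workflows.Rmd` — the methods vignette: the
  algebra, the workflow-operator semantics and their limits, the engine's
  weak-transition treatment of silent actions, and the design decisions.
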