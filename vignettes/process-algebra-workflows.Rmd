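---
title: "Process-algebra workflows for genetic-testing management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Process-algebra workflows for genetic-testing management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npdl)
```

## The problem

A genetic-testing laboratory runs dozens of test types over thousands of
samples, with heavy parallelism (one thermal cycler runs many PCRs at once)
and constantly evolving protocols. Staff need to be told, per sample, which
procedure may run *now*; a procedure may have to be repeated when a run
fails; a test is complete only when every required step has succeeded. Ad
hoc status fields cannot guarantee that the recorded execution of a test
actually followed its protocol.

`npdl` treats each test protocol as a term of a small process algebra. The
control flow of a test is a closed expression over atomic actions (the
procedures); the engine *interprets* that expression to decide what is
released for execution, and a brute-force trace oracle makes the algebraic
claims checkable. End users never see the algebra: they define a test as a
list of procedures with execution-order numbers, and the compiler produces
the expression.

## The algebra

Expressions are built from atoms and the operators

| syntax | meaning |
|---|---|
| `a . b` | sequence: `a` then `b` |
| `a + b` | choice: one of the two |
| `a || b` | parallel merge: all interleavings |
| `a |* b` | interleaved parallel routing: either order, no overlap |
| `a & b` | multi-merge |
| `a ^ b` | discriminator |
| `e ?*` | repetition, one or more times |
| `e ?3` | exactly three sequential executions |
| `e ?f(g)` | `g` (a registered function of the instance facts) many times |
| `e % r`, `e %! r` | guarded execution: initial actions enabled iff rule `r` is true (false) |

Two action symbols are special: `GO` is silent — an internal "go on" marker
fired by the system and elided from traces — and `END` is terminal: its
release marks test completion and it may only occur at the tail of a trace
(a static validator checks this).

The semantics is derivative-style: `enabled()` lists the initial action
occurrences of an expression, `step()` returns the residual after consuming
one, and `terminated()` says whether all obligatory work is done. The
observational equivalence throughout is *weak trace equivalence*: two
expressions are equivalent when their sets of complete, silent-elided traces
coincide. Traces are what a laboratory observes; finer equivalences
(bisimulation, failures) are deliberately out of scope.

```{r}
e <- parse_expression("(PCR_exon7 || PCR_exon8) . END")
enabled(e)$action
traces(e)
```

### The bounded trace oracle

`traces()` is the package's independent referee: it enumerates every
complete trace after statically unrolling each repetition and each recursive
definition at most `loop_bound` times (default 2). Exhaustive interleaving
enumeration is exponential, so two caps bound the work: `max_states` (1e5)
on distinct residuals and `max_traces` (1e5) on the trace set held at any
residual; exceeding either is an error, never a silent truncation. Property
sweeps over random expressions skip — deterministically, by advancing the
derived seed — draws whose enumeration exceeds the caps, so every checked
draw is checked exhaustively.

Bounded unrolling treats `e ?*` as admitting 1..`loop_bound` passes and cuts
recursive definitions off after `loop_bound` expansions per name (the
truncated branch deadlocks and contributes no complete trace). Both sides of
an equivalence are bounded identically, which is what makes
`trace_equivalent()` a fair comparison.

### Workflow operators and their scope

The names multi-merge and discriminator come from the workflow-patterns
literature, and this package fixes their meaning as follows:

* `(l & r) . c` — each branch completion independently enables one
  execution of `c`: interpreted as `(l . c) || (r . c)`.
* `(l ^ r) . c` — the first branch completion enables `c` exactly once;
  the other branch runs to completion with its completion absorbed:
  interpreted as `((l . c) || r) + ((r . c) || l)` — all interleavings of
  `l`, `r`, `c` in which `c` starts after the first completion.
* Bare `l & r` / `l ^ r` (no sequential continuation) degenerate to
  `l || r`.

The continuation is the *syntactic* right operand of the enclosing `.` whose
left child is the `&`/`^` node. The interpreter applies these readings by
head normalisation inside `enabled`/`step`/`traces`, and `rewrite_extended()`
applies literally the same transformation, so the interpreter and the
rewriter cannot drift apart; their agreement is property-tested against the
oracle on hundreds of random expressions.

One consequence deserves emphasis: **continuation capture is
context-sensitive**, so `&` and `^` are workflow patterns, not algebra
operators. `((a & b) . c) . d` fires `c` twice and `d` once, while
`(a & b) . (c . d)` fires `c . d` twice — sequence is *not* associative
across a multi-merge top. The algebraic-law suite (commutativity,
associativity, idempotence of `+`; commutativity/associativity of `||`;
associativity of `.`; distributivity of `.` over `+`) therefore draws its
random operands with compositional top nodes (any operator may still occur
below the top) and with unrolled size at most 4, which also keeps the
worst-case multinomial interleaving counts of the associativity checks well
inside the enumeration caps.

### Rewriting to basic operators

`rewrite_extended()` eliminates every extended operator, yielding an
expression over `.`, `+`, `||` (plus guards, unless stripped) and recursion:

* `e ?n` unrolls to `n` copies; `e ?f(g)` is read as `e ?*` (to static
  analysis, function-limited repetition is unlimited repetition; the engine
  resolves `g` at instantiation instead — exactly once, against the initial
  facts).
* `e ?*` becomes a fresh guarded recursive definition `X ::= e + e . X`.
* `l |* r` becomes `(l . r) + (r . l)`. A recursive encoding is possible
  but pointless for a binary operator whose meaning is "the two orders":
  the alternative of the two sequencings is already basic and
  trace-equivalent by construction.
* `&`/`^` as above.

Soundness — equality of bounded trace sets before and after — is asserted on
500 seeded random expressions per run of the acceptance suite.

### Repetition semantics

`e ?*` is **one-or-more**: a laboratory procedure compiled into a test is
performed at least once; "repeat as needed" extends, never skips. This was a
genuinely open reading and is fixed package-wide (the rewrite
`X ::= e + e . X`, the oracle's 1..k unrolling, and the builder all agree).

## From user test definitions to expressions

A test definition is a set of `(procedure, execution_order)` items plus
metadata (description, duration in days, cost). Compilation groups items by
ascending order into groups `G1..Gk`; each procedure `p` becomes

```
(p ?*) . (GO % ok_p)
```

— `p` at least once, repeatable, followed by a silent gate that opens only
when `p`'s last outcome is ok. Groups compose with `||` inside and `.`
between, and the whole test ends with `. END`:

```{r}
catalog <- procedure_catalog(c("PCR_exon7", "PCR_exon8"))
sma <- test_definition("SMA", procedures = data.frame(
  name = c("PCR_exon7", "PCR_exon8"), order = c(1, 1)))
reg <- process_registry()
built <- build_expression(sma, reg, catalog)
npdl_serialize(built$expr)
traces(built$expr, reg, loop_bound = 1)
```

The `ok_<procedure>` rules are generated; registering a user rule of the
same name is an error. One gate is attached per procedure (not per group):
each procedure's success is assessed independently, which is what lets one
failed PCR hold the test open while its sibling is already done.

## The execution engine

`instantiate()` resolves `?f` nodes, validates guardedness and rule
bindings, and logs a released event per enabled procedure. Reports carry one
of four statuses — complete, repeat, cancel, finish — mirroring the
execution interface of the original laboratory system. `complete` consumes
the occurrence and records the outcome in the facts; `repeat` re-executes in
place (the residual is untouched; the execution count grows and the latest
outcome wins); `cancel` closes the test as canceled; `finish` closes it as
`finished` when the residual can terminate and as `forced_finished`
otherwise, preserving auditability of early closures.

Silent actions are handled by *weak transitions*: the released set is
computed over the whole silent closure of the residual, and a `GO` prefix is
committed only when the user's chosen action — or the terminal `END` —
actually requires it. This is what keeps a completed procedure repeatable
while its gate is already passable: the engine does not commit the "stop
repeating" choice on the user's behalf. `END` auto-fires as soon as it is
weakly enabled, closing the instance (open repeat options lapse at that
point — the test is complete). The closure is capped at `tau_cap` (default
10000) states. An instance whose residual is not terminated but enables
nothing is flagged `stuck` — with per-procedure `?*` wrapping this arises
only from genuinely unsatisfiable guards, since a gated procedure always
remains repeatable.

The event log is event-sourced: sequence numbers are gapless, timestamps
come from an injectable clock (a deterministic logical clock by default),
and replaying the user-driven events of a log on a fresh instance reproduces
residual, facts, lifecycle and log bit-for-bit.

## Persistence and work queues

The repository stores definitions (as reparsable text), the catalog, tests,
patients, samples, orders, instances and events as relational tables —
data.frames in memory, one CSV per table on disk, with referential-integrity
checks on insert and the equivalent SQL DDL shipped in `inst/sql/schema.sql`
for deployment against a server RDBMS. Work queues are a pure function of
persisted state: one row per released (instance, occurrence), joined to
patient/sample/order metadata, filterable by procedure (exact or prefix
wildcard `PCR*`) or by disease/test. The union of the disease-filtered
queues always equals the unfiltered queue; this partition property is
asserted in the test suite.

## Synthetic data

No external datasets exist for this domain, so the package generates its own
study material:

* `gen_expression()` draws random ASTs with per-operator weights (defaults:
  sequence-heavy, all operators present, depth 4) over a six-letter
  alphabet. It emulates the *shape* of protocol control flow, not wet-lab
  content.
* `gen_workload()` emulates a desk-scale testing routine: by default 5
  patients, 3 tests of up to 4 procedures in up to 3 order groups, at least
  one sample per patient, and orders referencing only generated tests. The
  first generated test always has two procedures at one order — the
  canonical two-PCR deletion screen — so every workload exercises the
  parallel-release path.
* `simulate_instance()` drives an instance with seeded repeat/fail
  probabilities until it terminates (or sticks, which is reported rather
  than raised).

Everything is seed-deterministic and leaves the caller's RNG state
untouched. What passing these tests does *not* show: real laboratories have
far larger catalogs, concurrent human writers (excluded by design:
single-writer per instance), and protocols whose structure drifts over
time in ways a stationary generator cannot emulate.

## Problem sizes and numerical choices

The property suites run at the sizes the package considers meaningful for
exhaustive checking: 500 random expressions for rewrite soundness and 500
random definitions for engine-oracle conformance (depth ≤ 4, unrolled
size-capped as above), 200 operand triples for the law suite, 1000 ASTs for
parser round-trips, loop bound 2 throughout (3 where a run's realised repeat
count demands it). Occurrence selection is deterministic: when one label is
enabled at several paths, the leftmost-innermost occurrence is consumed
unless a path is given explicitly. Dates and timestamps are ISO-8601 text;
config caps (`loop_bound`, `state_cap`, `tau_cap`) must be positive and
default as documented in `?npdl_config`.

## Known limitations

* Communication/synchronisation merge is not implemented: `||` is pure
  interleaving. The laboratory processes modelled here never communicate.
* `&` and `^` break sequential-context algebra (see above); rewrite them
  away before algebraic reasoning.
* Undefined names in program text parse as atoms — the grammar gives atoms
  and process names one lexical space — so "undefined reference" is only
  detectable for `name_ref` nodes built through the API, where
  `reg_validate()` names the dangling reference.
* Bounded trace enumeration is a verification aid, not a model checker:
  properties are certified up to the loop bound and the caps.
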