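# Operational semantics: enabled actions, derivatives (residuals),
# termination, and the bounded brute-force trace oracle.
#
# The semantics is derivative-style: moves(e) yields every initial action of e
# together with the residual expression left after consuming it. Workflow
# operators whose meaning involves the sequential continuation (multi-merge,
# discriminator) are handled by a head normalisation shared verbatim with the
# rewrite engine, so the interpreter and the rewriter cannot drift apart:
#
#   (l & r) . c  ==  (l . c) || (r . c)        continuation fires per branch
#   (l ^ r) . c  ==  ((l . c) || r) + ((r . c) || l)
#                                              c starts after first completion
#   l & r, l ^ r (no continuation)  ==  l || r
#   e ?f(name)   ==  e ?*           for static analysis
#
# The discriminator form reads: all interleavings of l, r and c in which c
# begins after at least one branch has completed.

norm_head <- function(e) {
  if (e$kind == "seq") {
    l <- e$left
    if (l$kind == "mmerge")
      return(px_par(px_seq(l$left, e$right), px_seq(l$right, e$right)))
    if (l$kind == "disc")
      return(px_alt(px_par(px_seq(l$left, e$right), l$right),
                    px_par(px_seq(l$right, e$right), l$left)))
    return(e)
  }
  if (e$kind %in% c("mmerge", "disc")) return(px_par(e$left, e$right))
  if (e$kind == "rep_f") return(px_star(e$left))
  e
}

# A bare multi-merge/discriminator reads as plain parallel merge. Internal
# constructions (residuals, unrollings) must fix that reading explicitly, so
# a subterm whose continuation scope was already decided can never drift into
# seq-left position and capture a new continuation.
depar <- function(e) {
  if (e$kind %in% c("mmerge", "disc")) px_par(e$left, e$right) else e
}

# Unit simplifications keep residuals readable; they do not change traces.
# Unwrapping may expose an operand to a new syntactic context, hence depar.
seq_simpl <- function(l, r) {
  if (l$kind == "nil") depar(r) else if (r$kind == "nil") depar(l)
  else px_seq(l, r)
}
par_simpl <- function(l, r) {
  if (l$kind == "nil") depar(r) else if (r$kind == "nil") depar(l)
  else px_par(l, r)
}

# Successful-termination predicate on raw expressions. Guard nodes require
# the rule to hold (a blocked guard over a nullable body cannot silently
# complete). Recursion through the registry terminates because guarded
# definitions always pass through an atom (non-nullable prefix) before
# re-entering a name, and && short-circuits there.
can_term <- function(e, reg = NULL, ctx = NULL, depth = 0L) {
  if (depth > 500L)
    stop("recursion too deep in termination check (unguarded definition?)",
         call. = FALSE)
  e <- norm_head(e)
  switch(e$kind,
    nil = TRUE,
    dead = FALSE,
    atom = FALSE,
    name_ref = can_term(def_of(reg, e$ref_name), reg, ctx, depth + 1L),
    seq = can_term(e$left, reg, ctx, depth) && can_term(e$right, reg, ctx, depth),
    alt = can_term(e$left, reg, ctx, depth) || can_term(e$right, reg, ctx, depth),
    par = ,
    ipar = can_term(e$left, reg, ctx, depth) && can_term(e$right, reg, ctx, depth),
    rep_star = ,
    rep_n = can_term(e$left, reg, ctx, depth),
    guard = rule_holds(ctx, e$rule) && can_term(e$left, reg, ctx, depth),
    stop("unknown kind ", e$kind)
  )
}

def_of <- function(reg, name) {
  if (is.null(reg)) stop(sprintf("unresolved process reference '%s'", name),
                         call. = FALSE)
  reg_get(reg, name)
}

rule_holds <- function(ctx, rule) {
  if (is.null(ctx)) ctx <- const_context()
  ctx_rule(ctx, rule$name, rule$negated)
}

mv <- function(symbol, path, residual) list(symbol = symbol, path = path,
                                            residual = residual)

prefix_moves <- function(ms, pre) {
  lapply(ms, function(m) { m$path <- paste0(pre, m$path); m })
}

# All single-step derivatives of e: list of (symbol, path, residual). Paths
# identify occurrences within the derivation; the list order is the engine's
# leftmost-innermost default.
moves <- function(e, reg = NULL, ctx = NULL, depth = 0L) {
  if (depth > 2000L)
    stop("recursion too deep while computing enabled actions", call. = FALSE)
  e <- norm_head(e)
  switch(e$kind,
    nil = ,
    dead = list(),
    atom = list(mv(e$symbol, "a", px_nil())),
    name_ref = prefix_moves(moves(def_of(reg, e$ref_name), reg, ctx, depth + 1L),
                            paste0("@", e$ref_name, "/")),
    seq = {
      out <- lapply(moves(e$left, reg, ctx, depth + 1L), function(m) {
        m$residual <- seq_simpl(m$residual, e$right)
        m$path <- paste0("1/", m$path)
        m
      })
      if (can_term(e$left, reg, ctx))
        out <- c(out, prefix_moves(moves(e$right, reg, ctx, depth + 1L), "2/"))
      out
    },
    alt = c(prefix_moves(moves(e$left, reg, ctx, depth + 1L), "L/"),
            prefix_moves(moves(e$right, reg, ctx, depth + 1L), "R/")),
    par = {
      lm <- lapply(moves(e$left, reg, ctx, depth + 1L), function(m) {
        m$residual <- par_simpl(m$residual, e$right)
        m$path <- paste0("L/", m$path)
        m
      })
      rm_ <- lapply(moves(e$right, reg, ctx, depth + 1L), function(m) {
        m$residual <- par_simpl(e$left, m$residual)
        m$path <- paste0("R/", m$path)
        m
      })
      c(lm, rm_)
    },
    ipar = {
      # no-overlap interleaved routing: the branch that moves first runs to
      # completion before the other may start
      lm <- lapply(moves(e$left, reg, ctx, depth + 1L), function(m) {
        m$residual <- seq_simpl(m$residual, e$right)
        m$path <- paste0("L/", m$path)
        m
      })
      rm_ <- lapply(moves(e$right, reg, ctx, depth + 1L), function(m) {
        m$residual <- seq_simpl(m$residual, e$left)
        m$path <- paste0("R/", m$path)
        m
      })
      c(lm, rm_)
    },
    rep_star = {
      # one-or-more: after a first pass through the body, continuing is
      # optional (alt with the terminated process)
      lapply(moves(e$left, reg, ctx, depth + 1L), function(m) {
        m$residual <- seq_simpl(m$residual, px_alt(px_nil(), px_star(e$left)))
        m$path <- paste0("*/", m$path)
        m
      })
    },
    rep_n = {
      if (e$n == 1L) prefix_moves(moves(e$left, reg, ctx, depth + 1L), "#/")
      else prefix_moves(
        moves(px_seq(depar(e$left), px_rep(e$left, e$n - 1L)), reg, ctx,
              depth + 1L), "#/")
    },
    guard = {
      if (rule_holds(ctx, e$rule))
        prefix_moves(moves(e$left, reg, ctx, depth + 1L), "%/")
      else list()
    },
    stop("unknown kind ", e$kind)
  )
}

#' Enabled actions of a process expression
#'
#' The initial actions executable now, with occurrence paths disambiguating
#' identical labels in different branches. A guarded action is included iff
#' its rule currently evaluates true (negated guards: iff false); guards are
#' re-evaluated on every call.
#'
#' @param expr an \code{npdl_expr}.
#' @param registry a \code{\link{process_registry}} resolving any
#'   \code{name_ref}; may be omitted for closed expressions.
#' @param ctx an \code{\link{eval_context}}; defaults to a context in which
#'   every rule is true.
#' @return a data.frame with columns \code{action}, \code{kind}
#'   (regular/silent/terminal) and \code{path}, in leftmost-innermost order.
#' @examples
#' enabled(parse_expression("a . b"))$action
#' enabled(parse_expression("a || b"))$action
#' @export
enabled <- function(expr, registry = NULL, ctx = NULL) {
  ms <- moves(expr, registry, ctx)
  data.frame(
    action = vapply(ms, function(m) m$symbol$name, character(1)),
    kind = vapply(ms, function(m) m$symbol$kind, character(1)),
    path = vapply(ms, function(m) m$path, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Consume one enabled occurrence and return the residual expression
#'
#' @inheritParams enabled
#' @param path an occurrence path as returned by \code{\link{enabled}}, or an
#'   action name (the leftmost-innermost occurrence of that action is taken).
#' @return the unique residual \code{npdl_expr}.
#' @examples
#' npdl_serialize(step(parse_expression("(a || b) . c"), "b"))
#' @export
step <- function(expr, path, registry = NULL, ctx = NULL) {
  ms <- moves(expr, registry, ctx)
  paths <- vapply(ms, function(m) m$path, character(1))
  i <- match(path, paths)
  if (is.na(i)) {
    # fall back: treat `path` as an action label, take leftmost occurrence
    labels <- vapply(ms, function(m) m$symbol$name, character(1))
    i <- match(path, labels)
  }
  if (is.na(i))
    stop(sprintf("occurrence '%s' is not currently enabled", path), call. = FALSE)
  ms[[i]]$residual
}

#' Successful termination predicate
#'
#' \code{TRUE} iff the process can be considered successfully completed with
#' no obligatory work remaining (optional work, such as further repetitions
#' of a \code{?*} body already executed once, does not block termination).
#'
#' @inheritParams enabled
#' @return logical.
#' @export
terminated <- function(expr, registry = NULL, ctx = NULL) {
  can_term(expr, registry, ctx)
}

# ---- bounded trace enumeration (the brute-force oracle) ----------------

# Replace every unbounded construct by a finite unrolling: rep_star by a
# chain admitting 1..k passes, name_refs by inline expansion with a per-name
# budget of k (exhausted budget becomes the deadlocked process, pruning any
# would-be longer trace). The result is enumerable by exhaustive DFS.
bound_expr <- function(e, reg, k, budgets) {
  switch(e$kind,
    nil = ,
    dead = ,
    atom = e,
    name_ref = {
      b <- budgets[[e$ref_name]] %||% k
      if (b <= 0L) px_dead()
      else {
        budgets[[e$ref_name]] <- b - 1L
        bound_expr(def_of(reg, e$ref_name), reg, k, budgets)
      }
    },
    rep_star = {
      body <- bound_expr(e$left, reg, k, budgets)
      out <- body
      if (k > 1L) for (i in seq_len(k - 1L))
        out <- px_seq(depar(body), px_alt(px_nil(), out))
      out
    },
    rep_f = bound_expr(px_star(e$left), reg, k, budgets),
    rep_n = px_rep(bound_expr(e$left, reg, k, budgets), e$n),
    guard = px_guard(bound_expr(e$left, reg, k, budgets), e$rule$name,
                     negated = e$rule$negated),
    {
      e$left <- bound_expr(e$left, reg, k, budgets)
      e$right <- bound_expr(e$right, reg, k, budgets)
      e
    }
  )
}

#' Bounded enumeration of complete traces
#'
#' The brute-force oracle: enumerates every complete trace of \code{expr}
#' reachable when each unbounded repetition and each recursive definition is
#' unrolled at most \code{loop_bound} times. Silent (\code{GO}) actions are
#' elided; terminal actions appear. Traces are returned as strings of
#' space-separated action names (the empty trace is \code{""}); only runs
#' that reach successful termination contribute (a guard-blocked or
#' deadlocked branch yields nothing).
#'
#' @inheritParams enabled
#' @param loop_bound positive integer unroll bound (default 2).
#' @param max_states cap on distinct residual states visited (default 1e5);
#'   exceeding it is an error.
#' @param max_traces cap on the number of distinct trace suffixes held at any
#'   residual (default 1e5); exceeding it is an error. Both caps guard
#'   against the exponential blow-up inherent to exhaustive interleaving
#'   enumeration.
#' @return sorted character vector of distinct complete traces.
#' @examples
#' traces(parse_expression("a || b"))
#' traces(parse_expression("a ?*"), loop_bound = 3)
#' @export
traces <- function(expr, registry = NULL, loop_bound = 2L, ctx = NULL,
                   max_states = 1e5, max_traces = 1e5) {
  stopifnot(loop_bound >= 1L)
  if (!is.null(registry)) reg_validate(registry, expr)
  b <- bound_expr(expr, registry, as.integer(loop_bound), list())
  memo <- new.env(parent = emptyenv())
  nstates <- 0L
  # T(e): set of complete trace suffixes from e, memoised on the canonical key
  suffixes <- function(e) {
    key <- expr_key(e)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    nstates <<- nstates + 1L
    if (nstates > max_states)
      stop(sprintf("state-space cap exceeded (%d residuals); raise max_states",
                   as.integer(max_states)), call. = FALSE)
    out <- if (can_term(e, NULL, ctx)) "" else character(0)
    for (m in moves(e, NULL, ctx)) {
      tails <- suffixes(m$residual)
      if (length(tails)) {
        if (m$symbol$kind == "silent") out <- c(out, tails)
        else out <- c(out, ifelse(tails == "", m$symbol$name,
                                  paste(m$symbol$name, tails)))
      }
    }
    out <- unique(out)
    if (length(out) > max_traces)
      stop(sprintf("trace-set cap exceeded (%d traces at one residual)",
                   as.integer(max_traces)), call. = FALSE)
    assign(key, out, envir = memo)
    out
  }
  sort(suffixes(b))
}

#' Trace equivalence at a loop bound
#'
#' Two expressions are trace-equivalent at bound \code{k} iff their sets of
#' complete, silent-elided traces coincide when every repetition/recursion is
#' unrolled at most \code{k} times. This is the observational equivalence the
#' package uses for all algebraic-law and rewrite-soundness checks.
#'
#' @param e1,e2 expressions.
#' @inheritParams traces
#' @return logical.
#' @examples
#' trace_equivalent(parse_expression("a + b"), parse_expression("b + a"))
#' trace_equivalent(parse_expression("a . b"), parse_expression("b . a"))
#' @export
trace_equivalent <- function(e1, e2, registry = NULL, loop_bound = 2L,
                             ctx = NULL, max_states = 1e5, max_traces = 1e5) {
  identical(traces(e1, registry, loop_bound, ctx, max_states, max_traces),
            traces(e2, registry, loop_bound, ctx, max_states, max_traces))
}

#' Static validation of an expression
#'
#' Checks (1) resolution and guardedness via \code{\link{reg_validate}} and
#' (2) the terminal-position invariant: a terminal action (\code{END}) may
#' only occur in tail position of a trace, verified on the bounded trace set.
#'
#' @inheritParams traces
#' @return invisibly \code{TRUE}; errors describe the violation.
#' @export
px_validate <- function(expr, registry = NULL, loop_bound = 2L) {
  if (!is.null(registry)) reg_validate(registry, expr) else {
    refs <- expr_refs(expr)
    if (length(refs))
      stop(sprintf("unresolved process reference(s): %s",
                   paste(refs, collapse = ", ")), call. = FALSE)
  }
  if (length(expr_atoms(expr, "terminal"))) {
    for (tr in traces(expr, registry, loop_bound)) {
      steps <- strsplit(tr, " ", fixed = TRUE)[[1L]]
      at <- which(steps == "END")
      if (length(at) > 1L || (length(at) == 1L && at != length(steps)))
        stop(sprintf("terminal action END in non-tail position in trace '%s'", tr),
             call. = FALSE)
    }
  }
  invisible(TRUE)
}
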