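#' Seeded random process expressions
#'
#' Generates structurally valid random expressions for property-based
#' testing: everything the algebra supports except unguarded recursion
#' (generated expressions are closed, so guardedness holds trivially).
#' Identical arguments yield identical output; the caller's RNG state is
#' untouched.
#'
#' @param seed integer seed.
#' @param max_depth maximum AST depth (0 = a single atom).
#' @param alphabet atom labels to draw from.
#' @param weights named numeric vector of operator weights; names from
#'   \code{seq, alt, par, ipar, mmerge, disc, rep_star, rep_n, rep_f, guard}.
#'   Operators with weight 0 never occur.
#' @param rules rule names guards may use (all true in the oracle's default
#'   context).
#' @param funcs function names \code{?f} may use.
#' @return an \code{npdl_expr}.
#' @examples
#' e <- gen_expression(1, max_depth = 3)
#' npdl_serialize(e)
#' px_equal(e, gen_expression(1, max_depth = 3))
#' @export
gen_expression <- function(seed, max_depth = 4,
                           alphabet = letters[1:6],
                           weights = c(seq = 3, alt = 2, par = 1.5, ipar = 1,
                                       mmerge = 1, disc = 1, rep_star = 0.8,
                                       rep_n = 0.8, rep_f = 0.4, guard = 0.8),
                           rules = c("r1", "r2"),
                           funcs = c("n_repeats")) {
  stopifnot(length(alphabet) > 0L, max_depth >= 0L)
  with_seed(seed, gen_expr_rec(max_depth, alphabet, weights, rules, funcs))
}

gen_expr_rec <- function(depth, alphabet, weights, rules, funcs) {
  if (depth <= 0L || stats::runif(1) < 0.3)
    return(px_atom(sample(alphabet, 1L)))
  op <- sample(names(weights), 1L, prob = weights)
  l <- gen_expr_rec(depth - 1L, alphabet, weights, rules, funcs)
  switch(op,
    seq = px_seq(l, gen_expr_rec(depth - 1L, alphabet, weights, rules, funcs)),
    alt = px_alt(l, gen_expr_rec(depth - 1L, alphabet, weights, rules, funcs)),
    par = px_par(l, gen_expr_rec(depth - 1L, alphabet, weights, rules, funcs)),
    ipar = px_ipar(l, gen_expr_rec(depth - 1L, alphabet, weights, rules, funcs)),
    mmerge = px_mmerge(l, gen_expr_rec(depth - 1L, alphabet, weights, rules, funcs)),
    disc = px_disc(l, gen_expr_rec(depth - 1L, alphabet, weights, rules, funcs)),
    rep_star = px_star(l),
    rep_n = px_rep(l, sample(2:3, 1L)),
    rep_f = px_frep(l, sample(funcs, 1L)),
    guard = px_guard(l, sample(rules, 1L),
                     negated = stats::runif(1) < 0.25)
  )
}

#' Seeded synthetic laboratory workload
#'
#' Emulates a genetic-testing routine at desk scale: a procedure catalog, a
#' set of test definitions (procedures grouped into execution-order groups,
#' the first generated test shaped like the SMA example: two procedures at
#' the same order), patients, one or more DNA samples per patient, and test
#' orders referencing only generated tests. The dataset is referentially
#' consistent and loadable into a repository; identical seeds give identical
#' output.
#'
#' @param seed integer seed.
#' @param n_patients,n_tests counts (at least 1).
#' @param max_procedures_per_test,max_order_groups shape limits.
#' @return list with \code{catalog}, \code{tests} (list of
#'   \code{npdl_test_def}), \code{patients}, \code{samples}, \code{orders}
#'   data.frames.
#' @export
gen_workload <- function(seed, n_patients = 5, n_tests = 3,
                         max_procedures_per_test = 4, max_order_groups = 3) {
  stopifnot(n_patients >= 1, n_tests >= 1)
  with_seed(seed, {
    n_proc <- max(4L, 2L * n_tests)
    proc_names <- sprintf("PROC_%02d", seq_len(n_proc))
    proc_names[1:2] <- c("PCR_exon7", "PCR_exon8")
    catalog <- procedure_catalog(data.frame(
      name = proc_names,
      description = sprintf("synthetic procedure %d", seq_len(n_proc)),
      technique = sample(c("PCR", "sequencing", "DHPLC", "extraction"),
                         n_proc, replace = TRUE),
      reagents = "primer;polymerase;buffer", stringsAsFactors = FALSE))
    tests <- vector("list", n_tests)
    for (t in seq_len(n_tests)) {
      if (t == 1L) {
        items <- data.frame(name = c("PCR_exon7", "PCR_exon8"), order = c(1L, 1L))
      } else {
        k <- sample(seq_len(min(max_procedures_per_test, n_proc)), 1L)
        nms <- sample(proc_names, k)
        items <- data.frame(
          name = nms,
          order = sort(sample(seq_len(max_order_groups), k, replace = TRUE)))
      }
      tests[[t]] <- test_definition(
        sprintf("TEST_%02d", t), procedures = items,
        description = sprintf("synthetic test %d", t),
        duration_days = sample(1:30, 1L), cost = round(stats::runif(1, 50, 500), 2))
    }
    patients <- data.frame(number = seq_len(n_patients),
                           name = sprintf("Patient %03d", seq_len(n_patients)),
                           stringsAsFactors = FALSE)
    n_samples <- n_patients + sample(0:n_patients, 1L)
    samples <- data.frame(
      dna_number = sprintf("DNA%04d", seq_len(n_samples)),
      patient = c(seq_len(n_patients),
                  sample(seq_len(n_patients), n_samples - n_patients,
                         replace = TRUE)),
      stringsAsFactors = FALSE)
    orders <- data.frame(
      id = seq_len(n_samples),
      sample = samples$dna_number,
      test = sprintf("TEST_%02d", sample(seq_len(n_tests), n_samples,
                                         replace = TRUE)),
      request_date = sprintf("2020-01-%02d", sample(1:28, n_samples,
                                                    replace = TRUE)),
      stringsAsFactors = FALSE)
    list(catalog = catalog, tests = tests, patients = patients,
         samples = samples, orders = orders)
  })
}

#' Load a generated workload into a repository
#'
#' @param repo an \code{npdl_repo}.
#' @param workload a list from \code{\link{gen_workload}}.
#' @param registry registry the compiled tests are registered into.
#' @return the repository, invisibly.
#' @export
repo_load_workload <- function(repo, workload, registry) {
  repo_add_catalog(repo, workload$catalog)
  for (td in workload$tests) repo_add_test(repo, td, registry)
  for (i in seq_len(nrow(workload$patients)))
    repo_add_patient(repo, workload$patients$number[[i]],
                     workload$patients$name[[i]])
  for (i in seq_len(nrow(workload$samples)))
    repo_add_sample(repo, workload$samples$dna_number[[i]],
                    workload$samples$patient[[i]])
  for (i in seq_len(nrow(workload$orders)))
    repo_add_order(repo, workload$orders$id[[i]], workload$orders$sample[[i]],
                   workload$orders$test[[i]], workload$orders$request_date[[i]])
  invisible(repo)
}

#' Drive an instance with a random execution policy
#'
#' At each step a uniformly random released occurrence is chosen and, with
#' the given probabilities, first repeated (up to \code{repeat_cap}
#' consecutive repeats) and then completed with outcome failed or ok. Runs
#' until the instance leaves the running lifecycle or \code{max_steps}
#' completions have occurred. Stuck instances are reported in the result,
#' never raised.
#'
#' @param inst a running \code{npdl_instance}.
#' @param seed policy seed.
#' @param p_repeat probability of repeating a drawn procedure before
#'   completing it.
#' @param p_fail probability a completion reports outcome failed; may also be
#'   a named vector of per-procedure probabilities (default applies to
#'   unnamed procedures).
#' @param repeat_cap maximum consecutive repeats of one draw.
#' @param max_steps cap on completions.
#' @return list with \code{lifecycle}, \code{log}, \code{steps} (the
#'   completed action names in order) and \code{stuck} flag.
#' @export
simulate_instance <- function(inst, seed, p_repeat = 0, p_fail = 0,
                              repeat_cap = 3L, max_steps = 200L) {
  with_seed(seed, {
    steps <- character(0)
    n <- 0L
    while (inst$lifecycle == "running" && n < max_steps) {
      rel <- released(inst)
      if (!nrow(rel)) break
      i <- sample.int(nrow(rel), 1L)
      act <- rel$action[[i]]
      pf <- if (length(p_fail) > 1L || !is.null(names(p_fail)))
        unname(p_fail[act] %||% 0) else p_fail
      if (is.na(pf)) pf <- 0
      reps <- 0L
      while (stats::runif(1) < p_repeat && reps < repeat_cap) {
        report(inst, act, "repeat", outcome = "failed")
        reps <- reps + 1L
      }
      outcome <- if (stats::runif(1) < pf) "failed" else "ok"
      report(inst, act, "complete", outcome, path = rel$path[[i]])
      steps <- c(steps, act)
      n <- n + 1L
    }
    list(lifecycle = inst$lifecycle, log = inst$log, steps = steps,
         stuck = identical(inst$lifecycle, "stuck"))
  })
}
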