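#' Process instances: instantiation, release, and status reports
#'
#' A process instance is one running test for one sample: a residual
#' expression, an evaluation context of accumulated facts, a lifecycle state
#' and an event-sourced log. The engine analyses the residual after every
#' report to decide which procedures are released next.
#'
#' Silent (\code{GO}) actions are the system's job: they never appear in the
#' work queue or the log, and the engine treats them as weak transitions —
#' released steps are computed over the whole silent closure of the residual
#' (capped at \code{tau_cap} states), and a silent prefix is committed only
#' when the user's chosen step, or the terminal action, requires it. This
#' keeps optional repetitions open: completing one SMA PCR leaves both that
#' procedure (repeatable) and the other PCR released, because the GO gate is
#' not forced until the instance actually needs it. A terminal (\code{END})
#' action fires automatically as soon as it is weakly enabled — its release
#' marks test completion — which forecloses any still-open optional
#' repetitions at that point.
#'
#' @name engine
NULL

RUNNING_STATES <- c("running", "stuck")

new_instance <- function(id, def_name, def_version, residual, ctx, clock) {
  inst <- new.env(parent = emptyenv())
  inst$id <- id
  inst$def_name <- def_name
  inst$def_version <- def_version
  inst$residual <- residual
  inst$ctx <- ctx
  inst$lifecycle <- "running"
  inst$clock <- clock
  inst$log <- data.frame(seq = integer(0), action = character(0),
                         status = character(0), outcome = character(0),
                         timestamp = character(0), stringsAsFactors = FALSE)
  inst$released_before <- character(0)  # (action|path) keys already announced
  class(inst) <- "npdl_instance"
  inst
}

log_event <- function(inst, action, status, outcome = NA_character_) {
  if (!inst$lifecycle %in% RUNNING_STATES)
    stop("no events may be appended to a ", inst$lifecycle, " instance",
         call. = FALSE)
  inst$log <- rbind(inst$log, data.frame(
    seq = nrow(inst$log) + 1L, action = action, status = status,
    outcome = outcome, timestamp = inst$clock(), stringsAsFactors = FALSE))
  invisible(inst)
}

# Silent closure: every residual reachable through silent (GO) steps alone,
# in BFS/leftmost order, each paired with the silent route that reaches it.
# Guards are evaluated against the current facts as the closure is built.
silent_closure <- function(expr, registry, ctx, tau_cap = 10000L) {
  states <- list(list(expr = expr, route = character(0)))
  seen <- expr_key(expr)
  i <- 1L
  while (i <= length(states)) {
    cur <- states[[i]]
    en <- enabled(cur$expr, registry, ctx)
    sil <- which(en$kind == "silent")
    for (j in sil) {
      nxt <- step(cur$expr, en$path[[j]], registry, ctx)
      key <- expr_key(nxt)
      if (!key %in% seen) {
        seen <- c(seen, key)
        if (length(seen) > tau_cap)
          stop(sprintf("silent-step cap exceeded (%d reachable silent states)",
                       tau_cap), call. = FALSE)
        states[[length(states) + 1L]] <-
          list(expr = nxt, route = c(cur$route, en$path[[j]]))
      }
    }
    i <- i + 1L
  }
  states
}

# Weakly enabled user-visible occurrences: regular and terminal actions
# enabled in any silent-closure state. Within one state every occurrence is
# listed; across states an action label already seen is not re-listed (the
# earliest — least committed — state wins, so firing a silent prefix is
# deferred until the user's choice requires it).
weak_enabled <- function(expr, registry, ctx, tau_cap = 10000L) {
  out <- data.frame(action = character(0), kind = character(0),
                    path = character(0), stringsAsFactors = FALSE)
  can_finish <- FALSE
  for (st in silent_closure(expr, registry, ctx, tau_cap)) {
    if (can_term(st$expr, registry, ctx)) can_finish <- TRUE
    en <- enabled(st$expr, registry, ctx)
    en <- en[en$kind != "silent", , drop = FALSE]
    if (!nrow(en)) next
    en$path <- vapply(en$path, function(p)
      paste(c(st$route, p), collapse = " "), character(1))
    new <- !(en$action %in% out$action)
    out <- rbind(out, en[new, , drop = FALSE])
  }
  attr(out, "can_finish") <- can_finish
  out
}

# Apply a weak route: the silent prefix followed by the chosen occurrence.
step_weak <- function(expr, route, registry, ctx) {
  for (p in strsplit(route, " ", fixed = TRUE)[[1L]])
    expr <- step(expr, p, registry, ctx)
  expr
}

# Settle the instance after instantiation or a completion: auto-fire any
# weakly enabled terminal action (END's release marks test completion), log
# newly released occurrences and set the lifecycle.
auto_advance <- function(inst, registry, tau_cap = 10000L) {
  repeat {
    en <- weak_enabled(inst$residual, registry, inst$ctx, tau_cap)
    term <- which(en$kind == "terminal")
    if (length(term)) {
      i <- term[[1L]]
      inst$residual <- step_weak(inst$residual, en$path[[i]], registry, inst$ctx)
      log_event(inst, en$action[[i]], "completed", "ok")
      next
    }
    break
  }
  user <- en[en$kind == "regular", , drop = FALSE]
  # release announcements are per action-name multiset: a label is announced
  # again only when the number of its released occurrences grows
  now <- table(user$action)
  before <- table(inst$released_before)
  for (nm in names(now)) {
    extra <- now[[nm]] - (if (nm %in% names(before)) before[[nm]] else 0L)
    if (extra > 0L) for (j in seq_len(extra)) log_event(inst, nm, "released")
  }
  inst$released_before <- user$action
  if (nrow(user) == 0L) {
    if (isTRUE(attr(en, "can_finish"))) {
      log_event(inst, inst$def_name, "test_finished")
      inst$lifecycle <- "finished"
    } else {
      inst$lifecycle <- "stuck"
    }
  } else {
    inst$lifecycle <- "running"
  }
  invisible(inst)
}

#' Instantiate a process definition
#'
#' Looks the definition up in the registry, validates guardedness, resolves
#' every function-limited repetition \code{?f(g)} to a fixed count \code{?n}
#' by evaluating \code{g} once against the initial facts, performs silent
#' auto-advance and logs a released event for every enabled user action.
#'
#' @param def_name name of a definition in \code{registry}.
#' @param registry a \code{\link{process_registry}}.
#' @param ctx an \code{\link{eval_context}} (or \code{NULL} for an empty one);
#'   supplies initial facts plus the rule and function registries.
#' @param id instance identifier (default derived from the definition name).
#' @param clock zero-argument function returning an ISO-8601 timestamp; the
#'   default is a deterministic logical clock so runs are reproducible.
#' @param tau_cap cap on consecutive silent steps.
#' @return an object of class \code{npdl_instance}.
#' @examples
#' reg <- process_registry()
#' catalog <- procedure_catalog(c("PCR_exon7", "PCR_exon8"))
#' def <- test_definition("SMA", procedures = data.frame(
#'   name = c("PCR_exon7", "PCR_exon8"), order = c(1, 1)))
#' build_expression(def, reg, catalog)
#' inst <- instantiate("SMA", reg)
#' released(inst)
#' @export
instantiate <- function(def_name, registry, ctx = NULL, id = NULL,
                        clock = logical_clock(), tau_cap = 10000L) {
  expr <- reg_get(registry, def_name)
  reg_validate(registry, expr)
  if (is.null(ctx)) ctx <- eval_context()
  ctx_check_rules(ctx, expr_rules(expr))
  # generated completion rules (ok_<procedure>) must not be shadowed by
  # user-registered rules of the same name
  gen <- intersect(expr_rules(expr), paste0("ok_", expr_atoms(expr, "regular")))
  clash <- intersect(gen, names(ctx$rules))
  if (length(clash))
    stop(sprintf("user rule name(s) collide with generated completion rules: %s",
                 paste(clash, collapse = ", ")), call. = FALSE)
  # resolve ?f once, at instantiation, against the initial facts
  expr <- expr_map(expr, function(e) {
    if (e$kind == "rep_f") px_rep(e$left, ctx_func(ctx, e$func_name)) else e
  })
  inst <- new_instance(id %||% paste0(def_name, "-1"), def_name,
                       reg_version(registry, def_name), expr, ctx, clock)
  inst$registry <- registry
  inst$tau_cap <- as.integer(tau_cap)
  auto_advance(inst, registry, tau_cap)
  inst
}

#' Released user steps of an instance
#'
#' The currently enabled regular actions (silent actions are auto-advanced,
#' never shown). Guards are re-evaluated against the current facts on every
#' call.
#'
#' @param inst an \code{npdl_instance}.
#' @return a data.frame with columns \code{action} and \code{path}; empty for
#'   finished/canceled/stuck instances.
#' @export
released <- function(inst) {
  if (!inst$lifecycle %in% RUNNING_STATES)
    return(data.frame(action = character(0), path = character(0),
                      stringsAsFactors = FALSE))
  en <- weak_enabled(inst$residual, inst$registry, inst$ctx,
                     inst$tau_cap %||% 10000L)
  out <- en[en$kind == "regular", c("action", "path"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Report the execution status of a procedure
#'
#' The four Fig-3-style statuses:
#' \describe{
#'   \item{complete}{the action (which must be released) is consumed, the
#'     outcome is recorded in the facts, silent auto-advance runs and new
#'     releases are logged.}
#'   \item{repeat}{the residual is unchanged; the execution count is
#'     incremented, the outcome recorded, and the action stays released.}
#'   \item{cancel}{the whole test is canceled.}
#'   \item{finish}{the test is closed: \code{finished} if the residual is
#'     terminated, else \code{forced_finished} (auditable early closure).}
#' }
#'
#' @param inst an \code{npdl_instance}.
#' @param action action name (required for complete/repeat).
#' @param status one of \code{"complete"}, \code{"repeat"}, \code{"cancel"},
#'   \code{"finish"}.
#' @param outcome \code{"ok"} or \code{"failed"}; recorded in the facts for
#'   complete/repeat.
#' @param path optional occurrence path selecting between identically
#'   labelled released occurrences; default is the leftmost-innermost one.
#' @return the instance, invisibly.
#' @export
report <- function(inst, action = NULL, status, outcome = "ok", path = NULL) {
  status <- match.arg(status, c("complete", "repeat", "cancel", "finish"))
  if (!inst$lifecycle %in% RUNNING_STATES)
    stop(sprintf("instance %s is %s; no further reports accepted",
                 inst$id, inst$lifecycle), call. = FALSE)
  if (status %in% c("complete", "repeat")) {
    stopifnot(!is.null(action))
    rel <- released(inst)
    hit <- if (is.null(path)) which(rel$action == action)
           else which(rel$action == action & rel$path == path)
    if (!length(hit))
      stop(sprintf("action '%s' is not currently released for instance %s",
                   action, inst$id), call. = FALSE)
    if (status == "complete") {
      inst$residual <- step_weak(inst$residual, rel$path[[hit[[1L]]]],
                                 inst$registry, inst$ctx)
      ctx_record(inst$ctx, action, outcome)
      log_event(inst, action, "completed", outcome)
      # the consumed occurrence no longer counts as announced
      inst$released_before <-
        inst$released_before[-match(action, inst$released_before)]
      auto_advance(inst, inst$registry, inst$tau_cap %||% 10000L)
    } else {
      ctx_record(inst$ctx, action, outcome)
      log_event(inst, action, "repeated", outcome)
    }
  } else if (status == "cancel") {
    log_event(inst, action %||% inst$def_name, "test_canceled")
    inst$lifecycle <- "canceled"
  } else {  # finish
    log_event(inst, action %||% inst$def_name, "test_finished")
    en <- weak_enabled(inst$residual, inst$registry, inst$ctx,
                       inst$tau_cap %||% 10000L)
    inst$lifecycle <-
      if (isTRUE(attr(en, "can_finish"))) "finished" else "forced_finished"
  }
  invisible(inst)
}

#' Replay an event log on a fresh instance
#'
#' Event-sourced determinism: applying the user-driven events of a log
#' (completed/repeated/test_canceled/test_finished rows; released rows are
#' derived and regenerated) to a fresh instance of the same definition
#' reproduces residual, facts, lifecycle and log bit-for-bit.
#'
#' @param def_name,registry,ctx,clock as in \code{\link{instantiate}}.
#' @param log an event log data.frame from an existing instance.
#' @param id instance identifier to reuse.
#' @return the reconstructed \code{npdl_instance}.
#' @export
replay <- function(def_name, registry, log, ctx = NULL, id = NULL,
                   clock = logical_clock()) {
  inst <- instantiate(def_name, registry, ctx, id = id, clock = clock)
  user <- log[log$status %in% c("completed", "repeated", "test_canceled",
                                "test_finished"), , drop = FALSE]
  for (i in seq_len(nrow(user))) {
    row <- user[i, ]
    if (!inst$lifecycle %in% RUNNING_STATES) break
    if (row$status == "completed") {
      if (row$action %in% released(inst)$action)
        report(inst, row$action, "complete", row$outcome)
      # terminal completions (END) are auto-fired, not replayed
    } else if (row$status == "repeated") {
      report(inst, row$action, "repeat", row$outcome)
    } else if (row$status == "test_canceled") {
      report(inst, row$action, "cancel")
    } else if (row$status == "test_finished") {
      # auto-finish events are regenerated by auto_advance; explicit user
      # finishes are replayed
      if (inst$lifecycle %in% RUNNING_STATES && nrow(released(inst)) > 0L)
        report(inst, row$action, "finish")
    }
  }
  inst
}

#' Export an instance's event log
#'
#' @param inst an \code{npdl_instance}.
#' @param path optional file path; CSV gets columns seq, action, status,
#'   outcome, timestamp (ISO-8601).
#' @return the log data.frame (csv) or a JSON string (json), invisibly when
#'   written to a file.
#' @export
events_csv <- function(inst, path = NULL) {
  if (is.null(path)) return(inst$log)
  utils::write.csv(inst$log, path, row.names = FALSE)
  invisible(inst$log)
}

#' @rdname events_csv
#' @export
events_json <- function(inst, path = NULL) {
  js <- jsonlite::toJSON(inst$log, dataframe = "rows", na = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @export
print.npdl_instance <- function(x, ...) {
  cat(sprintf("<npdl_instance> %s: %s (v%d), lifecycle=%s\n", x$id, x$def_name,
              x$def_version, x$lifecycle))
  cat("  residual: ", npdl_serialize(x$residual), "\n", sep = "")
  rel <- released(x)
  if (nrow(rel))
    cat("  released: ", paste(rel$action, collapse = ", "), "\n", sep = "")
  cat(sprintf("  log: %d event(s)\n", nrow(x$log)))
  invisible(x)
}
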