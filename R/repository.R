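#' Relational process repository
#'
#' File-backed relational persistence for process definitions, the procedure
#' catalog, tests, patients, samples, test orders, instances and events, plus
#' the two work-queue views (by procedure and by disease/test). Tables are
#' data.frames with referential-integrity checks enforced on insert; a
#' repository directory holds one CSV per table, and the equivalent SQL DDL
#' ships in \code{inst/sql/schema.sql}. Dates and timestamps are ISO-8601
#' text.
#'
#' @param path optional directory; if it exists and contains tables they are
#'   loaded, otherwise it is used by \code{\link{repo_save}}.
#' @return an object of class \code{npdl_repo}.
#' @examples
#' repo <- repo_new()
#' repo_add_patient(repo, 1, "Patient Zero")
#' repo_add_sample(repo, "DNA0001", 1)
#' @export
repo_new <- function(path = NULL) {
  repo <- new.env(parent = emptyenv())
  class(repo) <- "npdl_repo"
  repo$path <- path
  repo$tables <- list(
    process_definition = data.frame(name = character(0), version = integer(0),
                                    npdl_text = character(0)),
    procedure_catalog = data.frame(name = character(0), description = character(0),
                                   technique = character(0), reagents = character(0)),
    test = data.frame(name = character(0), description = character(0),
                      duration_days = numeric(0), cost = numeric(0),
                      process_name = character(0)),
    test_item = data.frame(test = character(0), procedure = character(0),
                           exec_order = integer(0)),
    patient = data.frame(number = integer(0), name = character(0)),
    sample = data.frame(dna_number = character(0), patient = integer(0)),
    test_order = data.frame(id = integer(0), sample = character(0),
                            test = character(0), request_date = character(0)),
    instance = data.frame(id = character(0), order_id = integer(0),
                          residual_npdl = character(0), lifecycle = character(0)),
    event = data.frame(instance = character(0), seq = integer(0),
                       action = character(0), status = character(0),
                       outcome = character(0), timestamp = character(0))
  )
  for (nm in names(repo$tables))
    repo$tables[[nm]] <- as_chr_safe(repo$tables[[nm]])
  if (!is.null(path) && dir.exists(path)) repo_load_dir(repo, path)
  repo
}

as_chr_safe <- function(df) { rownames(df) <- NULL; df }

tbl <- function(repo, name) repo$tables[[name]]

append_row <- function(repo, name, row) {
  repo$tables[[name]] <- rbind(repo$tables[[name]],
                               as.data.frame(row, stringsAsFactors = FALSE))
  rownames(repo$tables[[name]]) <- NULL
  invisible(repo)
}

require_fk <- function(repo, table, column, value, what) {
  if (!value %in% repo$tables[[table]][[column]])
    stop(sprintf("integrity violation: %s '%s' does not exist", what, value),
         call. = FALSE)
  invisible(TRUE)
}

#' @describeIn repo_new store a process definition (name, version, text).
#' @param repo a repository.
#' @param name,version,npdl_text definition identity and serialized text.
#' @export
repo_add_process_definition <- function(repo, name, version, npdl_text) {
  t <- tbl(repo, "process_definition")
  if (any(t$name == name & t$version == version))
    stop(sprintf("integrity violation: process_definition (%s, v%d) already exists",
                 name, version), call. = FALSE)
  append_row(repo, "process_definition",
             list(name = name, version = as.integer(version), npdl_text = npdl_text))
}

#' @describeIn repo_new store the catalog (replaces existing rows of the same
#'   names).
#' @param catalog an \code{npdl_catalog}.
#' @export
repo_add_catalog <- function(repo, catalog) {
  df <- as.data.frame(catalog, stringsAsFactors = FALSE)
  keep <- !(tbl(repo, "procedure_catalog")$name %in% df$name)
  repo$tables$procedure_catalog <-
    rbind(tbl(repo, "procedure_catalog")[keep, , drop = FALSE], df)
  rownames(repo$tables$procedure_catalog) <- NULL
  invisible(repo)
}

#' @describeIn repo_new store a test definition, its items, its compiled
#'   process (registered in \code{registry}) and the definition text.
#' @param test_def an \code{npdl_test_def}.
#' @param registry the registry the compiled expression is registered in.
#' @export
repo_add_test <- function(repo, test_def, registry) {
  built <- build_expression(test_def, registry,
                            procedure_catalog(tbl(repo, "procedure_catalog")))
  for (p in test_def$items$name)
    require_fk(repo, "procedure_catalog", "name", p, "procedure")
  if (test_def$name %in% tbl(repo, "test")$name)
    stop(sprintf("integrity violation: test '%s' already exists", test_def$name),
         call. = FALSE)
  append_row(repo, "test", list(name = test_def$name,
                                description = test_def$description %||% "",
                                duration_days = test_def$duration_days,
                                cost = test_def$cost,
                                process_name = built$name))
  for (i in seq_len(nrow(test_def$items)))
    append_row(repo, "test_item", list(test = test_def$name,
                                       procedure = test_def$items$name[[i]],
                                       exec_order = as.integer(test_def$items$order[[i]])))
  repo_add_process_definition(repo, built$name, reg_version(registry, built$name),
                              npdl_serialize(built$expr))
  invisible(built)
}

#' @describeIn repo_new add a patient.
#' @param number patient number; \code{pname} patient name.
#' @param pname patient name.
#' @export
repo_add_patient <- function(repo, number, pname) {
  if (number %in% tbl(repo, "patient")$number)
    stop(sprintf("integrity violation: patient %s already exists", number),
         call. = FALSE)
  append_row(repo, "patient", list(number = as.integer(number), name = pname))
}

#' @describeIn repo_new add a DNA sample for a patient.
#' @param dna_number sample identifier.
#' @param patient patient number (must exist).
#' @export
repo_add_sample <- function(repo, dna_number, patient) {
  require_fk(repo, "patient", "number", as.integer(patient), "patient")
  if (dna_number %in% tbl(repo, "sample")$dna_number)
    stop(sprintf("integrity violation: sample %s already exists", dna_number),
         call. = FALSE)
  append_row(repo, "sample", list(dna_number = dna_number,
                                  patient = as.integer(patient)))
}

#' @describeIn repo_new order a test for a sample.
#' @param id order id; \code{sample} DNA number; \code{test} test name;
#'   \code{request_date} ISO-8601 date string.
#' @param sample,test,request_date order fields.
#' @export
repo_add_order <- function(repo, id, sample, test,
                           request_date = "2020-01-01") {
  require_fk(repo, "sample", "dna_number", sample, "sample")
  require_fk(repo, "test", "name", test, "test")
  if (id %in% tbl(repo, "test_order")$id)
    stop(sprintf("integrity violation: test_order %s already exists", id),
         call. = FALSE)
  append_row(repo, "test_order", list(id = as.integer(id), sample = sample,
                                      test = test, request_date = request_date))
}

#' Persist / load a running instance
#'
#' The residual is stored as reparsable NPDL text and the full event log in
#' the event table; \code{repo_load_instance} reconstructs residual, facts
#' (from the event log) and lifecycle, so the released set after a reload
#' matches the in-memory instance exactly.
#'
#' @param repo a repository.
#' @param inst an \code{npdl_instance}.
#' @param order_id the test order this instance executes.
#' @export
repo_persist_instance <- function(repo, inst, order_id) {
  require_fk(repo, "test_order", "id", as.integer(order_id), "test_order")
  t <- tbl(repo, "instance")
  repo$tables$instance <- t[t$id != inst$id, , drop = FALSE]
  append_row(repo, "instance", list(id = inst$id, order_id = as.integer(order_id),
                                    residual_npdl = npdl_serialize(inst$residual),
                                    lifecycle = inst$lifecycle))
  ev <- tbl(repo, "event")
  repo$tables$event <- ev[ev$instance != inst$id, , drop = FALSE]
  log <- inst$log
  if (nrow(log)) {
    if (anyDuplicated(log$seq))
      stop("integrity violation: duplicate event sequence number", call. = FALSE)
    for (i in seq_len(nrow(log)))
      append_row(repo, "event", list(instance = inst$id, seq = log$seq[[i]],
                                     action = log$action[[i]],
                                     status = log$status[[i]],
                                     outcome = log$outcome[[i]],
                                     timestamp = log$timestamp[[i]]))
  }
  invisible(repo)
}

#' @rdname repo_persist_instance
#' @param id instance id.
#' @param registry registry holding the instance's process definition (e.g.
#'   rebuilt via \code{\link{repo_registry}}).
#' @export
repo_load_instance <- function(repo, id, registry) {
  t <- tbl(repo, "instance")
  i <- match(id, t$id)
  if (is.na(i)) stop(sprintf("instance '%s' not found", id), call. = FALSE)
  ord <- tbl(repo, "test_order")
  o <- ord[ord$id == t$order_id[[i]], ]
  test <- tbl(repo, "test")
  proc_name <- test$process_name[[match(o$test, test$name)]]
  residual <- if (nzchar(t$residual_npdl[[i]]))
    parse_expression(t$residual_npdl[[i]], known = reg_names(registry))
  else px_nil()
  ctx <- eval_context()
  ev <- tbl(repo, "event")
  ev <- ev[ev$instance == id, , drop = FALSE]
  ev <- ev[order(ev$seq), , drop = FALSE]
  for (j in seq_len(nrow(ev)))
    if (ev$status[[j]] %in% c("completed", "repeated") && ev$action[[j]] != "END" &&
        !is.na(ev$outcome[[j]]))
      ctx_record(ctx, ev$action[[j]], ev$outcome[[j]])
  inst <- new_instance(id, proc_name,
                       reg_version(registry, proc_name), residual, ctx,
                       logical_clock())
  inst$registry <- registry
  inst$lifecycle <- t$lifecycle[[i]]
  inst$log <- data.frame(seq = as.integer(ev$seq), action = ev$action,
                         status = ev$status, outcome = ev$outcome,
                         timestamp = ev$timestamp, stringsAsFactors = FALSE)
  inst$released_before <- released(inst)$action
  inst
}

#' Rebuild an in-memory registry from persisted definitions
#'
#' @param repo a repository.
#' @return an \code{npdl_registry} with the latest version of each stored
#'   definition.
#' @export
repo_registry <- function(repo) {
  reg <- process_registry()
  t <- tbl(repo, "process_definition")
  known <- unique(t$name)
  for (nm in known) {
    rows <- t[t$name == nm, , drop = FALSE]
    latest <- rows[which.max(rows$version), ]
    for (v in seq_len(latest$version))  # replay versions so counters match
      reg_define(reg, nm, parse_expression(latest$npdl_text, known = known))
  }
  reg
}

#' Work queue views
#'
#' One item per currently released (instance, procedure occurrence), joined
#' to patient/sample/test metadata — the seven columns of the execution
#' interface: procedure name, patient number, patient name, DNA number, date
#' of test request, test name, execution status — plus the available actions.
#'
#' \code{filter_kind = "procedure"} selects a group of similar procedures
#' regardless of test (exact name or prefix wildcard, e.g. \code{"PCR*"});
#' \code{filter_kind = "disease"} follows one test: only released procedures
#' of orders for that test are shown. \code{NULL} returns the whole queue.
#'
#' @param repo a repository.
#' @param filter_kind \code{NULL}, \code{"procedure"} or \code{"disease"}.
#' @param value filter value (procedure name/prefix pattern, or test name).
#' @param registry optional registry; defaults to \code{repo_registry(repo)}.
#' @return data.frame with columns procedure, patient_number, patient_name,
#'   dna_number, request_date, test_name, execution_status, available_actions.
#' @export
work_queue <- function(repo, filter_kind = NULL, value = NULL, registry = NULL) {
  if (is.null(registry)) registry <- repo_registry(repo)
  out <- data.frame(procedure = character(0), patient_number = integer(0),
                    patient_name = character(0), dna_number = character(0),
                    request_date = character(0), test_name = character(0),
                    execution_status = character(0),
                    available_actions = character(0), stringsAsFactors = FALSE)
  insts <- tbl(repo, "instance")
  for (i in seq_len(nrow(insts))) {
    if (!insts$lifecycle[[i]] %in% c("running")) next
    inst <- repo_load_instance(repo, insts$id[[i]], registry)
    rel <- released(inst)
    if (!nrow(rel)) next
    ord <- tbl(repo, "test_order")
    o <- ord[ord$id == insts$order_id[[i]], ]
    smp <- tbl(repo, "sample")
    s <- smp[smp$dna_number == o$sample, ]
    pat <- tbl(repo, "patient")
    p <- pat[pat$number == s$patient, ]
    for (j in seq_len(nrow(rel))) {
      act <- rel$action[[j]]
      ev <- inst$log
      prev <- ev[ev$action == act & ev$status %in% c("completed", "repeated"), ]
      status <- if (nrow(prev)) prev$status[[nrow(prev)]] else "released"
      out <- rbind(out, data.frame(
        procedure = act, patient_number = p$number, patient_name = p$name,
        dna_number = s$dna_number, request_date = o$request_date,
        test_name = o$test, execution_status = status,
        available_actions = "complete|repeat|cancel|finish",
        stringsAsFactors = FALSE))
    }
  }
  if (!is.null(filter_kind)) {
    filter_kind <- match.arg(filter_kind, c("procedure", "disease"))
    if (filter_kind == "procedure") {
      if (grepl("\\*$", value)) {
        pre <- sub("\\*$", "", value)
        out <- out[startsWith(out$procedure, pre), , drop = FALSE]
      } else out <- out[out$procedure == value, , drop = FALSE]
    } else {
      out <- out[out$test_name == value, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out
}

#' @rdname work_queue
#' @param path CSV output path.
#' @export
work_queue_csv <- function(repo, path, filter_kind = NULL, value = NULL) {
  utils::write.csv(work_queue(repo, filter_kind, value), path, row.names = FALSE)
  invisible(path)
}

# ---- directory persistence ---------------------------------------------

#' Save / load a repository directory (one CSV per table)
#'
#' @param repo a repository.
#' @param path directory (defaults to the path the repository was opened
#'   with).
#' @export
repo_save <- function(repo, path = repo$path) {
  stopifnot(!is.null(path))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(repo$tables))
    utils::write.csv(repo$tables[[nm]], file.path(path, paste0(nm, ".csv")),
                     row.names = FALSE)
  invisible(path)
}

repo_load_dir <- function(repo, path) {
  for (nm in names(repo$tables)) {
    f <- file.path(path, paste0(nm, ".csv"))
    if (file.exists(f)) {
      df <- utils::read.csv(f, stringsAsFactors = FALSE,
                            colClasses = vapply(repo$tables[[nm]], class,
                                                character(1)))
      repo$tables[[nm]] <- df
    }
  }
  invisible(repo)
}

#' CSV import of patients, samples and orders
#'
#' Patients CSV: columns \code{number,name}; samples: \code{dna_number,patient};
#' orders: \code{id,sample,test,request_date}.
#'
#' @param repo a repository.
#' @param path CSV path.
#' @export
repo_import_patients_csv <- function(repo, path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) repo_add_patient(repo, df$number[[i]], df$name[[i]])
  invisible(repo)
}

#' @rdname repo_import_patients_csv
#' @export
repo_import_samples_csv <- function(repo, path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df)))
    repo_add_sample(repo, df$dna_number[[i]], df$patient[[i]])
  invisible(repo)
}

#' @rdname repo_import_patients_csv
#' @export
repo_import_orders_csv <- function(repo, path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df)))
    repo_add_order(repo, df$id[[i]], df$sample[[i]], df$test[[i]],
                   df$request_date[[i]])
  invisible(repo)
}

#' @export
print.npdl_repo <- function(x, ...) {
  cat("<npdl_repo>", if (!is.null(x$path)) paste0(" at ", x$path), "\n", sep = "")
  for (nm in names(x$tables))
    cat(sprintf("  %-20s %d row(s)\n", nm, nrow(x$tables[[nm]])))
  invisible(x)
}
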