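# Engine: instantiation, release, the four statuses, event sourcing.

test_that("SMA instantiation releases both PCRs and finishes in either order", {
  reg <- sma_registry()
  inst <- instantiate("SMA", reg)
  expect_setequal(released(inst)$action, c("PCR_exon7", "PCR_exon8"))
  report(inst, "PCR_exon7", "complete", "ok")
  # the other PCR stays released, and the completed one remains repeatable
  expect_setequal(released(inst)$action, c("PCR_exon7", "PCR_exon8"))
  report(inst, "PCR_exon8", "complete", "ok")
  expect_identical(inst$lifecycle, "finished")
  expect_identical(nrow(released(inst)), 0L)
  expect_true("END" %in% inst$log$action[inst$log$status == "completed"])

  # opposite completion order reaches the same residual and lifecycle
  inst2 <- instantiate("SMA", reg)
  report(inst2, "PCR_exon8", "complete", "ok")
  report(inst2, "PCR_exon7", "complete", "ok")
  expect_identical(inst2$lifecycle, "finished")
  expect_true(px_equal(inst$residual, inst2$residual))
})

test_that("repeat keeps the action released and counts executions", {
  reg <- sma_registry()
  inst <- instantiate("SMA", reg)
  report(inst, "PCR_exon7", "repeat", "failed")
  report(inst, "PCR_exon7", "repeat", "failed")
  expect_true("PCR_exon7" %in% released(inst)$action)
  expect_identical(sum(inst$log$status == "repeated"), 2L)
  expect_identical(inst$ctx$facts[["PCR_exon7"]]$times, 2L)
  report(inst, "PCR_exon7", "complete", "ok")
  expect_identical(inst$ctx$facts[["PCR_exon7"]]$times, 3L)
  expect_identical(inst$ctx$facts[["PCR_exon7"]]$last, "ok")
})

test_that("failed outcomes gate the END release until a later ok completion", {
  reg <- sma_registry()
  inst <- instantiate("SMA", reg)
  report(inst, "PCR_exon7", "complete", "failed")
  report(inst, "PCR_exon8", "complete", "ok")
  # gated: END has not fired, the failed procedure is still on offer
  expect_identical(inst$lifecycle, "running")
  expect_false("END" %in% inst$log$action)
  expect_true("PCR_exon7" %in% released(inst)$action)
  report(inst, "PCR_exon7", "complete", "ok")
  expect_identical(inst$lifecycle, "finished")
  expect_true("END" %in% inst$log$action)
})

test_that("cancel and finish close the instance with the right lifecycle", {
  reg <- sma_registry()
  inst <- instantiate("SMA", reg)
  report(inst, status = "cancel")
  expect_identical(inst$lifecycle, "canceled")
  expect_identical(nrow(released(inst)), 0L)
  expect_error(report(inst, "PCR_exon7", "complete"), "no further reports")

  # finish before the work is done is an audited forced finish
  inst2 <- instantiate("SMA", reg)
  report(inst2, status = "finish")
  expect_identical(inst2$lifecycle, "forced_finished")
  # finish when the residual can terminate is a clean finish
  reg2 <- process_registry(list(OPT = parse_expression("a . b ?*")))
  inst3 <- instantiate("OPT", reg2)
  report(inst3, "a", "complete", "ok")
  report(inst3, "b", "complete", "ok")
  expect_identical(inst3$lifecycle, "running")  # b still repeatable
  report(inst3, status = "finish")
  expect_identical(inst3$lifecycle, "finished")
})

test_that("a fully guard-blocked non-terminated residual is flagged stuck", {
  reg <- process_registry(list(G = parse_expression("a % never")))
  inst <- instantiate("G", reg, eval_context(rules = list(never = function(f) FALSE)))
  expect_identical(inst$lifecycle, "stuck")
  expect_identical(nrow(released(inst)), 0L)
})

test_that("?f resolves through the function registry at instantiation", {
  reg <- process_registry(list(R3 = parse_expression("a ?f(n_runs)")))
  ctx <- eval_context(funcs = list(n_runs = function(f) 3L))
  inst <- instantiate("R3", reg, ctx)
  expect_identical(inst$residual$kind, "rep_n")
  expect_identical(inst$residual$n, 3L)
  for (i in 1:3) report(inst, "a", "complete", "ok")
  expect_identical(inst$lifecycle, "finished")
  expect_error(instantiate("R3", process_registry(list(R3 = parse_expression("a ?f(n_runs)")))),
               "unresolved function 'n_runs'")
})

test_that("missing rule bindings are reported by name at instantiation", {
  reg <- process_registry(list(G = parse_expression("a % approved")))
  expect_error(instantiate("G", reg), "unresolved rule\\(s\\): approved")
  # the built-in ok_<procedure> family needs no registration
  reg2 <- process_registry(list(G2 = parse_expression("a . (GO % ok_a) . b")))
  expect_silent(inst <- instantiate("G2", reg2))
})

test_that("multi-merge fires the continuation twice, discriminator once", {
  reg <- process_registry(list(MM = parse_expression("(a & b) . c"),
                               DC = parse_expression("(a ^ b) . c")))
  for (order in list(c("a", "b"), c("b", "a"))) {
    mm <- instantiate("MM", reg)
    for (act in order) report(mm, act, "complete", "ok")
    while (mm$lifecycle == "running" && "c" %in% released(mm)$action)
      report(mm, "c", "complete", "ok")
    expect_identical(sum(mm$log$action == "c" & mm$log$status == "completed"), 2L)
    expect_identical(mm$lifecycle, "finished")

    dc <- instantiate("DC", reg)
    for (act in order) report(dc, act, "complete", "ok")
    while (dc$lifecycle == "running" && "c" %in% released(dc)$action)
      report(dc, "c", "complete", "ok")
    expect_identical(sum(dc$log$action == "c" & dc$log$status == "completed"), 1L)
    expect_identical(dc$lifecycle, "finished")
  }
})

test_that("event log replay reproduces residual, facts and lifecycle exactly", {
  reg <- sma_registry()
  inst <- instantiate("SMA", reg, id = "i1")
  report(inst, "PCR_exon7", "repeat", "failed")
  report(inst, "PCR_exon7", "complete", "ok")
  report(inst, "PCR_exon8", "complete", "ok")
  twin <- replay("SMA", reg, inst$log, id = "i1")
  expect_identical(twin$lifecycle, inst$lifecycle)
  expect_true(px_equal(twin$residual, inst$residual))
  expect_identical(twin$log, inst$log)
  expect_identical(ls(twin$ctx$facts), ls(inst$ctx$facts))
  for (nm in ls(inst$ctx$facts))
    expect_identical(twin$ctx$facts[[nm]], inst$ctx$facts[[nm]])

  # mid-flight replay too
  inst2 <- instantiate("SMA", reg, id = "i2")
  report(inst2, "PCR_exon8", "complete", "failed")
  twin2 <- replay("SMA", reg, inst2$log, id = "i2")
  expect_identical(twin2$log, inst2$log)
  expect_true(px_equal(twin2$residual, inst2$residual))
})

test_that("event sequence numbers are strictly increasing and gapless", {
  reg <- sma_registry()
  inst <- instantiate("SMA", reg)
  report(inst, "PCR_exon7", "complete", "ok")
  report(inst, "PCR_exon8", "complete", "ok")
  expect_identical(inst$log$seq, seq_len(nrow(inst$log)))
  j <- jsonlite::fromJSON(events_json(inst))
  expect_identical(nrow(j), nrow(inst$log))
  f <- tempfile(fileext = ".csv")
  events_csv(inst, f)
  expect_identical(utils::read.csv(f)$action, inst$log$action)
})

test_that("simulated runs stay within the oracle's trace set", {
  reg <- process_registry()
  defs <- 0L
  for (i in 1:60) {
    e <- draw_expression(7000 + i, max_depth = 3,
                         weights = c(seq = 3, alt = 2, par = 1.5, ipar = 1,
                                     mmerge = 1, disc = 1, rep_n = 0.8),
                         accept = function(x) length(expr_atoms(x)) <= 8)
    nm <- sprintf("D%d", i)
    reg_define(reg, nm, e)
    inst <- instantiate(nm, reg, clock = logical_clock())
    run <- simulate_instance(inst, seed = 40000 + i)
    if (run$lifecycle == "finished") {
      tr <- paste(run$steps, collapse = " ")
      expect_true(tr %in% traces(e, reg, loop_bound = 2),
                  label = sprintf("run <%s> of %s in oracle set", tr,
                                  npdl_serialize(e)))
      defs <- defs + 1L
    }
  }
  expect_gt(defs, 30L)  # most runs complete
})
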