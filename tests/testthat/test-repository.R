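# Repository: persistence round-trips, integrity, work-queue views.

seeded_repo <- function(seed = 11, n_patients = 4, n_tests = 3) {
  reg <- process_registry()
  repo <- repo_new()
  wl <- gen_workload(seed, n_patients = n_patients, n_tests = n_tests)
  repo_load_workload(repo, wl, reg)
  list(repo = repo, reg = reg, wl = wl)
}

test_that("entities enforce referential integrity and uniqueness", {
  repo <- repo_new()
  expect_error(repo_add_sample(repo, "DNA1", 99), "patient '99' does not exist")
  repo_add_patient(repo, 1, "Patient 001")
  expect_error(repo_add_patient(repo, 1, "again"), "already exists")
  repo_add_sample(repo, "DNA1", 1)
  expect_error(repo_add_order(repo, 1, "DNA1", "nope"), "test 'nope' does not exist")
  expect_error(repo_load_instance(repo, "ghost", process_registry()), "not found")
})

test_that("instances round-trip through the store with identical released sets", {
  reg <- sma_registry()
  repo <- repo_new()
  repo_add_catalog(repo, sma_catalog())
  repo_add_test(repo, sma_def(), process_registry())
  repo_add_patient(repo, 1, "Patient 001")
  repo_add_sample(repo, "DNA0001", 1)
  repo_add_order(repo, 1, "DNA0001", "SMA", "2020-01-02")
  inst <- instantiate("SMA", reg, id = "inst-1")
  report(inst, "PCR_exon7", "complete", "failed")   # mid-execution, gated
  repo_persist_instance(repo, inst, 1)
  back <- repo_load_instance(repo, "inst-1", reg)
  expect_identical(back$lifecycle, "running")
  expect_identical(released(back), released(inst))
  expect_identical(back$log, inst$log)
  expect_identical(back$ctx$facts[["PCR_exon7"]]$last, "failed")
  # duplicate event sequence numbers are an integrity violation
  inst$log$seq[2] <- inst$log$seq[1]
  expect_error(repo_persist_instance(repo, inst, 1), "duplicate event sequence")
})

test_that("a repository directory reloads byte-identically", {
  s <- seeded_repo()
  ord <- tbl(s$repo, "test_order")
  inst <- instantiate(
    tbl(s$repo, "test")$process_name[[match(ord$test[[1]], tbl(s$repo, "test")$name)]],
    s$reg, id = "inst-1")
  repo_persist_instance(s$repo, inst, ord$id[[1]])
  dir <- file.path(tempdir(), "npdl-repo-test")
  unlink(dir, recursive = TRUE)
  repo_save(s$repo, dir)
  repo2 <- repo_new(dir)
  for (nm in names(s$repo$tables))
    expect_identical(repo2$tables[[nm]], s$repo$tables[[nm]], label = nm)
  reg2 <- repo_registry(repo2)
  back <- repo_load_instance(repo2, "inst-1", reg2)
  expect_identical(released(back), released(inst))
})

test_that("process definitions rebuilt from npdl_text parse to equal expressions", {
  s <- seeded_repo()
  reg2 <- repo_registry(s$repo)
  expect_setequal(reg_names(reg2), reg_names(s$reg))
  for (nm in reg_names(s$reg))
    expect_true(px_equal(reg_get(reg2, nm), reg_get(s$reg, nm)), label = nm)
})

test_that("work queue shows one row per released occurrence with Fig-3 columns", {
  reg <- sma_registry()
  repo <- repo_new()
  repo_add_catalog(repo, sma_catalog())
  repo_add_test(repo, sma_def(), process_registry())
  repo_add_patient(repo, 1, "Patient 001")
  repo_add_sample(repo, "DNA0001", 1)
  repo_add_order(repo, 1, "DNA0001", "SMA", "2020-01-02")
  inst <- instantiate("SMA", reg, id = "inst-1")
  repo_persist_instance(repo, inst, 1)
  q <- work_queue(repo, registry = reg)
  expect_identical(names(q), c("procedure", "patient_number", "patient_name",
                               "dna_number", "request_date", "test_name",
                               "execution_status", "available_actions"))
  expect_setequal(q$procedure, c("PCR_exon7", "PCR_exon8"))
  expect_identical(unique(q$patient_name), "Patient 001")
  expect_identical(unique(q$execution_status), "released")
  # prefix wildcard selects the PCR group; unknown values give empty queues
  expect_identical(nrow(work_queue(repo, "procedure", "PCR*", reg)), 2L)
  expect_identical(nrow(work_queue(repo, "procedure", "PCR_exon7", reg)), 1L)
  expect_identical(nrow(work_queue(repo, "procedure", "sorcery", reg)), 0L)
  expect_identical(nrow(work_queue(repo, "disease", "SMA", reg)), 2L)
  expect_identical(nrow(work_queue(repo, "disease", "unknown", reg)), 0L)
  expect_identical(nrow(work_queue(repo_new())), 0L)
})

test_that("disease-filtered queues partition the full queue", {
  s <- seeded_repo(seed = 23, n_patients = 5, n_tests = 3)
  ord <- tbl(s$repo, "test_order")
  tests <- tbl(s$repo, "test")
  for (i in seq_len(nrow(ord))) {
    inst <- instantiate(tests$process_name[[match(ord$test[[i]], tests$name)]],
                        s$reg, id = sprintf("inst-%d", ord$id[[i]]))
    # advance a few instances so queues differ in shape
    if (i %% 2 == 0) {
      rel <- released(inst)
      if (nrow(rel)) report(inst, rel$action[[1]], "complete", "ok")
    }
    repo_persist_instance(s$repo, inst, ord$id[[i]])
  }
  full <- work_queue(s$repo, registry = s$reg)
  parts <- lapply(unique(tests$name), function(tn)
    work_queue(s$repo, "disease", tn, registry = s$reg))
  joined <- do.call(rbind, parts)
  key <- function(df) sort(do.call(paste, c(df, sep = "|")))
  expect_identical(key(joined), key(full))
  expect_identical(nrow(full), sum(vapply(parts, nrow, 1L)))
})

test_that("CSV imports feed patients, samples and orders", {
  s <- seeded_repo(seed = 31)
  dir <- tempdir()
  fp <- file.path(dir, "patients.csv"); fs <- file.path(dir, "samples.csv")
  fo <- file.path(dir, "orders.csv")
  utils::write.csv(s$wl$patients, fp, row.names = FALSE)
  utils::write.csv(s$wl$samples, fs, row.names = FALSE)
  utils::write.csv(s$wl$orders, fo, row.names = FALSE)
  repo2 <- repo_new()
  reg2 <- process_registry()
  repo_add_catalog(repo2, s$wl$catalog)
  for (td in s$wl$tests) repo_add_test(repo2, td, reg2)
  repo_import_patients_csv(repo2, fp)
  repo_import_samples_csv(repo2, fs)
  repo_import_orders_csv(repo2, fo)
  expect_identical(nrow(tbl(repo2, "patient")), nrow(s$wl$patients))
  expect_identical(nrow(tbl(repo2, "test_order")), nrow(s$wl$orders))
  f <- tempfile(fileext = ".csv")
  work_queue_csv(repo2, f)
  expect_true(file.exists(f))
})
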