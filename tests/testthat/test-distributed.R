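# The distributed protocol is exercised with real concurrent processes
# (forked via parallel::mclapply) against a shared on-disk work directory.

make_grid_fixture <- function(seed, n_q = 6, n_r = 12, qcl, rcl,
                              workdir = tempfile("swarm")) {
  set.seed(seed)
  base <- replicate(n_r, random_protein(60))
  qseqs <- vapply(sample(n_r, n_q), function(i) mutate_seq(base[i], 0.2), "")
  qfa <- write_temp_fasta(qseqs, sprintf("q%02d", seq_len(n_q)))
  rfa <- write_temp_fasta(base, sprintf("r%02d", seq_len(n_r)))
  qdb <- tempfile(); rdb <- tempfile()
  make_database(qfa, qdb)
  make_database(rfa, rdb)
  list(qdb = qdb, rdb = rdb, workdir = workdir)
}

test_that("plan_grid builds the Cartesian package set deterministically", {
  fx <- make_grid_fixture(81)
  # budget >= total letters: one chunk
  plan_grid(fx$qdb, fx$rdb, 1e6, 1e6, fx$workdir)
  m <- jsonlite::read_json(file.path(fx$workdir, "manifest.json"))
  expect_equal(m$n_query_chunks, 1L)
  expect_equal(m$n_ref_chunks, 1L)

  # 3 query chunks x 2 ref chunks -> 6 packages across 3 stacks
  wd2 <- tempfile()
  plan_grid(fx$qdb, fx$rdb, 120, 360, wd2)
  m2 <- jsonlite::read_json(file.path(wd2, "manifest.json"))
  expect_equal(m2$n_query_chunks, 3L)
  expect_equal(m2$n_ref_chunks, 2L)
  pend <- lapply(1:3, function(qc)
    list.files(file.path(wd2, "stacks", sprintf("q%03d", qc), "pending")))
  expect_equal(lengths(pend), rep(2L, 3))
  expect_equal(length(unique(unlist(pend))), 6L)

  # replanning produces an identical manifest
  wd3 <- tempfile()
  plan_grid(fx$qdb, fx$rdb, 120, 360, wd3)
  expect_identical(readLines(file.path(wd2, "manifest.json")),
                   readLines(file.path(wd3, "manifest.json")))

  # refusing to clobber a used workdir
  expect_error(plan_grid(fx$qdb, fx$rdb, 120, 360, wd2), "not empty")
})

test_that("no sequence is split and letter budgets are respected", {
  lens <- c(50, 60, 50, 70, 10)
  chunks <- seedhit:::chunk_by_letters(lens, 115)
  expect_equal(unlist(chunks), 1:5)
  expect_true(all(vapply(chunks, function(ix) sum(lens[ix]), 1) <= 115 |
                    lengths(chunks) == 1))
})

test_that("concurrent pops claim every package exactly once", {
  fx <- make_grid_fixture(82, n_q = 2, n_r = 25)
  plan_grid(fx$qdb, fx$rdb, 1e6, 30, fx$workdir)  # many tiny ref chunks
  m <- jsonlite::read_json(file.path(fx$workdir, "manifest.json"))
  expect_gte(m$n_ref_chunks, 10)
  claims <- parallel::mclapply(1:8, function(w) {
    got <- character(0)
    repeat {
      p <- stack_pop(fx$workdir, 1, worker_id = w)
      if (is.null(p)) break
      got <- c(got, p$name)
    }
    got
  }, mc.cores = 8)
  all_claims <- unlist(claims)
  expect_equal(sort(all_claims),
               sort(sprintf("p_001_%03d", seq_len(m$n_ref_chunks))))
  expect_false(any(duplicated(all_claims)))
  # empty stack pops return NULL
  expect_null(stack_pop(fx$workdir, 1))
})

test_that("1 worker and 4 workers produce identical merged output", {
  fx <- make_grid_fixture(83)
  cfg <- search_config(preset = "fast", masking = "none",
                       evalue_cutoff = 10)
  wd1 <- tempfile(); wd4 <- tempfile()
  out1 <- swarm_run(fx$qdb, fx$rdb, wd1, workers = 1,
                    query_chunk_letters = 150, ref_chunk_letters = 200,
                    config = cfg)
  out4 <- swarm_run(fx$qdb, fx$rdb, wd4, workers = 4,
                    query_chunk_letters = 150, ref_chunk_letters = 200,
                    config = cfg)
  expect_identical(sort(readLines(out1)), sort(readLines(out4)))
})

test_that("distributed output equals a monolithic run after canonical sort", {
  fx <- make_grid_fixture(84)
  cfg <- search_config(preset = "fast", masking = "none", evalue_cutoff = 10)
  wd <- tempfile()
  out <- swarm_run(fx$qdb, fx$rdb, wd, workers = 2,
                   query_chunk_letters = 130, ref_chunk_letters = 250,
                   config = cfg)
  mono <- run_search(load_database(fx$qdb), load_database(fx$rdb), cfg)
  mono_file <- tempfile()
  write_tabular(mono, mono_file)
  expect_identical(sort(readLines(out)), sort(readLines(mono_file)))
})

test_that("e-values after the join use the full database letter count", {
  fx <- make_grid_fixture(85)
  cfg <- search_config(preset = "fast", masking = "none", evalue_cutoff = 10)
  wd <- tempfile()
  plan_grid(fx$qdb, fx$rdb, 1e6, 200, wd)
  worker_run(wd, cfg)
  m <- jsonlite::read_json(file.path(wd, "manifest.json"))
  expect_gte(m$n_ref_chunks, 2)
  # per-chunk parts carry raw scores; their per-chunk e-values are strictly
  # smaller than the joined (full-n) e-values for the same alignment
  part <- NULL
  for (rc in seq_len(m$n_ref_chunks)) {
    p <- utils::read.table(seedhit:::part_path(wd, 1, rc), header = TRUE,
                           sep = "\t")
    if (nrow(p) > 0) { part <- p; chunk_id <- rc; break }
  }
  expect_false(is.null(part))
  rdb <- load_database(fx$rdb)
  chunk <- load_database(file.path(wd, "chunks",
                                   sprintf("ref_%03d.db", chunk_id)))
  e_chunk <- evalue_bitscore(part$score[1], part$qlen[1],
                             chunk$letters_total)$evalue
  e_full <- evalue_bitscore(part$score[1], part$qlen[1],
                            rdb$letters_total)$evalue
  expect_gt(e_full, e_chunk)
})

test_that("killed claims are requeued and completed runs are untouched", {
  fx <- make_grid_fixture(86)
  cfg <- search_config(preset = "fast", masking = "none", evalue_cutoff = 10)
  # clean reference run
  wd_ok <- tempfile()
  ok <- swarm_run(fx$qdb, fx$rdb, wd_ok, workers = 1,
                  query_chunk_letters = 150, ref_chunk_letters = 250,
                  config = cfg)
  # crashed run: a worker claims a package and dies without completing it
  wd <- tempfile()
  plan_grid(fx$qdb, fx$rdb, 150, 250, wd)
  dead <- stack_pop(wd, 1, worker_id = "dead")
  expect_false(is.null(dead))
  # too fresh to requeue: recovery must not steal a live claim
  expect_equal(recover_workdir(wd, staleness = 3600), 0L)
  # stale: requeued exactly once, idempotently
  expect_equal(recover_workdir(wd, staleness = 0), 1L)
  expect_equal(recover_workdir(wd, staleness = 0), 0L)
  # a later worker generation finishes the run with identical output
  worker_run(wd, cfg)
  m <- jsonlite::read_json(file.path(wd, "manifest.json"))
  outs <- unlist(lapply(seq_len(m$n_query_chunks), function(qc)
    readLines(file.path(wd, "results", sprintf("query_%03d.tsv", qc)))))
  expect_identical(sort(outs), sort(readLines(ok)))
})
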