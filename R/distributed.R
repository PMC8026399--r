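# File-based distributed work protocol. The query and reference databases
# are split into contiguous chunks; the Cartesian product of chunks defines
# work packages distributed through per-query-chunk file stacks whose push
# and pop are implemented with create-then-atomic-rename, the only portable
# filesystem transaction. Workers self-organize: any process may claim any
# pending package; the worker completing the last package of a query chunk
# performs the final join. No process is a designated coordinator, and
# claims left by dead workers can be requeued.

stack_dir <- function(workdir, qc) file.path(workdir, "stacks",
                                             sprintf("q%03d", qc))

#' Plan a distributed chunk grid
#'
#' Splits both databases into contiguous chunks by letter budget (never
#' splitting a sequence), writes per-chunk database files, one work stack per
#' query chunk holding its pending packages, and a manifest. Planning is
#' deterministic: replanning the same inputs produces an identical manifest.
#'
#' @param query_db,ref_db Paths to databases made by [make_database()].
#' @param query_chunk_letters,ref_chunk_letters Letter budget per chunk.
#' @param workdir Directory to initialize (must be empty or absent unless
#'   `resume = TRUE`).
#' @param shuffle Shuffle sequence order (deterministically from
#'   `shuffle_seed`) before chunking, to even out load.
#' @param shuffle_seed Seed for the shuffle.
#' @param resume Permit planning into a non-empty directory.
#' @return Invisibly, the manifest list.
#' @export
plan_grid <- function(query_db, ref_db, query_chunk_letters,
                      ref_chunk_letters, workdir, shuffle = FALSE,
                      shuffle_seed = 1L, resume = FALSE) {
  stopifnot(query_chunk_letters >= 1, ref_chunk_letters >= 1)
  if (dir.exists(workdir) && length(dir(workdir)) > 0 && !resume)
    stop("workdir not empty: ", workdir, " (use resume to override)")
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  qdb <- load_database(query_db)
  rdb <- load_database(ref_db)
  qord <- seq_along(qdb$ids)
  rord <- seq_along(rdb$ids)
  if (shuffle) {
    qord <- det_shuffle(length(qdb$ids), shuffle_seed)
    rord <- det_shuffle(length(rdb$ids), shuffle_seed + 1L)
  }
  qchunks <- chunk_by_letters(nchar(qdb$seq)[qord], query_chunk_letters)
  rchunks <- chunk_by_letters(nchar(rdb$seq)[rord], ref_chunk_letters)
  write_chunk <- function(db, ord, members, path) {
    idx <- ord[members]
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("#seedhitdb 1", paste("#sequences", length(idx)),
                 paste("#letters", sum(nchar(db$seq[idx])))), con, sep = "\n")
    writeLines(as.vector(rbind(paste0(">", db$ids[idx],
                                      ifelse(nzchar(db$desc[idx]),
                                             paste0(" ", db$desc[idx]), "")),
                               db$seq[idx])), con, sep = "\n")
  }
  dir.create(file.path(workdir, "chunks"), showWarnings = FALSE)
  dir.create(file.path(workdir, "parts"), showWarnings = FALSE)
  dir.create(file.path(workdir, "results"), showWarnings = FALSE)
  for (i in seq_along(qchunks))
    write_chunk(qdb, qord, qchunks[[i]],
                file.path(workdir, "chunks", sprintf("query_%03d.db", i)))
  for (j in seq_along(rchunks))
    write_chunk(rdb, rord, rchunks[[j]],
                file.path(workdir, "chunks", sprintf("ref_%03d.db", j)))
  for (i in seq_along(qchunks)) {
    sd <- stack_dir(workdir, i)
    dir.create(file.path(sd, "pending"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(sd, "claimed"), showWarnings = FALSE)
    dir.create(file.path(sd, "done"), showWarnings = FALSE)
    for (j in seq_along(rchunks)) stack_push(workdir, i, j)
    # join token: claimed by exactly one worker once all packages are done
    writeLines("pending", file.path(sd, "join.pending"))
  }
  manifest <- list(version = 1L, query_db = normalizePath(query_db),
                   ref_db = normalizePath(ref_db),
                   n_query_chunks = length(qchunks),
                   n_ref_chunks = length(rchunks),
                   query_chunk_letters = query_chunk_letters,
                   ref_chunk_letters = ref_chunk_letters,
                   total_ref_letters = rdb$letters_total,
                   shuffle = shuffle, shuffle_seed = shuffle_seed)
  jsonlite::write_json(manifest, file.path(workdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# Fisher-Yates with a private RNG stream (leaves the global seed untouched).
det_shuffle <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  sample.int(n)
}

chunk_by_letters <- function(lens, budget) {
  chunks <- list()
  cur <- integer(0)
  acc <- 0
  for (i in seq_along(lens)) {
    if (length(cur) > 0 && acc + lens[i] > budget) {
      chunks[[length(chunks) + 1L]] <- cur
      cur <- integer(0)
      acc <- 0
    }
    cur <- c(cur, i)
    acc <- acc + lens[i]
  }
  if (length(cur) > 0) chunks[[length(chunks) + 1L]] <- cur
  chunks
}

package_name <- function(qc, rc) sprintf("p_%03d_%03d", qc, rc)

stack_push <- function(workdir, qc, rc) {
  sd <- stack_dir(workdir, qc)
  tmp <- tempfile(tmpdir = sd)
  writeLines(jsonlite::toJSON(list(query_chunk = qc, ref_chunk = rc),
                              auto_unbox = TRUE), tmp)
  # durable before visible: write to a temporary name, then atomic rename
  file.rename(tmp, file.path(sd, "pending", package_name(qc, rc)))
}

#' Atomically pop a work package from a stack
#'
#' Claims one pending package of a query chunk via atomic rename; under any
#' number of concurrent callers each package is claimed exactly once.
#'
#' @param workdir Work directory from [plan_grid()].
#' @param query_chunk Query chunk id.
#' @param worker_id Identifier recorded on the claim.
#' @return A list (`query_chunk`, `ref_chunk`, `name`) or `NULL` when the
#'   stack is empty.
#' @export
stack_pop <- function(workdir, query_chunk, worker_id = Sys.getpid()) {
  sd <- stack_dir(workdir, query_chunk)
  repeat {
    pend <- list.files(file.path(sd, "pending"))
    if (length(pend) == 0) return(NULL)
    for (p in sort(pend)) {
      from <- file.path(sd, "pending", p)
      to <- file.path(sd, "claimed", p)
      ok <- suppressWarnings(file.rename(from, to))
      if (isTRUE(ok)) {
        writeLines(as.character(worker_id), paste0(to, ".worker"))
        meta <- jsonlite::read_json(to)
        return(list(query_chunk = meta$query_chunk,
                    ref_chunk = meta$ref_chunk, name = p))
      }
    }
    # every candidate was taken by another worker meanwhile; re-list
  }
}

mark_done <- function(workdir, pkg) {
  sd <- stack_dir(workdir, pkg$query_chunk)
  file.rename(file.path(sd, "claimed", pkg$name),
              file.path(sd, "done", pkg$name))
  unlink(file.path(sd, "claimed", paste0(pkg$name, ".worker")))
}

part_path <- function(workdir, qc, rc)
  file.path(workdir, "parts", sprintf("part_%03d_%03d.tsv", qc, rc))

PART_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
               "qstart", "qend", "sstart", "send", "score", "qlen")

#' Run one worker process
#'
#' Loops: pop a package, search the (query chunk x reference chunk) pair,
#' write the result part (atomically), mark the package done. After each
#' package, if all packages of the query chunk are done, the worker attempts
#' to claim the join token and, on success, merges that chunk's parts.
#' Returns when every stack is empty.
#'
#' @param workdir Work directory from [plan_grid()].
#' @param config A [search_config()] applied to every package.
#' @param worker_id Identifier for claim bookkeeping.
#' @return Invisibly, the number of packages this worker processed.
#' @export
worker_run <- function(workdir, config = search_config(),
                       worker_id = Sys.getpid()) {
  manifest <- jsonlite::read_json(file.path(workdir, "manifest.json"))
  nq <- manifest$n_query_chunks
  n_total <- manifest$total_ref_letters
  db_cache <- new.env(parent = emptyenv())
  getdb <- function(path) {
    key <- basename(path)
    if (is.null(db_cache[[key]])) db_cache[[key]] <- load_database(path)
    db_cache[[key]]
  }
  processed <- 0L
  for (qc in seq_len(nq)) {
    repeat {
      pkg <- stack_pop(workdir, qc, worker_id)
      if (is.null(pkg)) break
      qdb <- getdb(file.path(workdir, "chunks",
                             sprintf("query_%03d.db", pkg$query_chunk)))
      rdb <- getdb(file.path(workdir, "chunks",
                             sprintf("ref_%03d.db", pkg$ref_chunk)))
      res <- tryCatch(
        run_search(qdb, rdb, config, n_letters = rdb$letters_total),
        error = function(e) e)
      if (inherits(res, "error")) {
        # failed-requeueable: put the package back for another worker
        sd <- stack_dir(workdir, pkg$query_chunk)
        file.rename(file.path(sd, "claimed", pkg$name),
                    file.path(sd, "pending", pkg$name))
        stop("package ", pkg$name, " failed: ", conditionMessage(res))
      }
      res$qlen <- nchar(qdb$seq)[match(res$qseqid, qdb$ids)]
      tmp <- tempfile(tmpdir = file.path(workdir, "parts"))
      utils::write.table(res[, PART_COLS], tmp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      file.rename(tmp, part_path(workdir, pkg$query_chunk, pkg$ref_chunk))
      mark_done(workdir, pkg)
      processed <- processed + 1L
      maybe_join(workdir, pkg$query_chunk, manifest, config)
    }
    # parts may all exist while the join token was claimed by a worker that
    # died; recovery requeues it, so just retry here as well
    maybe_join(workdir, qc, manifest, config)
  }
  invisible(processed)
}

# The worker observing all packages of a query chunk done claims the join
# token (atomic rename) and merges the chunk's parts.
maybe_join <- function(workdir, qc, manifest, config) {
  sd <- stack_dir(workdir, qc)
  nr <- manifest$n_ref_chunks
  done <- list.files(file.path(sd, "done"))
  if (length(done) < nr) return(invisible(FALSE))
  tok <- file.path(sd, "join.pending")
  claimed <- suppressWarnings(file.rename(tok, file.path(sd, "join.claimed")))
  if (!isTRUE(claimed)) return(invisible(FALSE))
  finalize_join(workdir, qc, manifest, config)
  file.rename(file.path(sd, "join.claimed"), file.path(sd, "join.done"))
  invisible(TRUE)
}

#' Join the result parts of a query chunk
#'
#' Merges the per-reference-chunk hit lists, recomputes e-values against the
#' full reference letter count, re-applies the reporting cut-off and
#' `max_target_seqs` globally, deduplicates targets (best alignment kept)
#' and writes the chunk's final output. The merged output is identical to a
#' monolithic search of the chunk's queries against the whole reference.
#'
#' @param workdir,qc Work directory and query chunk id.
#' @param manifest Parsed manifest (read from the workdir if `NULL`).
#' @param config The search configuration used by the workers.
#' @return Invisibly, the output path.
#' @export
finalize_join <- function(workdir, qc, manifest = NULL,
                          config = search_config()) {
  if (is.null(manifest))
    manifest <- jsonlite::read_json(file.path(workdir, "manifest.json"))
  nr <- manifest$n_ref_chunks
  n_total <- manifest$total_ref_letters
  parts <- lapply(seq_len(nr), function(rc) {
    p <- part_path(workdir, qc, rc)
    if (!file.exists(p))
      stop("missing result part for package ", package_name(qc, rc))
    utils::read.table(p, header = TRUE, sep = "\t",
                      colClasses = c(qseqid = "character",
                                     sseqid = "character"))
  })
  all <- do.call(rbind, parts)
  out_path <- file.path(workdir, "results", sprintf("query_%03d.tsv", qc))
  if (nrow(all) == 0) {
    file.create(out_path)
    return(invisible(out_path))
  }
  eb <- evalue_bitscore(all$score, all$qlen, n_total, gapped = TRUE)
  all$bitscore <- eb$bitscore
  all$evalue <- eb$evalue
  all <- all[all$evalue <= config$evalue_cutoff, , drop = FALSE]
  all <- all[order(all$qseqid, all$evalue, -all$bitscore, all$sseqid), ,
             drop = FALSE]
  # best alignment per (query, target)
  all <- all[!duplicated(all[, c("qseqid", "sseqid")]), , drop = FALSE]
  all <- do.call(rbind, lapply(split(all, all$qseqid), function(d)
    utils::head(d, config$max_target_seqs)))
  con <- file(out_path, "wb")
  lines <- sprintf("%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f",
                   all$qseqid, all$sseqid, all$pident, all$length,
                   all$mismatch, all$gapopen, all$qstart, all$qend,
                   all$sstart, all$send, format_evalue(all$evalue),
                   all$bitscore)
  writeLines(lines, con, sep = "\n")
  close(con)
  invisible(out_path)
}

#' Requeue stale claims after worker failures
#'
#' Claims older than `staleness` seconds without a completed result are
#' returned to pending, as is a stale claimed join token. Completed work is
#' never redone; recovery is idempotent.
#'
#' @param workdir Work directory.
#' @param staleness Minimum claim age in seconds before requeueing
#'   (default 600).
#' @return Invisibly, the number of requeued packages.
#' @export
recover_workdir <- function(workdir, staleness = 600) {
  manifest <- jsonlite::read_json(file.path(workdir, "manifest.json"))
  requeued <- 0L
  now <- Sys.time()
  for (qc in seq_len(manifest$n_query_chunks)) {
    sd <- stack_dir(workdir, qc)
    for (p in list.files(file.path(sd, "claimed"), pattern = "^p_")) {
      if (endsWith(p, ".worker")) next
      f <- file.path(sd, "claimed", p)
      age <- as.numeric(difftime(now, file.mtime(f), units = "secs"))
      if (!is.na(age) && age >= staleness) {
        if (isTRUE(suppressWarnings(
          file.rename(f, file.path(sd, "pending", p))))) {
          unlink(paste0(f, ".worker"))
          requeued <- requeued + 1L
        }
      }
    }
    jc <- file.path(sd, "join.claimed")
    if (file.exists(jc) && !file.exists(file.path(sd, "join.done"))) {
      age <- as.numeric(difftime(now, file.mtime(jc), units = "secs"))
      if (!is.na(age) && age >= staleness)
        suppressWarnings(file.rename(jc, file.path(sd, "join.pending")))
    }
  }
  invisible(requeued)
}

#' Run a distributed search with local worker processes
#'
#' Convenience driver: plans the grid (unless resuming), forks `workers`
#' local worker processes, waits for completion, and concatenates the
#' per-query-chunk outputs.
#'
#' @inheritParams plan_grid
#' @param workers Number of concurrent local workers.
#' @param config A [search_config()].
#' @param resume Continue an existing workdir (after [recover_workdir()]).
#' @return Path of the merged output file.
#' @export
swarm_run <- function(query_db, ref_db, workdir, workers = 2L,
                      query_chunk_letters = 1e6, ref_chunk_letters = 1e6,
                      config = search_config(), shuffle = FALSE,
                      shuffle_seed = 1L, resume = FALSE) {
  if (!resume)
    plan_grid(query_db, ref_db, query_chunk_letters, ref_chunk_letters,
              workdir, shuffle, shuffle_seed)
  if (workers <= 1L) {
    worker_run(workdir, config)
  } else {
    parallel::mclapply(seq_len(workers), function(w)
      worker_run(workdir, config, worker_id = w), mc.cores = workers)
  }
  manifest <- jsonlite::read_json(file.path(workdir, "manifest.json"))
  out <- file.path(workdir, "output.tsv")
  chunk_files <- file.path(workdir, "results",
                           sprintf("query_%03d.tsv",
                                   seq_len(manifest$n_query_chunks)))
  missing <- chunk_files[!file.exists(chunk_files)]
  if (length(missing) > 0)
    stop("missing joined results: ", paste(basename(missing), collapse = ", "))
  writeLines(unlist(lapply(chunk_files, readLines)), out)
  out
}
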