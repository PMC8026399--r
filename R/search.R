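# End-to-end search orchestrator. Stage order is fixed: masking ->
# seeding/hash join -> Hamming window filter -> ungapped extension (with
# ungapped e-value cut-off) -> leftmost redundancy filter -> adaptive ranked
# extension (gapped-score filter -> chaining -> banded or full
# Smith-Waterman) -> e-value reporting.

#' Run a protein homology search
#'
#' @param query,ref `seed_db` objects (protein).
#' @param config A [search_config()].
#' @param n_letters Search-space letter count used for e-values; defaults to
#'   the reference database's total letters. The distributed protocol passes
#'   the full-database count when searching a reference chunk.
#' @param verbose Log per-stage hit counters to stderr.
#' @return Data frame of alignment records ordered per query by ascending
#'   e-value, then descending bit score, then subject id; at most
#'   `max_target_seqs` targets per query, all with e-value at or below the
#'   reporting cut-off. Columns: the 12 tabular output fields plus `score`,
#'   `frame`, `transcript`.
#' @export
run_search <- function(query, ref, config = search_config(),
                       n_letters = NULL, verbose = FALSE) {
  if (length(query) == 0 || length(ref) == 0) stop("empty database")
  if (!is.null(config$frameshift_penalty) &&
      identical(query$type, "protein"))
    stop("frameshift penalty is only valid for translated (DNA) queries")
  if (identical(query$type, "dna"))
    return(run_search_translated(query, ref, config, n_letters, verbose))
  if (is.null(n_letters)) n_letters <- ref$letters_total
  mat <- score_matrix(config$matrix)
  shapes <- load_shape_set(config$preset$mode)
  segs <- collect_segments(query, ref, shapes, config, mat, n_letters,
                           verbose)
  recs <- lapply(seq_along(query$ids), function(qi) {
    extend_query(qi, segs[segs$q == qi, , drop = FALSE], query, ref, config,
                 mat, n_letters)
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  out <- if (length(recs)) do.call(rbind, recs) else empty_records()
  rownames(out) <- NULL
  out
}

empty_records <- function() {
  data.frame(qseqid = character(0), sseqid = character(0),
             pident = numeric(0), length = integer(0), mismatch = integer(0),
             gapopen = integer(0), qstart = integer(0), qend = integer(0),
             sstart = integer(0), send = integer(0), evalue = numeric(0),
             bitscore = numeric(0), score = numeric(0), frame = integer(0),
             transcript = character(0), stringsAsFactors = FALSE)
}

# Seeding plus the three early filters, over all shapes. Returns the
# surviving diagonal segments: q, s, qstart, sstart, length, score, diag.
collect_segments <- function(query, ref, shapes, config, mat, n_letters,
                             verbose = FALSE) {
  preset <- config$preset
  qmask <- rmask <- NULL
  if (config$masking == "tantan") {
    qmask <- mask_database(query, config$mask_params, mat)
    rmask <- mask_database(ref, config$mask_params, mat)
  }
  hit_table <- build_hit_table(shapes)
  L <- max_span(shapes)
  # the ungapped e-value cut-off as a per-query minimum raw score:
  # E <= Eu  <=>  S >= (log2(m*n/Eu) * ln 2 + ln K) / lambda
  qlens <- vapply(query$enc, length, integer(1))
  min_score <- if (is.finite(preset$ungapped_evalue)) {
    (log(qlens * n_letters / preset$ungapped_evalue) +
       log(KA_UNGAPPED$K)) / KA_UNGAPPED$lambda
  } else rep(-1e18, length(qlens))
  n_seed <- 0L
  segs <- list()
  for (k in seq_along(shapes)) {
    sh <- shapes[[k]]
    qent <- extract_seeds_db(query, sh, qmask)
    rent <- extract_seeds_db(ref, sh, rmask)
    matches <- hash_join(qent, rent, config$partition_limit)
    n_seed <- n_seed + nrow(matches)
    if (nrow(matches) == 0) next
    disc <- if (!is.null(hit_table) && isTRUE(config$leftmost_filter))
      hit_table$discard[[k]] else logical(0)
    kept <- filter_matches_cpp(query$enc, ref$enc, matches$q_ord,
                               matches$q_off, matches$s_ord, matches$s_off,
                               sh$span, mat, config$xdrop,
                               preset$hamming_cutoff, HAMMING_WINDOW,
                               min_score, disc, L)
    if (nrow(kept) > 0) segs[[length(segs) + 1L]] <- kept
  }
  if (length(segs) == 0) {
    if (verbose) message(sprintf("hits: seed=%d surviving=0", n_seed))
    return(data.frame(q = integer(0), s = integer(0), qstart = integer(0),
                      sstart = integer(0), length = integer(0),
                      score = numeric(0), diag = integer(0)))
  }
  m <- do.call(rbind, segs)
  if (verbose)
    message(sprintf("hits: seed=%d surviving=%d", n_seed, nrow(m)))
  out <- data.frame(q = m[, 1], s = m[, 2], qstart = m[, 3], sstart = m[, 4],
                    length = m[, 5], score = m[, 6], diag = m[, 4] - m[, 3])
  out <- out[!duplicated(out[, c("q", "s", "qstart", "sstart", "length")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Adaptive ranked extension for one query's surviving segments.
extend_query <- function(qi, segs_q, query, ref, config, mat, n_letters) {
  if (nrow(segs_q) == 0) return(NULL)
  preset <- config$preset
  eq <- query$enc[[qi]]
  m <- length(eq)
  q_comp <- if (config$comp_based_stats == 1L) residue_composition(eq) else NULL
  ranking <- rank_targets(segs_q)
  extend_one <- function(t) {
    st <- segs_q[segs_q$s == t, , drop = FALSE]
    es <- ref$enc[[t]]
    pair_mat <- mat
    if (!is.null(q_comp))
      pair_mat <- comp_adjust(mat, q_comp, residue_composition(es))
    if (preset$gapped_filter_evalue > 0) {
      dm <- diagonal_maxima(eq, es, min(st$diag) - config$band_pad,
                            max(st$diag) + config$band_pad, pair_mat)
      s_est <- gapped_filter_score(dm, config$gap_open, diag_band = Inf)
      e_est <- evalue_bitscore(s_est, m, n_letters, gapped = TRUE)$evalue
      if (e_est > preset$gapped_filter_evalue) return(NULL)
    }
    aln <- if (config$ext_mode == "full") {
      sw_full_cpp(eq, es, pair_mat, config$gap_open, config$gap_extend)
    } else {
      ch <- chain_segments(st, eq, es, pair_mat, config$gap_open,
                           config$gap_extend, config$band_pad)
      sw_banded_cpp(eq, es, pair_mat, config$gap_open, config$gap_extend,
                    as.integer(ch$band$d_min), as.integer(ch$band$d_max))
    }
    if (aln$score <= 0) return(NULL)
    make_record(aln, eq, es, m, n_letters, config$gap_open,
                config$gap_extend, qseqid = query$ids[qi],
                sseqid = ref$ids[t])
  }
  recs <- adaptive_extend(ranking, preset$ext_chunk_size, extend_one,
                          function(r) r$evalue <= config$evalue_cutoff)
  if (length(recs) == 0) return(NULL)
  out <- do.call(rbind, recs)
  out <- out[out$evalue <= config$evalue_cutoff, , drop = FALSE]
  if (nrow(out) == 0) return(NULL)
  out <- out[order(out$evalue, -out$bitscore, out$sseqid), , drop = FALSE]
  utils::head(out, config$max_target_seqs)
}

# Translated (blastx-style) search: translate all six frames, seed and
# filter on the frames, then either report per-frame local alignments or,
# when a frameshift penalty is set, realign read against target with the
# frameshift-aware dynamic program. Reporting is per read, frame recorded.
run_search_translated <- function(query, ref, config, n_letters = NULL,
                                  verbose = FALSE) {
  if (is.null(n_letters)) n_letters <- ref$letters_total
  mat <- score_matrix(config$matrix)
  shapes <- load_shape_set(config$preset$mode)
  frames <- c("1", "2", "3", "-1", "-2", "-3")
  fr_ids <- character(0); fr_seq <- character(0)
  fr_read <- integer(0); fr_frame <- integer(0); fr_off <- list()
  for (i in seq_along(query$ids)) {
    tr <- translate_frames(query$seq[i])
    for (f in frames) {
      res <- tr[[f]]$residues
      if (nchar(res) == 0) next
      fr_ids <- c(fr_ids, paste0(query$ids[i], "|", f))
      fr_seq <- c(fr_seq, res)
      fr_read <- c(fr_read, i)
      fr_frame <- c(fr_frame, as.integer(f))
      fr_off[[length(fr_off) + 1L]] <- tr[[f]]$nt_offset
    }
  }
  fdb <- new_seq_db(fr_ids, rep("", length(fr_ids)), fr_seq)
  segs <- collect_segments(fdb, ref, shapes, config, mat, n_letters, verbose)
  out <- list()
  for (i in seq_along(query$ids)) {
    fidx <- which(fr_read == i)
    segs_i <- segs[segs$q %in% fidx, , drop = FALSE]
    if (nrow(segs_i) == 0) next
    if (!is.null(config$frameshift_penalty)) {
      targets <- unique(segs_i$s)
      recs <- lapply(targets, function(t) {
        a <- frameshift_align(query$seq[i], ref$enc[[t]],
                              config$frameshift_penalty, mat,
                              config$gap_open, config$gap_extend)
        if (a$score <= 0) return(NULL)
        frameshift_record(a, query, i, ref, t, n_letters, mat)
      })
      recs <- recs[!vapply(recs, is.null, logical(1))]
      if (length(recs) == 0) next
      rr <- do.call(rbind, recs)
    } else {
      # per-frame protein extension, then map coordinates to nucleotides
      sub_cfg <- config
      per_frame <- lapply(fidx, function(fq) {
        r <- extend_query(fq, segs_i[segs_i$q == fq, , drop = FALSE], fdb,
                          ref, sub_cfg, mat, n_letters)
        if (is.null(r)) return(NULL)
        f <- fr_frame[fq]
        off <- fr_off[[fq]]
        nt_start <- off[r$qstart] + 1L
        nt_end <- off[r$qend] + 1L
        if (f > 0) nt_end <- nt_end + 2L else nt_end <- nt_end - 2L
        r$qstart <- nt_start
        r$qend <- nt_end
        r$frame <- f
        r$qseqid <- query$ids[i]
        r
      })
      per_frame <- per_frame[!vapply(per_frame, is.null, logical(1))]
      if (length(per_frame) == 0) next
      rr <- do.call(rbind, per_frame)
      # best alignment per target across frames
      rr <- rr[order(rr$evalue, -rr$bitscore, rr$sseqid), , drop = FALSE]
      rr <- rr[!duplicated(rr$sseqid), , drop = FALSE]
    }
    rr <- rr[rr$evalue <= config$evalue_cutoff, , drop = FALSE]
    if (nrow(rr) == 0) next
    rr <- rr[order(rr$evalue, -rr$bitscore, rr$sseqid), , drop = FALSE]
    out[[length(out) + 1L]] <- utils::head(rr, config$max_target_seqs)
  }
  res <- if (length(out)) do.call(rbind, out) else empty_records()
  rownames(res) <- NULL
  res
}

frameshift_record <- function(a, query, qi, ref, t, n_letters, mat) {
  es <- ref$enc[[t]]
  # reconstruct the emitted residues to count identities along the transcript
  ops <- strsplit(a$transcript, "", fixed = TRUE)[[1]]
  m_aa <- nchar(query$seq[qi]) %/% 3
  eb <- evalue_bitscore(a$score, max(1L, m_aa), n_letters, gapped = TRUE)
  aligned <- sum(ops %in% c("M", "/", "\\"))
  gapo <- sum(rle(ops)$values %in% c("I", "D"))
  # identities from a replay of the DP emissions
  ident <- frameshift_identities(a, query$seq[qi], es)
  len <- length(ops)
  data.frame(qseqid = query$ids[qi], sseqid = ref$ids[t],
             pident = if (len > 0) 100 * ident / len else 0,
             length = len, mismatch = aligned - ident, gapopen = gapo,
             qstart = a$qstart_nt + 1L, qend = a$qend_nt + 1L,
             sstart = a$sstart + 1L, send = a$send + 1L,
             evalue = eb$evalue, bitscore = eb$bitscore, score = a$score,
             frame = a$strand * a$frame, transcript = a$transcript,
             stringsAsFactors = FALSE)
}

# Count identical aligned residue pairs of a frameshift alignment by
# replaying its transcript over the read.
frameshift_identities <- function(a, dna, es) {
  strand_seq <- if (a$strand == 1L) dna else revcomp(dna)
  nt <- encode_nucleotides(strand_seq)
  tab <- codon_table()
  ops <- strsplit(a$transcript, "", fixed = TRUE)[[1]]
  # DP coordinates were on the aligned strand
  i <- if (a$strand == 1L) a$qstart_nt else nchar(dna) - 1L - a$qend_nt
  j <- a$sstart
  ident <- 0L
  for (op in ops) {
    di <- switch(op, "M" = 3L, "/" = 2L, "\\" = 4L, "I" = 3L, "D" = 0L)
    if (op %in% c("M", "/", "\\")) {
      e <- i + di  # 0-based end (exclusive) after the move
      c1 <- nt[e - 2L]; c2 <- nt[e - 1L]; c3 <- nt[e]
      aa <- if (any(c(c1, c2, c3) > 3L)) AA_X
            else tab[16L * c1 + 4L * c2 + c3 + 1L]
      if (aa == es[j + 1L]) ident <- ident + 1L
      j <- j + 1L
    } else if (op == "D") {
      j <- j + 1L
    }
    i <- i + di
  }
  ident
}
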