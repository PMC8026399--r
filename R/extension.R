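# Target ranking, the gapped-score heuristic filter, diagonal-segment
# chaining, banded/full Smith-Waterman extension and frameshift alignment.

#' Rank targets by best ungapped extension score
#'
#' @param segments Data frame of diagonal segments with columns `s` (target
#'   ordinal) and `score`.
#' @return Data frame `target`, `best_score`, ordered by descending score,
#'   ties broken by ascending target ordinal.
#' @export
rank_targets <- function(segments) {
  if (nrow(segments) == 0)
    return(data.frame(target = integer(0), best_score = integer(0)))
  best <- vapply(split(segments$score, segments$s), max, numeric(1))
  targ <- as.integer(names(best))
  ord <- order(-best, targ)
  data.frame(target = targ[ord], best_score = unname(best[ord]))
}

#' Gapped-score heuristic estimate
#'
#' Estimates a gapped alignment score from per-diagonal ungapped maxima while
#' disregarding where the diagonal segments lie: with sorted diagonal maxima
#' `s1 >= s2 >= ...`, the estimate is `s1 + sum_i>=2 max(0, s_i -
#' gap_open_cost)`. It is always at least the best single-diagonal score and
#' tends to overestimate the true gapped score.
#'
#' @param segments Data frame with columns `diag` and `score`.
#' @param gap_open_cost Gap-open penalty charged per extra diagonal.
#' @param diag_band Only diagonals within this distance of the best
#'   segment's diagonal contribute.
#' @return The score estimate (numeric scalar).
#' @export
gapped_filter_score <- function(segments, gap_open_cost = 11L,
                                diag_band = 64L) {
  if (nrow(segments) == 0) return(0)
  dmax <- vapply(split(segments$score, segments$diag), max, numeric(1))
  diags <- as.numeric(names(dmax))
  centre <- diags[which.max(dmax)]
  dmax <- dmax[abs(diags - centre) <= diag_band]
  s <- sort(unname(dmax), decreasing = TRUE)
  s[1] + sum(pmax(0, s[-1] - gap_open_cost))
}

#' Per-diagonal maximal ungapped scores
#'
#' Sweeps a query profile along every diagonal of a band, recording the best
#' contiguous ungapped score per diagonal (never below 0). These maxima are
#' the input of [gapped_filter_score()] in the pipeline: they upper-bound any
#' single alignment run on their diagonal, which is what makes the heuristic
#' estimate an overestimate of the true gapped score in the band (barring
#' alignments that revisit a diagonal).
#'
#' @param q,s Residue strings or integer code vectors.
#' @param d_min,d_max Diagonal band (subject minus query, 0-based).
#' @param matrix Scoring matrix.
#' @return Data frame with columns `diag` and `score`.
#' @export
diagonal_maxima <- function(q, s, d_min, d_max, matrix = score_matrix()) {
  if (is.character(q)) q <- encode_residues(q)
  if (is.character(s)) s <- encode_residues(s)
  m <- diagonal_max_scores_cpp(q, s, matrix, as.integer(d_min),
                               as.integer(d_max))
  data.frame(diag = m[, 1], score = m[, 2])
}

# Column-wise score of part of a diagonal segment, recomputed from the
# matrix; used for overlap trimming in chaining.
segment_col_scores <- function(seg, enc_q, enc_s, matrix) {
  qi <- seg$qstart + seq_len(seg$length)
  si <- seg$sstart + seq_len(seg$length)
  matrix[cbind(enc_q[qi] + 1L, enc_s[si] + 1L)]
}

#' Chain diagonal segments and derive the extension band
#'
#' Dynamic programming over diagonal segments rather than residues: segments
#' are sorted by subject start and connected in one left-to-right pass;
#' shifting between diagonals costs `gap_open + gap_extend * |diagonal
#' shift|`, co-diagonal connections are free. When consecutive segments
#' overlap in query or subject, the lower-scoring segment is trimmed
#' column-wise (scores recomputed from the matrix). The best chain's diagonal
#' range, padded by `band_pad`, gives the band for the banded extension.
#'
#' @param segments Data frame with columns `qstart`, `sstart`, `length`,
#'   `score`, `diag` (0-based coordinates).
#' @param enc_q,enc_s Encoded query/subject sequences (for overlap trimming).
#' @param matrix Scoring matrix.
#' @param gap_open,gap_extend Affine gap penalties.
#' @param band_pad Diagonals added each side of the chain's range.
#' @return List with `score`, `members` (row indices of the chain, in chain
#'   order) and `band` (`d_min`, `d_max`).
#' @export
chain_segments <- function(segments, enc_q, enc_s, matrix = score_matrix(),
                           gap_open = 11L, gap_extend = 1L, band_pad = 16L) {
  n <- nrow(segments)
  if (n == 0) stop("no segments to chain")
  ord <- order(segments$sstart, segments$qstart, segments$diag)
  segs <- segments[ord, , drop = FALSE]
  cols <- lapply(seq_len(n), function(i)
    segment_col_scores(segs[i, ], enc_q, enc_s, matrix))
  best <- numeric(n)
  pred <- integer(n)
  for (v in seq_len(n)) {
    best[v] <- segs$score[v]
    pred[v] <- 0L
    if (v == 1) next
    for (u in seq_len(v - 1)) {
      cand <- chain_edge_value(segs[u, ], segs[v, ], best[u], cols[[u]],
                               cols[[v]], gap_open, gap_extend)
      if (!is.na(cand) && cand > best[v]) {
        best[v] <- cand
        pred[v] <- u
      }
    }
  }
  top <- which.max(best)
  chain <- integer(0)
  v <- top
  while (v != 0L) {
    chain <- c(v, chain)
    v <- pred[v]
  }
  diags <- segs$diag[chain]
  list(score = best[top], members = ord[chain],
       band = list(d_min = min(diags) - band_pad,
                   d_max = max(diags) + band_pad))
}

# Value of chaining u -> v given best score ending at u. Returns NA when the
# connection is invalid (v not strictly after u, or overlap swallows a whole
# segment).
chain_edge_value <- function(u, v, best_u, cols_u, cols_v, gap_open,
                             gap_extend) {
  if (v$sstart <= u$sstart || v$qstart <= u$qstart) return(NA_real_)
  dd <- v$diag - u$diag
  cost <- if (dd == 0) 0 else gap_open + gap_extend * abs(dd)
  ov <- max(0, u$sstart + u$length - v$sstart, u$qstart + u$length - v$qstart)
  if (ov == 0) return(max(best_u - cost, 0) + v$score)
  if (ov >= u$length || ov >= v$length) return(NA_real_)
  if (u$score >= v$score) {
    v_trim <- sum(cols_v[(ov + 1):v$length])
    max(best_u - cost, 0) + v_trim
  } else {
    u_tail <- sum(cols_u[(u$length - ov + 1):u$length])
    max(best_u - u_tail - cost, 0) + v$score
  }
}

transcript_stats <- function(transcript, enc_q, enc_s, qstart, sstart,
                             translated_aa = NULL) {
  ops <- strsplit(transcript, "", fixed = TRUE)[[1]]
  len <- length(ops)
  qi <- qstart
  si <- sstart
  ident <- 0L
  mism <- 0L
  gapo <- 0L
  prev_gap <- FALSE
  ai <- 0L
  for (op in ops) {
    if (op %in% c("M", "/", "\\")) {
      ai <- ai + 1L
      qa <- if (is.null(translated_aa)) enc_q[qi + 1L] else translated_aa[ai]
      if (!is.na(qa) && qa == enc_s[si + 1L]) ident <- ident + 1L
      else mism <- mism + 1L
      qi <- qi + 1L
      si <- si + 1L
      prev_gap <- FALSE
    } else if (op == "I") {
      if (!prev_gap) gapo <- gapo + 1L
      prev_gap <- TRUE
      qi <- qi + 1L
      ai <- ai + 1L
    } else if (op == "D") {
      if (!prev_gap) gapo <- gapo + 1L
      prev_gap <- TRUE
      si <- si + 1L
    }
  }
  list(length = len, identities = ident, mismatch = mism, gapopen = gapo,
       pident = if (len > 0) 100 * ident / len else 0)
}

make_record <- function(aln, enc_q, enc_s, m, n, gap_open, gap_extend,
                        qseqid = NA_character_, sseqid = NA_character_,
                        frame = NA_integer_) {
  st <- transcript_stats(aln$transcript, enc_q, enc_s, aln$qstart, aln$sstart)
  eb <- evalue_bitscore(aln$score, m, n, gapped = TRUE)
  data.frame(qseqid = qseqid, sseqid = sseqid, pident = st$pident,
             length = st$length, mismatch = st$mismatch, gapopen = st$gapopen,
             qstart = aln$qstart + 1L, qend = aln$qend + 1L,
             sstart = aln$sstart + 1L, send = aln$send + 1L,
             evalue = eb$evalue, bitscore = eb$bitscore, score = aln$score,
             frame = frame, transcript = aln$transcript,
             stringsAsFactors = FALSE)
}

#' Full-matrix local Smith-Waterman alignment
#'
#' Textbook affine-gap local alignment with traceback, optimal over the full
#' dynamic-programming matrix.
#'
#' @param q,s Residue strings or integer code vectors.
#' @param matrix Scoring matrix.
#' @param gap_open,gap_extend Affine gap penalties (gap of length k costs
#'   `gap_open + k * gap_extend`).
#' @return List with `score`, 0-based `qstart`, `qend`, `sstart`, `send`
#'   (inclusive; `qend < qstart` for an empty alignment) and `transcript`
#'   over ops `M`, `I` (gap in subject), `D` (gap in query).
#' @export
full_smith_waterman <- function(q, s, matrix = score_matrix(),
                                gap_open = 11L, gap_extend = 1L) {
  if (is.character(q)) q <- encode_residues(q)
  if (is.character(s)) s <- encode_residues(s)
  sw_full_cpp(q, s, matrix, gap_open, gap_extend)
}

#' Banded local Smith-Waterman alignment
#'
#' As [full_smith_waterman()], restricted to cells whose diagonal
#' `j - i` (subject minus query, 0-based) lies within `[d_min, d_max]`. The
#' score is optimal within the band.
#'
#' @inheritParams full_smith_waterman
#' @param band List or vector with `d_min`, `d_max`.
#' @export
banded_smith_waterman <- function(q, s, band, matrix = score_matrix(),
                                  gap_open = 11L, gap_extend = 1L) {
  if (is.character(q)) q <- encode_residues(q)
  if (is.character(s)) s <- encode_residues(s)
  b <- as.list(band)
  sw_banded_cpp(q, s, matrix, gap_open, gap_extend, as.integer(b$d_min),
                as.integer(b$d_max))
}

#' Frameshift-aware translated alignment
#'
#' Aligns a nucleotide read against a protein subject, translating on the
#' fly: codon moves consume 3 nucleotides; the reading frame may shift at
#' any position by consuming 2 or 4 nucleotides at penalty `F`; protein-level
#' gaps use the affine model. Both strands are evaluated and the better one
#' is returned. `F = Inf` disables frameshifts, collapsing the move set to
#' single-frame local alignment.
#'
#' @param dna Nucleotide read (string over A,C,G,T,N), length >= 3.
#' @param protein Protein subject (string or codes).
#' @param F Frameshift penalty (positive; may be `Inf`).
#' @inheritParams full_smith_waterman
#' @return List with `score`, `strand` (+1/-1), `frame` (1..3 on the
#'   reported strand), nucleotide query range `qstart_nt`/`qend_nt` (0-based
#'   on the forward strand), subject range, `transcript` (ops `M`, `I`, `D`,
#'   `/` = 2-nt codon, `\` = 4-nt codon) and `n_frameshifts`.
#' @export
frameshift_align <- function(dna, protein, F, matrix = score_matrix(),
                             gap_open = 11L, gap_extend = 1L) {
  if (!is.numeric(F) || length(F) != 1 || F <= 0)
    stop("frameshift penalty must be positive")
  if (nchar(dna) < 3) stop("read shorter than one codon")
  if (is.character(protein)) protein <- encode_residues(protein)
  fs <- if (is.finite(F)) as.integer(F) else 10000000L
  tab <- codon_table()
  n <- nchar(dna)
  fwd <- frameshift_sw_cpp(encode_nucleotides(dna), protein, matrix,
                           gap_open, gap_extend, fs, tab, AA_X)
  rev <- frameshift_sw_cpp(encode_nucleotides(revcomp(dna)), protein, matrix,
                           gap_open, gap_extend, fs, tab, AA_X)
  use_rev <- rev$score > fwd$score
  a <- if (use_rev) rev else fwd
  nfs <- sum(strsplit(a$transcript, "", fixed = TRUE)[[1]] %in% c("/", "\\"))
  qs <- a$qstart_nt
  qe <- a$qend_nt
  if (use_rev) {  # map back to forward-strand coordinates
    qs2 <- n - 1 - a$qend_nt
    qe2 <- n - 1 - a$qstart_nt
    qs <- qe2
    qe <- qs2
  }
  list(score = a$score, strand = if (use_rev) -1L else 1L,
       frame = (a$qstart_nt %% 3L) + 1L, qstart_nt = qs, qend_nt = qe,
       sstart = a$sstart, send = a$send, transcript = a$transcript,
       n_frameshifts = nfs)
}

#' Adaptive ranked extension
#'
#' Processes a ranked target list in fixed-size chunks, calling
#' `extend_fun(target)` for each target. Extension stops after the first
#' chunk in which no target produced a significant alignment (as judged by
#' `significant_fun` on each result). All results from processed chunks are
#' retained.
#'
#' @param ranking Data frame from [rank_targets()].
#' @param chunk_size Targets per chunk (>= 1).
#' @param extend_fun Function of a target ordinal returning a result or
#'   `NULL`.
#' @param significant_fun Predicate on a result.
#' @return List of non-`NULL` results from all processed chunks.
#' @export
adaptive_extend <- function(ranking, chunk_size, extend_fun, significant_fun) {
  stopifnot(chunk_size >= 1)
  out <- list()
  nt <- nrow(ranking)
  i <- 1L
  while (i <= nt) {
    idx <- i:min(i + chunk_size - 1L, nt)
    any_sig <- FALSE
    for (t in ranking$target[idx]) {
      res <- extend_fun(t)
      if (!is.null(res)) {
        out[[length(out) + 1L]] <- res
        if (isTRUE(significant_fun(res))) any_sig <- TRUE
      }
    }
    if (!any_sig) break
    i <- i + chunk_size
  }
  out
}
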