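# Shared fixtures and independent oracles. Everything is generated in code;
# Biostrings::pairwiseAlignment is the independent alignment oracle.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

# mutate a fraction of positions to random other residues
mutate_seq <- function(s, rate) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- which(stats::runif(length(ch)) < rate)
  for (i in idx) ch[i] <- sample(setdiff(AA20, ch[i]), 1)
  paste(ch, collapse = "")
}

write_temp_fasta <- function(seqs, ids = sprintf("s%03d", seq_along(seqs)),
                             path = tempfile(fileext = ".fa")) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

make_test_db <- function(seqs, ids = sprintf("s%03d", seq_along(seqs))) {
  read_fasta(write_temp_fasta(seqs, ids))
}

blosum62_full <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})

# Independent local-alignment oracle
oracle_sw_score <- function(q, s) {
  Biostrings::pairwiseAlignment(q, s, type = "local",
                                substitutionMatrix = blosum62_full,
                                gapOpening = 11, gapExtension = 1,
                                scoreOnly = TRUE)
}

# Independent global-alignment oracle: score and identity over all columns
oracle_nw <- function(q, s) {
  p <- Biostrings::pairwiseAlignment(q, s, type = "global",
                                     substitutionMatrix = blosum62_full,
                                     gapOpening = 11, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(p)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(p)), "")[[1]]
  list(score = Biostrings::score(p),
       identity = 100 * sum(pa == sa) / length(pa))
}

# Nested-loop join oracle over seed tables
oracle_nested_join <- function(q, r) {
  rows <- list()
  for (i in seq_len(nrow(q)))
    for (j in seq_len(nrow(r)))
      if (q$code[i] == r$code[j])
        rows[[length(rows) + 1L]] <- data.frame(
          code = q$code[i], q_ord = q$ord[i], q_off = q$off[i],
          s_ord = r$ord[j], s_off = r$off[j])
  if (length(rows) == 0)
    return(data.frame(code = numeric(0), q_ord = integer(0),
                      q_off = integer(0), s_ord = integer(0),
                      s_off = integer(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$code, out$q_ord, out$q_off, out$s_ord, out$s_off), ]
  rownames(out) <- NULL
  out
}

# Brute-force chaining oracle: enumerate every ordered subset of segments
# under the same transition/trim cost model, computed independently.
oracle_chain_score <- function(segments, enc_q, enc_s, matrix,
                               gap_open = 11, gap_extend = 1) {
  n <- nrow(segments)
  col_score <- function(seg, from, to) {
    qi <- seg$qstart + from:to
    si <- seg$sstart + from:to
    sum(matrix[cbind(enc_q[qi + 1], enc_s[si + 1])])
  }
  seg_score <- function(i) col_score(segments[i, ], 0, segments$length[i] - 1)
  best <- -Inf
  # chains as ordered index sequences with strictly increasing q/s starts
  extend <- function(chain, score) {
    best <<- max(best, score)
    last <- chain[length(chain)]
    for (v in seq_len(n)) {
      if (v %in% chain) next
      u <- segments[last, ]; w <- segments[v, ]
      if (w$sstart <= u$sstart || w$qstart <= u$qstart) next
      dd <- w$diag - u$diag
      cost <- if (dd == 0) 0 else gap_open + gap_extend * abs(dd)
      ov <- max(0, u$sstart + u$length - w$sstart,
                u$qstart + u$length - w$qstart)
      if (ov >= u$length || ov >= w$length) next
      wsc <- seg_score(v)
      usc <- seg_score(last)
      val <- if (ov == 0) max(score - cost, 0) + wsc
      else if (usc >= wsc)
        max(score - cost, 0) + col_score(w, ov, w$length - 1)
      else max(score - col_score(u, u$length - ov, u$length - 1) - cost, 0) + wsc
      extend(c(chain, v), val)
    }
  }
  for (st in seq_len(n)) extend(st, seg_score(st))
  best
}

# diagonal range actually visited by a local alignment's optimal path
path_diag_range <- function(a) {
  i <- a$qstart; j <- a$sstart
  d <- j - i
  for (op in strsplit(a$transcript, "")[[1]]) {
    if (op == "M") { i <- i + 1; j <- j + 1 }
    else if (op == "I") i <- i + 1
    else j <- j + 1
    d <- c(d, j - i)
  }
  range(d)
}

# random consistent diagonal segments over a pair of sequences
random_segments <- function(n_seg, enc_q, enc_s, matrix) {
  m <- length(enc_q); n <- length(enc_s)
  rows <- lapply(seq_len(n_seg), function(i) {
    len <- sample(3:8, 1)
    qs <- sample(0:(m - len), 1)
    ss <- sample(0:(n - len), 1)
    sc <- sum(matrix[cbind(enc_q[qs + 1:len], enc_s[ss + 1:len])])
    data.frame(qstart = qs, sstart = ss, length = len, score = sc,
               diag = ss - qs)
  })
  do.call(rbind, rows)
}
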