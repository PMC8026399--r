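test_that("rank_targets orders by best score with ordinal tie-break", {
  segs <- data.frame(s = c(1L, 1L, 2L), score = c(50, 10, 70))
  r <- rank_targets(segs)
  expect_equal(r$target, c(2L, 1L))
  expect_equal(r$best_score, c(70, 50))

  # equal best scores: ascending target ordinal
  segs2 <- data.frame(s = c(5L, 3L), score = c(40, 40))
  expect_equal(rank_targets(segs2)$target, c(3L, 5L))

  # adding a lower-scoring segment never changes the order
  segs3 <- rbind(segs, data.frame(s = 1L, score = 1))
  expect_equal(rank_targets(segs3)$target, r$target)
})

test_that("gapped filter score follows the one-dimensional dynamic program", {
  one <- data.frame(diag = 0L, score = 30)
  expect_equal(gapped_filter_score(one, 11), 30)

  two <- data.frame(diag = c(0L, 5L), score = c(30, 20))
  expect_equal(gapped_filter_score(two, 11), 39)  # 30 + (20 - 11)

  # always at least the best single diagonal
  set.seed(12)
  for (rep in 1:20) {
    d <- data.frame(diag = sample(-20:20, 6), score = sample(5:60, 6))
    expect_gte(gapped_filter_score(d, 11), max(d$score))
  }
})

test_that("gapped filter overestimates the banded score for homolog pairs", {
  set.seed(88)
  fx <- generate_families(seed = 88, n_folds = 3, decoy_count = 5,
                          target_identity = c(0.35, 0.5))
  cfg <- search_config(preset = "very-sensitive", masking = "none")
  mat <- score_matrix()
  shapes <- load_shape_set("very-sensitive")
  segs <- seedhit:::collect_segments(fx$queries, fx$db, shapes, cfg,
                                     mat, fx$db$letters_total)
  pairs <- unique(segs[, c("q", "s")])
  over <- logical(0)
  for (i in seq_len(nrow(pairs))) {
    st <- segs[segs$q == pairs$q[i] & segs$s == pairs$s[i], ]
    eq <- fx$queries$enc[[pairs$q[i]]]
    es <- fx$db$enc[[pairs$s[i]]]
    dm <- diagonal_maxima(eq, es, min(st$diag) - 16, max(st$diag) + 16, mat)
    est <- gapped_filter_score(dm, 11, diag_band = Inf)
    ch <- chain_segments(st, eq, es, mat)
    true <- banded_smith_waterman(eq, es, ch$band, mat)$score
    over <- c(over, est >= true)
  }
  expect_gte(length(over), 30)
  expect_gte(mean(over), 0.9)
})

test_that("chaining handles single segments, free co-diagonal joins, bands", {
  mat <- score_matrix()
  eq <- seedhit:::encode_residues(random_protein(60))
  es <- eq
  one <- data.frame(qstart = 5L, sstart = 15L, length = 6L,
                    score = sum(mat[cbind(eq[6:11] + 1, es[16:21] + 1)]),
                    diag = 10L)
  ch <- chain_segments(one, eq, es, mat, band_pad = 16L)
  expect_equal(ch$score, one$score)
  expect_equal(ch$band$d_min, 10 - 16)
  expect_equal(ch$band$d_max, 10 + 16)

  # two non-overlapping co-diagonal segments chain with zero cost
  two <- data.frame(qstart = c(0L, 20L), sstart = c(0L, 20L),
                    length = c(5L, 5L), score = c(25, 15), diag = c(0L, 0L))
  ch2 <- chain_segments(two, eq, es, mat)
  expect_equal(ch2$score, 40)
  expect_equal(length(ch2$members), 2L)
  expect_error(chain_segments(two[0, ], eq, es, mat), "no segments")
})

test_that("chain score equals brute-force enumeration on random sets", {
  set.seed(55)
  mat <- score_matrix()
  for (rep in 1:12) {
    eq <- seedhit:::encode_residues(random_protein(50))
    es <- seedhit:::encode_residues(random_protein(50))
    segs <- random_segments(sample(2:6, 1), eq, es, mat)
    got <- chain_segments(segs, eq, es, mat)$score
    want <- oracle_chain_score(segs, eq, es, mat)
    expect_equal(got, want)
  }
})

test_that("full Smith-Waterman agrees with the independent oracle", {
  set.seed(303)
  for (rep in 1:60) {
    q <- random_protein(sample(20:80, 1))
    s <- if (rep %% 2 == 0) random_protein(sample(20:80, 1))
         else mutate_seq(q, runif(1, 0.2, 0.7))
    expect_equal(full_smith_waterman(q, s)$score, oracle_sw_score(q, s))
  }
  # disjoint alphabets with all-negative scores -> empty alignment
  a <- full_smith_waterman("WWWW", "PPPP")
  expect_equal(a$score, 0)
  expect_equal(a$transcript, "")
  # self-alignment scores the diagonal sum
  q <- random_protein(30)
  mat <- score_matrix()
  eq <- seedhit:::encode_residues(q)
  expect_equal(full_smith_waterman(q, q)$score,
               sum(mat[cbind(eq + 1, eq + 1)]))
})

test_that("alignment records are internally consistent", {
  set.seed(304)
  mat <- score_matrix()
  for (rep in 1:10) {
    q <- random_protein(60)
    s <- mutate_seq(q, 0.4)
    a <- full_smith_waterman(q, s)
    eq <- seedhit:::encode_residues(q)
    es <- seedhit:::encode_residues(s)
    # score recomputable from the transcript + matrix + gap model
    ops <- strsplit(a$transcript, "")[[1]]
    qi <- a$qstart; si <- a$sstart; sc <- 0; prev <- ""
    for (op in ops) {
      if (op == "M") { sc <- sc + mat[eq[qi + 1] + 1, es[si + 1] + 1]
        qi <- qi + 1; si <- si + 1 }
      else if (op == "I") { sc <- sc - ifelse(prev == "I", 1, 12); qi <- qi + 1 }
      else { sc <- sc - ifelse(prev == "D", 1, 12); si <- si + 1 }
      prev <- op
    }
    expect_equal(sc, a$score)
    expect_equal(qi, a$qend + 1)
    expect_equal(si, a$send + 1)
  }
})

test_that("banded alignment is exact within its band", {
  set.seed(305)
  for (rep in 1:20) {
    q <- random_protein(50)
    s <- mutate_seq(q, 0.3)
    full <- full_smith_waterman(q, s)
    # full-width band reproduces the unrestricted score
    wide <- banded_smith_waterman(q, s, list(d_min = -50, d_max = 50))
    expect_equal(wide$score, full$score)
    # a band containing the optimal path reproduces the optimal score
    dpath <- range(full$sstart - full$qstart, full$send - full$qend)
    tight <- banded_smith_waterman(q, s, list(d_min = dpath[1] - 1,
                                              d_max = dpath[2] + 1))
    expect_equal(tight$score, full$score)
  }
  expect_equal(banded_smith_waterman("MKV", "MKV",
                                     list(d_min = 0, d_max = 0))$score, 14)
  expect_error(banded_smith_waterman("MKV", "MKV",
                                     list(d_min = 10, d_max = 12)),
               "band excludes")
})

test_that("banded score over the chain band dominates single segments", {
  set.seed(306)
  mat <- score_matrix()
  fx <- generate_families(seed = 306, n_folds = 2, decoy_count = 0)
  cfg <- search_config(preset = "sensitive", masking = "none")
  segs <- seedhit:::collect_segments(fx$queries, fx$db,
                                     load_shape_set("sensitive"), cfg, mat,
                                     fx$db$letters_total)
  pairs <- unique(segs[, c("q", "s")])
  for (i in seq_len(min(25, nrow(pairs)))) {
    st <- segs[segs$q == pairs$q[i] & segs$s == pairs$s[i], ]
    eq <- fx$queries$enc[[pairs$q[i]]]
    es <- fx$db$enc[[pairs$s[i]]]
    ch <- chain_segments(st, eq, es, mat)
    sc <- banded_smith_waterman(eq, es, ch$band, mat)$score
    expect_gte(sc, max(st$score))
  }
})

test_that("frameshift alignment recovers coding reads and charges shifts", {
  set.seed(307)
  prot <- random_protein(30)
  mat <- score_matrix()
  ep <- seedhit:::encode_residues(prot)
  self_score <- sum(mat[cbind(ep + 1, ep + 1)])
  # back-translate with a fixed codon choice
  codons <- vapply(strsplit(prot, "")[[1]], function(a) {
    hits <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a]
    hits[1]
  }, "")
  cds <- paste(codons, collapse = "")
  a <- frameshift_align(cds, prot, F = 15)
  expect_equal(a$score, self_score)
  expect_equal(a$n_frameshifts, 0L)
  expect_equal(a$strand, 1L)

  # one inserted nucleotide at a codon boundary costs exactly F
  ins <- paste0(substr(cds, 1, 45), "G", substr(cds, 46, nchar(cds)))
  a2 <- frameshift_align(ins, prot, F = 15)
  expect_equal(a2$score, self_score - 15)
  expect_equal(a2$n_frameshifts, 1L)

  # F = Inf collapses to the best single-frame local alignment
  a3 <- frameshift_align(ins, prot, F = Inf)
  frames <- translate_frames(ins)
  best <- max(vapply(frames, function(f)
    if (nchar(f$residues) == 0) 0L
    else full_smith_waterman(f$residues, prot)$score, integer(1)))
  expect_equal(a3$score, best)
  expect_equal(a3$n_frameshifts, 0L)

  # reverse-complement reads are found on the minus strand
  a4 <- frameshift_align(seedhit:::revcomp(cds), prot, F = 15)
  expect_equal(a4$score, self_score)
  expect_equal(a4$strand, -1L)

  expect_error(frameshift_align(cds, prot, F = 0), "positive")
  expect_error(frameshift_align("AT", prot, F = 15), "codon")
})

test_that("adaptive extension stops after the first silent chunk", {
  ranking <- data.frame(target = 1:5, best_score = 5:1)
  sig <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  seen <- integer(0)
  res <- adaptive_extend(ranking, chunk_size = 2,
                         extend_fun = function(t) {
                           seen <<- c(seen, t)
                           list(target = t, significant = sig[t])
                         },
                         significant_fun = function(r) r$significant)
  expect_equal(seen, 1:4)   # fifth target never extended
  expect_length(res, 4)     # all alignments from processed chunks retained
  expect_equal(sum(vapply(res, `[[`, TRUE, "significant")), 2L)

  # chunk >= #targets: single chunk, exhaustive
  seen <- integer(0)
  res2 <- adaptive_extend(ranking, chunk_size = 10,
                          extend_fun = function(t) { seen <<- c(seen, t); t },
                          significant_fun = function(r) FALSE)
  expect_equal(seen, 1:5)

  # all insignificant: exactly one chunk processed
  seen <- integer(0)
  adaptive_extend(ranking, chunk_size = 2,
                  extend_fun = function(t) { seen <<- c(seen, t); t },
                  significant_fun = function(r) FALSE)
  expect_equal(seen, 1:2)
})
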