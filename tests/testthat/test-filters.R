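test_that("hamming_filter counts identities and scales clipped cutoffs", {
  w <- random_protein(48)
  r <- hamming_filter(w, w, cutoff = 11)
  expect_equal(r$identities, 48L)
  expect_true(r$pass)

  ch <- strsplit(w, "")[[1]]
  for (i in c(2, 9, 17, 30, 44)) ch[i] <- setdiff(AA20, ch[i])[1]
  r2 <- hamming_filter(w, paste(ch, collapse = ""), cutoff = 11)
  expect_equal(r2$identities, 43L)

  # all-different windows fail any positive cutoff
  a <- paste(rep("A", 48), collapse = "")
  b <- paste(rep("W", 48), collapse = "")
  expect_false(hamming_filter(a, b, cutoff = 1)$pass)

  # cutoff 0 passes everything; cutoff 49 passes nothing (unclipped)
  expect_true(hamming_filter(a, b, cutoff = 0)$pass)
  expect_false(hamming_filter(w, w, cutoff = 49)$pass)

  # clipped windows scale the cutoff proportionally (round down)
  half <- substr(w, 1, 24)
  expect_true(hamming_filter(half, half, cutoff = 48)$pass)  # needs 24
  expect_error(hamming_filter(w, half, cutoff = 10), "unequal")
})

test_that("ungapped_extend grows along the diagonal and trims to the max", {
  seg <- ungapped_extend("MKV", "MKV", 0, 0, 3)
  expect_equal(seg$length, 3L)
  expect_equal(seg$score, 14L)   # 5 + 5 + 4

  # a perfect 20-mer flanked by mismatch noise is recovered in full
  set.seed(42)
  core <- random_protein(20)
  q <- paste0("WWWWW", core, "WWWWW")
  s <- paste0("PPPPP", core, "PPPPP")
  seg2 <- ungapped_extend(q, s, 10, 10, 5)  # seed inside the core
  expect_equal(seg2$qstart, 5L)
  expect_equal(seg2$length, 20L)

  # symmetric in query/subject
  seg3 <- ungapped_extend(s, q, 10, 10, 5)
  expect_equal(seg3$score, seg2$score)
  expect_equal(seg3$length, seg2$length)
})

test_that("ungapped extension matches an exhaustive diagonal-window scan", {
  set.seed(77)
  mat <- score_matrix()
  for (rep in 1:20) {
    q <- mutate_seq(random_protein(60), 0.4)
    s <- mutate_seq(q, 0.4)
    eq <- seedhit:::encode_residues(q)
    es <- seedhit:::encode_residues(s)
    qp <- sample(10:40, 1)
    seg <- ungapped_extend(eq, es, qp, qp, 4, mat, xdrop = 1000L)
    # oracle: best window on the diagonal containing the seed (huge x-drop)
    cols <- mat[cbind(eq + 1, es + 1)]
    best <- -Inf
    for (a in 1:(qp + 1)) for (b in (qp + 4):60)
      best <- max(best, sum(cols[a:b]))
    expect_equal(seg$score, best)
  }
})

test_that("leftmost filter keeps first discoveries and drops repeats", {
  shapes <- structure(list(parse_shape("1001"), parse_shape("11")),
                      class = "shape_set")
  L <- 4L
  all1 <- rep(TRUE, L)
  # leftmost possible offset of shape 1: nothing earlier can hit
  expect_true(leftmost_filter(all1, 1, 0, shapes))
  # the current shape also hits at a strictly earlier offset
  one_shape <- structure(list(parse_shape("11")), class = "shape_set")
  expect_true(leftmost_filter(rep(TRUE, 2), 1, 0, one_shape))
  expect_false(leftmost_filter(c(TRUE, TRUE), 1, 1, one_shape))
  # a later shape on a perfect window: earlier shapes hit too
  expect_false(leftmost_filter(all1, 2, 2, shapes))
  # a window where only the current placement of shape 2 hits
  pat <- c(FALSE, TRUE, FALSE, TRUE)  # kills shape 1 and earlier shape-2 hits
  expect_false(all(pat[shapes[[1]]$match_pos]))
  expect_true(leftmost_filter(c(FALSE, FALSE, TRUE, TRUE), 2, 2, shapes))
  expect_error(leftmost_filter(all1[-1], 1, 0, shapes), "length mismatch")
})

test_that("precomputed hit table equals the direct per-shape scan", {
  for (mode in c("fast", "very-sensitive")) {
    shapes <- load_shape_set(mode)
    tab <- build_hit_table(shapes)
    expect_false(is.null(tab))
    L <- tab$window
    set.seed(500)
    codes <- c(0, 2^L - 1, sample(0:(2^L - 1), 300))
    for (k in sample(seq_along(shapes), min(4, length(shapes)))) {
      own_off <- L - shapes[[k]]$span
      for (code in codes) {
        pattern <- as.logical(bitwAnd(code, 2^(0:(L - 1))) > 0)
        keep_direct <- leftmost_filter(pattern, k, own_off, shapes)
        keep_table <- leftmost_filter(pattern, k, own_off, shapes, tab)
        expect_identical(keep_table, keep_direct)
      }
    }
  }
})

test_that("disabling the leftmost filter leaves final alignments unchanged", {
  fx <- generate_families(seed = 31, n_folds = 2, decoy_count = 10)
  cfg <- search_config(preset = "sensitive", masking = "none")
  res_with <- run_search(fx$queries, fx$db, cfg)
  cfg2 <- search_config(preset = "sensitive", masking = "none",
                        leftmost_filter = FALSE)
  res_wo <- run_search(fx$queries, fx$db, cfg2)
  key <- function(d) d[order(d$qseqid, d$sseqid),
                       c("qseqid", "sseqid", "score", "qstart", "qend",
                         "sstart", "send")]
  expect_equal(key(res_with), key(res_wo))
})
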