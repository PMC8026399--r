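make_annotation <- function() {
  data.frame(
    seqid = c("q", paste0("m", 1:3), "sf", "other"),
    family = c("famA", "famA", "famA", "famA", "famB", "famC"),
    superfamily = c("sf1", "sf1", "sf1", "sf1", "sf1", "sf2"),
    fold = c("f1", "f1", "f1", "f1", "f1", "f2"),
    start = 1L, end = 50L)
}

test_that("AUC1 counts family hits until the first different-fold hit", {
  ann <- make_annotation()
  sizes <- c(famA = 4, famB = 1, famC = 1)
  # [T, T, F, T]: two family hits before a different-fold hit -> 2/4
  hits <- data.frame(sseqid = c("q", "m1", "other", "m2"))
  expect_equal(auc1(hits, "q", ann, sizes), 0.5)
  # all family members first -> 1.0
  expect_equal(auc1(data.frame(sseqid = c("q", "m1", "m2", "m3")),
                    "q", ann, sizes), 1.0)
  # first hit a different fold -> 0
  expect_equal(auc1(data.frame(sseqid = c("other", "q")), "q", ann, sizes), 0)
  # same-fold different-family hits neither count nor terminate
  expect_equal(auc1(data.frame(sseqid = c("q", "sf", "m1", "other", "m2")),
                    "q", ann, sizes), 0.5)
  # unannotated subjects (decoys) are false positives
  expect_equal(auc1(data.frame(sseqid = c("q", "decoy_1", "m1")),
                    "q", ann, sizes), 0.25)
  expect_error(auc1(hits, "nosuch", ann, sizes), "without annotation")
})

test_that("AUC1 averages over the domains of multidomain queries", {
  ann <- rbind(make_annotation(),
               data.frame(seqid = "q", family = "famC", superfamily = "sf2",
                          fold = "f2", start = 60L, end = 100L))
  sizes <- c(famA = 4, famB = 1, famC = 1)
  # domain famA: q,m1 = 2/4 then 'other' (fold f2) is neutral for... no:
  # for the famA domain, 'other' is a different fold -> terminates at 2/4;
  # for the famC domain, 'other' is same fold+family -> hits q then other
  hits <- data.frame(sseqid = c("q", "m1", "other", "m2"))
  a <- auc1(hits, "q", ann, sizes)
  expect_equal(a, mean(c(2 / 4, 1 / 1)))
})

test_that("ROC points are monotone with honest endpoints", {
  ann <- make_annotation()
  sizes <- c(famA = 4, famB = 1, famC = 1)
  hits <- data.frame(qseqid = "q",
                     sseqid = c("q", "m1", "other", "m2"),
                     evalue = c(1e-30, 1e-10, 1e-4, 1e-2))
  roc <- roc_curve(hits, ann, sizes, thresholds = c(1e-40, 1e-8, 1, 1e3))
  expect_equal(roc$mean_fp[1], 0)
  expect_equal(roc$mean_coverage[1], 0)
  expect_true(!is.unsorted(roc$mean_fp))
  expect_true(!is.unsorted(roc$mean_coverage))
  # loosest threshold covers the full hit list
  expect_equal(roc$mean_coverage[4], 3 / 4)
  expect_equal(roc$mean_fp[4], 1)
  expect_error(roc_curve(hits, ann, sizes, numeric(0)), "empty")
})

test_that("NW identity agrees with the independent global oracle", {
  a <- random_protein(10)
  expect_equal(nw_identity(a, a), 100)
  set.seed(91)
  for (rep in 1:10) {
    x <- random_protein(sample(8:25, 1))
    y <- paste(rev(strsplit(x, "")[[1]]), collapse = "")
    expect_equal(nw_identity(x, y), oracle_nw(x, y)$identity)
    expect_equal(nw_identity(x, y), nw_identity(y, x))
  }
  expect_error(nw_identity("", "AC"), "empty")
})

test_that("window shuffling preserves multisets and protected ranges", {
  set.seed(92)
  s <- random_protein(80)
  # fully protected -> unchanged
  expect_identical(window_shuffle(s, list(start = 1, end = 80), seed = 3), s)
  # unprotected: per-window letter multisets preserved
  sh <- window_shuffle(s, NULL, window = 40, seed = 3)
  for (w in c(1, 41)) {
    expect_identical(sort(strsplit(substr(s, w, w + 39), "")[[1]]),
                     sort(strsplit(substr(sh, w, w + 39), "")[[1]]))
  }
  # protected interior range byte-identical, flanks shuffled in place
  sh2 <- window_shuffle(s, data.frame(start = 30, end = 50), seed = 3)
  expect_identical(substr(sh2, 30, 50), substr(s, 30, 50))
  # determinism and seed sensitivity
  expect_identical(window_shuffle(s, NULL, seed = 7),
                   window_shuffle(s, NULL, seed = 7))
  expect_false(identical(window_shuffle(s, NULL, seed = 7),
                         window_shuffle(s, NULL, seed = 8)))
})

test_that("the family generator meets its counting contract", {
  fx <- generate_families(n_folds = 3, families_per_fold = 1,
                          members_per_family = 5, decoy_count = 7,
                          multidomain_fraction = 0, seed = 5)
  expect_equal(length(fx$db$ids), 3 * 5 + 7)
  expect_equal(sum(startsWith(fx$db$ids, "decoy")), 7)
  expect_true(all(fx$annotation$end <=
                    nchar(fx$db$seq[match(fx$annotation$seqid, fx$db$ids)])))
  expect_equal(unname(fx$family_sizes[paste0("fam", 1:3)]), rep(5, 3))
  # determinism
  fx2 <- generate_families(n_folds = 3, families_per_fold = 1,
                           members_per_family = 5, decoy_count = 7,
                           multidomain_fraction = 0, seed = 5)
  expect_identical(fx$db$seq, fx2$db$seq)
  expect_identical(fx$annotation, fx2$annotation)
  expect_error(generate_families(target_identity = 0.01), "infeasible")
})

test_that("realized pairwise domain identity tracks the target", {
  fx <- generate_families(n_folds = 3, families_per_fold = 1,
                          members_per_family = 5, decoy_count = 0,
                          target_identity = 0.5, multidomain_fraction = 0,
                          seed = 19)
  ann <- fx$annotation
  ids <- c()
  for (fam in unique(ann$family)) {
    rows <- ann[ann$family == fam, ]
    doms <- vapply(seq_len(nrow(rows)), function(i)
      substr(fx$db$seq[match(rows$seqid[i], fx$db$ids)],
             rows$start[i], rows$end[i]), "")
    for (a in 1:(length(doms) - 1))
      for (b in (a + 1):length(doms))
        ids <- c(ids, nw_identity(doms[a], doms[b]))
  }
  expect_gte(mean(abs(ids - 50) <= 10), 0.9)
})

test_that("shuffled decoys rarely align to each other", {
  fx <- generate_families(seed = 93, decoy_count = 20)
  dec <- which(startsWith(fx$db$ids, "decoy"))
  ddb <- make_test_db(fx$db$seq[dec], fx$db$ids[dec])
  cfg <- search_config(preset = "sensitive", evalue_cutoff = 1e-3)
  res <- run_search(ddb, ddb, cfg)
  res <- res[res$qseqid != res$sseqid, ]
  n_pairs <- length(dec) * (length(dec) - 1)
  expect_lt(nrow(res) / n_pairs, 0.01)
})
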