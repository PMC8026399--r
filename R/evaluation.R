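# Benchmark statistics and the synthetic fixture generator. Ground truth
# follows the structural-classification convention: hierarchical fold >
# superfamily > family labels per annotated domain. A false positive is a
# hit between sequences of different folds; same-fold different-family hits
# are neutral (they neither count nor terminate).

#' Per-query AUC1
#'
#' For each annotated domain of the query: the number of hits to sequences
#' of the same family, counted strictly before the first hit to a different
#' fold, divided by the number of database sequences of that family. Hits to
#' the same fold but a different family neither count nor terminate. The
#' query's value is the mean over its domains.
#'
#' @param hits Data frame of the query's hits in reported order, with column
#'   `sseqid`.
#' @param query_id Query sequence id.
#' @param annotation Annotation table: `seqid`, `family`, `superfamily`,
#'   `fold`, `start`, `end` (1-based inclusive).
#' @param family_sizes Named vector: database sequence count per family.
#' @return AUC1 in `[0, 1]`.
#' @export
auc1 <- function(hits, query_id, annotation, family_sizes) {
  qdom <- annotation[annotation$seqid == query_id, , drop = FALSE]
  if (nrow(qdom) == 0) stop("query without annotation: ", query_id)
  subj_fold <- split(annotation$fold, annotation$seqid)
  subj_fam <- split(annotation$family, annotation$seqid)
  vals <- vapply(seq_len(nrow(qdom)), function(d) {
    fam <- qdom$family[d]
    fold <- qdom$fold[d]
    size <- family_sizes[[fam]]
    if (is.null(size) || size < 1) stop("unknown family size for ", fam)
    tp <- 0L
    for (s in hits$sseqid) {
      folds <- subj_fold[[s]]
      if (is.null(folds)) break             # unannotated subject: false positive
      if (!(fold %in% folds)) break         # different fold: false positive
      if (fam %in% subj_fam[[s]]) tp <- tp + 1L
      # same fold, different family: neutral
    }
    tp / size
  }, numeric(1))
  mean(vals)
}

#' Dataset AUC1
#'
#' @param hits All hits (column `qseqid` present), ordered per query.
#' @param annotation,family_sizes See [auc1()].
#' @param query_ids Queries to evaluate (default: all annotated queries
#'   appearing in `hits`; queries with no hits score 0).
#' @return List with `per_query` (named vector) and `mean`.
#' @export
auc1_dataset <- function(hits, annotation, family_sizes, query_ids = NULL) {
  if (is.null(query_ids)) query_ids <- unique(hits$qseqid)
  per <- vapply(query_ids, function(q)
    auc1(hits[hits$qseqid == q, , drop = FALSE], q, annotation, family_sizes),
    numeric(1))
  list(per_query = stats::setNames(per, query_ids), mean = mean(per))
}

#' ROC curve over e-value thresholds
#'
#' For each threshold: the mean number per query of different-fold (false
#' positive) hits with e-value at or below the threshold, against the mean
#' family coverage (same-family hits over family size, averaged over query
#' domains). Both coordinates are non-decreasing as the threshold loosens.
#'
#' @param hits All hits with columns `qseqid`, `sseqid`, `evalue`.
#' @param annotation,family_sizes See [auc1()].
#' @param thresholds Non-empty numeric vector of e-value thresholds.
#' @param query_ids Queries to evaluate.
#' @return Data frame: `threshold`, `mean_fp`, `mean_coverage`.
#' @export
roc_curve <- function(hits, annotation, family_sizes, thresholds,
                      query_ids = NULL) {
  if (length(thresholds) == 0) stop("empty threshold list")
  if (is.null(query_ids)) query_ids <- unique(hits$qseqid)
  subj_fold <- split(annotation$fold, annotation$seqid)
  subj_fam <- split(annotation$family, annotation$seqid)
  rows <- lapply(sort(thresholds), function(t) {
    fp <- numeric(length(query_ids))
    cov <- numeric(length(query_ids))
    for (k in seq_along(query_ids)) {
      q <- query_ids[k]
      h <- hits[hits$qseqid == q & hits$evalue <= t, , drop = FALSE]
      qdom <- annotation[annotation$seqid == q, , drop = FALSE]
      is_fp <- vapply(h$sseqid, function(s) {
        folds <- subj_fold[[s]]
        is.null(folds) || !any(qdom$fold %in% folds)
      }, logical(1))
      fp[k] <- sum(is_fp)
      cov[k] <- if (nrow(qdom) == 0) 0 else mean(vapply(
        seq_len(nrow(qdom)), function(d) {
          fam <- qdom$family[d]
          sum(vapply(h$sseqid, function(s) fam %in% subj_fam[[s]],
                     logical(1))) / family_sizes[[fam]]
        }, numeric(1)))
    }
    data.frame(threshold = t, mean_fp = mean(fp), mean_coverage = mean(cov))
  })
  do.call(rbind, rows)
}

#' Global-alignment identity between two annotated ranges
#'
#' Needleman-Wunsch alignment with affine gaps; identity is the fraction of
#' identical columns over all alignment columns, as a percentage. Used to
#' bin sensitivity by sequence identity.
#'
#' @param q_range,s_range Residue strings (the annotated ranges).
#' @param matrix Scoring matrix.
#' @param gap_open,gap_extend Affine gap penalties.
#' @return Identity percentage in `[0, 100]`.
#' @export
nw_identity <- function(q_range, s_range, matrix = score_matrix(),
                        gap_open = 11L, gap_extend = 1L) {
  if (nchar(q_range) == 0 || nchar(s_range) == 0) stop("empty range")
  eq <- encode_residues(canonicalize_residues(q_range))
  es <- encode_residues(canonicalize_residues(s_range))
  a <- nw_global_cpp(eq, es, matrix, gap_open, gap_extend)
  st <- transcript_stats(a$transcript, eq, es, 0L, 0L)
  100 * st$identities / st$length
}

#' Shuffle a sequence locally in fixed windows
#'
#' Permutes letters within consecutive windows (default 40 letters) outside
#' the protected ranges; protected ranges are kept byte-identical and
#' overlapping ranges are merged. The letter multiset of every window is
#' preserved. Deterministic given the seed.
#'
#' @param seq Residue string.
#' @param protected Data frame or list of ranges with `start`, `end`
#'   (1-based inclusive); may be empty.
#' @param window Window length in letters.
#' @param seed RNG seed.
#' @return The shuffled sequence string.
#' @export
window_shuffle <- function(seq, protected = NULL, window = 40L, seed = 1L) {
  n <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  prot <- rep(FALSE, n)
  if (!is.null(protected) && length(protected) > 0) {
    pr <- as.data.frame(protected)
    if (nrow(pr) > 0)
      for (i in seq_len(nrow(pr)))
        prot[max(1, pr$start[i]):min(n, pr$end[i])] <- TRUE
  }
  free <- which(!prot)
  if (length(free) == 0) return(seq)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  # consecutive windows over the unprotected positions
  for (w0 in seq(1, length(free), by = window)) {
    idx <- free[w0:min(w0 + window - 1, length(free))]
    ch[idx] <- ch[sample(idx)]
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic protein-family benchmark
#'
#' Builds a database of protein families for homology-detection
#' benchmarking: per family an ancestral domain is drawn from the background
#' composition and independently mutated per member so that pairwise member
#' identity lands near the family's target identity (substitutions sampled
#' conditional on the scoring matrix). Domains are embedded in random
#' flanks; a fraction of members carry a second domain from a different
#' fold; decoys are window-shuffled member sequences. Fully deterministic
#' given the seed.
#'
#' @param n_folds Number of folds (each holding one superfamily).
#' @param families_per_fold Families per fold.
#' @param members_per_family Member sequences per family.
#' @param domain_length Domain length in residues.
#' @param target_identity Range (length-2 vector) or single value in
#'   `(0.05, 1]`; each family draws its target from this range.
#' @param flank_length Random flank residues on each side of a domain.
#' @param decoy_count Number of shuffled decoy sequences.
#' @param queries_per_family Members per family used as queries.
#' @param multidomain_fraction Fraction of members receiving a second domain
#'   from another fold.
#' @param rate_alpha Shape of the gamma distribution of per-site
#'   substitution rates. Real protein domains evolve with strongly
#'   heterogeneous site rates (conserved motifs next to variable loops);
#'   `rate_alpha` below 1 reproduces that heterogeneity, uniform rates are
#'   recovered as `rate_alpha = Inf`.
#' @param seed RNG seed.
#' @return List with `db` (`seed_db`), `queries` (`seed_db`), `annotation`
#'   (data frame), `family_sizes` (named vector).
#' @export
generate_families <- function(n_folds = 4L, families_per_fold = 2L,
                              members_per_family = 6L, domain_length = 120L,
                              target_identity = c(0.25, 0.40),
                              flank_length = 30L, decoy_count = 40L,
                              queries_per_family = 2L,
                              multidomain_fraction = 0.1, rate_alpha = 0.7,
                              seed = 1L) {
  if (any(target_identity < 0.05) || any(target_identity > 1))
    stop("infeasible identity target")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  mat <- score_matrix()
  bg <- AA_BACKGROUND
  letters20 <- AA_ORDER[1:20]
  # substitution proposal conditional on the original residue
  sub_prob <- exp(KA_UNGAPPED$lambda * mat[1:20, 1:20]) * rep(bg, each = 20)
  diag(sub_prob) <- 0
  sub_prob <- sweep(sub_prob, 1, rowSums(sub_prob), "/")

  rand_seq <- function(n) paste(sample(letters20, n, replace = TRUE,
                                       prob = bg), collapse = "")
  # probability that two independent substitutions of the same ancestral
  # residue coincide (inflates pairwise identity at mutated sites)
  coinc <- sum(bg * rowSums(sub_prob^2))
  # per-site mutation probabilities for one family: gamma-distributed site
  # rates, constant within blocks of geometric length (conserved motifs next
  # to variable stretches, as in real domains), scaled so that the expected
  # pairwise member identity hits the family's target
  site_mut_probs <- function(L, tgt, mean_block = 10) {
    r <- if (is.finite(rate_alpha)) {
      v <- numeric(0)
      while (length(v) < L)
        v <- c(v, rep(stats::rgamma(1, rate_alpha, rate_alpha),
                      1 + stats::rgeom(1, 1 / mean_block)))
      v[1:L]
    } else rep(1, L)
    f <- function(mu) {
      p <- pmin(1, mu * r)
      mean((1 - p)^2 + p^2 * coinc) - tgt
    }
    if (f(50) > 0) return(pmin(1, 50 * r))  # target below reachable floor
    mu <- stats::uniroot(f, c(1e-6, 50))$root
    pmin(1, mu * r)
  }
  mutate_member <- function(anc_ch, p_mut) {
    ch <- anc_ch
    mut <- stats::runif(length(ch)) < p_mut
    for (i in which(mut)) {
      a <- match(anc_ch[i], letters20)
      ch[i] <- sample(letters20, 1, prob = sub_prob[a, ])
    }
    paste(ch, collapse = "")
  }

  ids <- character(0); seqs <- character(0)
  ann <- list()
  fam_id <- 0L
  domains <- list()  # per family: member domain strings (for multidomain reuse)
  fam_meta <- list()
  for (fo in seq_len(n_folds)) {
    for (fa in seq_len(families_per_fold)) {
      fam_id <- fam_id + 1L
      tgt <- if (length(target_identity) == 2)
        stats::runif(1, target_identity[1], target_identity[2])
      else target_identity
      anc_ch <- strsplit(rand_seq(domain_length), "", fixed = TRUE)[[1]]
      p_mut <- site_mut_probs(domain_length, tgt)
      doms <- vapply(seq_len(members_per_family),
                     function(i) mutate_member(anc_ch, p_mut), character(1))
      domains[[fam_id]] <- doms
      fam_meta[[fam_id]] <- list(fold = paste0("fold", fo),
                                 superfamily = paste0("sf", fo),
                                 family = paste0("fam", fam_id))
    }
  }
  n_fam <- fam_id
  folds_of <- vapply(fam_meta, function(x) x$fold, character(1))
  for (fam_id in seq_len(n_fam)) {
    meta <- fam_meta[[fam_id]]
    for (i in seq_along(domains[[fam_id]])) {
      id <- sprintf("%s_m%02d", meta$family, i)
      fl1 <- rand_seq(flank_length)
      fl2 <- rand_seq(flank_length)
      dom <- domains[[fam_id]][i]
      s <- paste0(fl1, dom, fl2)
      rows <- data.frame(seqid = id, family = meta$family,
                         superfamily = meta$superfamily, fold = meta$fold,
                         start = flank_length + 1L,
                         end = flank_length + nchar(dom))
      if (stats::runif(1) < multidomain_fraction) {
        other <- which(folds_of != meta$fold)
        if (length(other) > 0) {
          of <- if (length(other) == 1) other else sample(other, 1)
          odom <- domains[[of]][sample(length(domains[[of]]), 1)]
          rows <- rbind(rows, data.frame(
            seqid = id, family = fam_meta[[of]]$family,
            superfamily = fam_meta[[of]]$superfamily,
            fold = fam_meta[[of]]$fold,
            start = nchar(s) + 1L, end = nchar(s) + nchar(odom)))
          s <- paste0(s, odom)
        }
      }
      ids <- c(ids, id)
      seqs <- c(seqs, s)
      ann[[length(ann) + 1L]] <- rows
    }
  }
  # decoys: window-shuffled copies of member sequences
  for (d in seq_len(decoy_count)) {
    src <- sample(length(seqs), 1)
    ids <- c(ids, sprintf("decoy_%03d", d))
    seqs <- c(seqs, window_shuffle(seqs[src], seed = seed + 1000L + d))
  }
  annotation <- do.call(rbind, ann)
  db <- new_seq_db(ids, rep("", length(ids)), seqs)
  qsel <- unlist(lapply(seq_len(n_fam), function(f) {
    members <- which(startsWith(ids, paste0(fam_meta[[f]]$family, "_m")))
    utils::head(members, queries_per_family)
  }))
  queries <- new_seq_db(ids[qsel], rep("", length(qsel)), seqs[qsel])
  fam_sizes <- vapply(split(annotation$seqid, annotation$family),
                      function(x) length(unique(x)), numeric(1))
  list(db = db, queries = queries, annotation = annotation,
       family_sizes = fam_sizes)
}

#' Write or read an annotation table
#'
#' Plain TSV with columns `seqid`, `family`, `superfamily`, `fold`,
#' `start`, `end` (1-based inclusive).
#'
#' @param annotation Data frame to write.
#' @param path File path.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(seqid = "character", family = "character",
                                   superfamily = "character",
                                   fold = "character"))
}

#' Write a `seed_db` as FASTA
#'
#' @param db A `seed_db`.
#' @param path Output FASTA path.
#' @export
write_fasta <- function(db, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0(">", db$ids,
                                    ifelse(nzchar(db$desc),
                                           paste0(" ", db$desc), "")),
                             db$seq)), con, sep = "\n")
  invisible(path)
}
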