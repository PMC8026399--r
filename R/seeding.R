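# Seed alphabet: the 20 standard residues, codes 0..19. X and masked
# positions never seed. Seed codes pack the matched letters base-20 into a
# double (weight <= 10 => codes < 20^10 < 2^53, exactly representable).

# Vectorized code computation for one sequence; returns list(code, off) with
# 0-based offsets, or NULL when no placement is valid.
seed_codes <- function(enc, shape, masked = NULL) {
  L <- length(enc)
  p <- shape$span
  if (L < p) return(NULL)
  n_off <- L - p + 1L
  code <- numeric(n_off)
  valid <- rep(TRUE, n_off)
  pw <- 20^(seq_along(shape$match_pos) - 1)
  for (k in seq_along(shape$match_pos)) {
    idx <- shape$match_pos[k]:(shape$match_pos[k] + n_off - 1L)
    v <- enc[idx]
    bad <- v >= 20L
    valid <- valid & !bad
    if (!is.null(masked)) valid <- valid & !masked[idx]
    v[bad] <- 0L
    code <- code + v * pw[k]
  }
  if (!any(valid)) return(NULL)
  list(code = code[valid], off = which(valid) - 1L)
}

#' Extract spaced seeds from one sequence
#'
#' One seed entry per pattern placement at which no matched position is
#' masked and no matched letter is `X`. Codes are computed from the matched
#' positions only, so placements differing solely at don't-care positions
#' yield the same code.
#'
#' @param enc Integer vector of 0-based residue codes (see
#'   [canonicalize_residues()]), or a residue string.
#' @param shape A shape from [load_shape_set()].
#' @param masked Optional logical vector of per-position mask flags.
#' @return A data frame with columns `code` (numeric) and `off` (0-based
#'   placement offset), sorted by offset.
#' @export
extract_seeds <- function(enc, shape, masked = NULL) {
  if (is.character(enc)) enc <- encode_residues(enc)
  sc <- seed_codes(enc, shape, masked)
  if (is.null(sc)) return(data.frame(code = numeric(0), off = integer(0)))
  data.frame(code = sc$code, off = sc$off)
}

# Seed table over a whole database: columns code, ord (sequence ordinal),
# off.
extract_seeds_db <- function(db, shape, masked = NULL) {
  n <- length(db$enc)
  codes <- vector("list", n)
  offs <- vector("list", n)
  lens <- integer(n)
  for (i in seq_len(n)) {
    sc <- seed_codes(db$enc[[i]], shape,
                     if (is.null(masked)) NULL else masked[[i]])
    if (is.null(sc)) next
    codes[[i]] <- sc$code
    offs[[i]] <- sc$off
    lens[i] <- length(sc$off)
  }
  data.frame(code = unlist(codes, use.names = FALSE),
             ord = rep(seq_len(n), lens),
             off = unlist(offs, use.names = FALSE))
}

#' Double-index hash join of seed tables
#'
#' Computes all pairs of query and reference seed entries with equal seed
#' code by recursive radix clustering: both tables are partitioned on
#' successive 8-bit digits of the seed code (most significant first) until
#' the query partition holds at most `partition_limit` entries, at which
#' point the remaining join is computed by hashing within the partition.
#' The result is independent of `partition_limit`.
#'
#' @param query_entries,ref_entries Data frames with columns `code`, `ord`,
#'   `off` (as from [extract_seeds()], plus `ord`).
#' @param partition_limit Maximum query-partition size joined by hashing.
#' @return Data frame of seed matches: `code`, `q_ord`, `q_off`, `s_ord`,
#'   `s_off`, ordered by code, then query location, then subject location.
#' @export
hash_join <- function(query_entries, ref_entries, partition_limit = 32768L) {
  if (partition_limit < 1) stop("partition_limit must be >= 1")
  empty <- data.frame(code = numeric(0), q_ord = integer(0), q_off = integer(0),
                      s_ord = integer(0), s_off = integer(0))
  if (nrow(query_entries) == 0 || nrow(ref_entries) == 0) return(empty)
  qc <- query_entries$code
  rc <- ref_entries$code
  acc_q <- list()
  acc_r <- list()
  # explicit work stack; partitions carry row-index vectors into the tables
  work <- list(list(qi = seq_along(qc), rj = seq_along(rc), level = 6L))
  while (length(work) > 0) {
    w <- work[[length(work)]]
    work[[length(work)]] <- NULL
    if (length(w$qi) == 0 || length(w$rj) == 0) next
    if (length(w$qi) <= partition_limit || w$level <= 0L) {
      pr <- join_partition(qc, rc, w$qi, w$rj)
      if (length(pr$qi) > 0) {
        acc_q[[length(acc_q) + 1L]] <- pr$qi
        acc_r[[length(acc_r) + 1L]] <- pr$rj
      }
    } else {
      scale <- 256^(w$level - 1L)
      qs <- split(w$qi, (qc[w$qi] %/% scale) %% 256)
      rs <- split(w$rj, (rc[w$rj] %/% scale) %% 256)
      for (d in intersect(names(qs), names(rs)))
        work[[length(work) + 1L]] <- list(qi = qs[[d]], rj = rs[[d]],
                                          level = w$level - 1L)
    }
  }
  if (length(acc_q) == 0) return(empty)
  qi <- unlist(acc_q, use.names = FALSE)
  rj <- unlist(acc_r, use.names = FALSE)
  out <- data.frame(code = qc[qi],
                    q_ord = query_entries$ord[qi],
                    q_off = query_entries$off[qi],
                    s_ord = ref_entries$ord[rj],
                    s_off = ref_entries$off[rj])
  ord <- order(out$code, out$q_ord, out$q_off, out$s_ord, out$s_off)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Hash join within one partition: group both sides on the query partition's
# distinct codes (match() hashes internally) and emit the cross product per
# shared code.
join_partition <- function(qc, rc, qi, rj) {
  uq <- unique(qc[qi])
  mi <- match(rc[rj], uq)
  keep <- !is.na(mi)
  if (!any(keep)) return(list(qi = integer(0), rj = integer(0)))
  rj <- rj[keep]
  mi <- mi[keep]
  # positional buckets of query rows per distinct code
  qg <- split(qi, factor(match(qc[qi], uq), levels = seq_along(uq)))
  sizes <- lengths(qg)
  list(qi = unlist(qg[mi], use.names = FALSE),
       rj = rep(rj, times = sizes[mi]))
}
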