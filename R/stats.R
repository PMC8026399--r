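# Karlin-Altschul significance statistics. Standard published constants for
# BLOSUM62: ungapped lambda = 0.3176, K = 0.134; gapped (11,1) lambda =
# 0.267, K = 0.041. No length correction is applied (documented
# simplification).

KA_UNGAPPED <- list(lambda = 0.3176, K = 0.134)
KA_GAPPED <- list(lambda = 0.267, K = 0.041)

#' Bit score and e-value of a raw alignment score
#'
#' Bit score `S' = (lambda * S - ln K) / ln 2`; e-value
#' `E = m * n * 2^(-S')` for query length `m` against `n` database letters.
#'
#' @param score Raw alignment score (non-negative).
#' @param m Query length in residues.
#' @param n Total database letters.
#' @param gapped Use the gapped constants (default) or the ungapped ones.
#' @return List with `bitscore` and `evalue`.
#' @export
evalue_bitscore <- function(score, m, n, gapped = TRUE) {
  ka <- if (gapped) KA_GAPPED else KA_UNGAPPED
  bit <- (ka$lambda * score - log(ka$K)) / log(2)
  list(bitscore = bit, evalue = m * n * 2^(-bit))
}

# Ungapped lambda for an arbitrary symmetric pair distribution: the positive
# root of sum_ab P_ab * exp(lambda * S_ab) = 1.
solve_lambda <- function(pair_prob, mat20) {
  f <- function(l) sum(pair_prob * exp(l * mat20)) - 1
  # expected score must be negative for a positive root to exist
  if (sum(pair_prob * mat20) >= 0) return(NA_real_)
  stats::uniroot(f, c(1e-3, 2), extendInt = "upX", tol = 1e-9)$root
}

#' Residue composition of a sequence
#'
#' @param x Residue string or integer code vector.
#' @return Probability vector over the 20 standard residues (X and `*` are
#'   ignored).
#' @export
residue_composition <- function(x) {
  if (is.character(x)) x <- encode_residues(x)
  x <- x[x < 20L]
  if (length(x) == 0) stop("zero-length composition")
  tab <- tabulate(x + 1L, nbins = 20L)
  stats::setNames(tab / sum(tab), AA_ORDER[1:20])
}

#' Simplified composition-based score adjustment
#'
#' Rescales the scoring matrix so that alignments between compositionally
#' biased sequences are not over-rewarded: the 20x20 block is multiplied by
#' the ratio of the statistical scale (ungapped Karlin-Altschul lambda) under
#' the observed pair composition to the scale under the matrix background
#' composition, then rounded to integers. The observed pair distribution is
#' symmetrized in the two compositions, so the adjustment is symmetric in
#' query and subject; when both compositions equal the background the matrix
#' is returned unchanged. Strongly biased (low-complexity) compositions
#' shrink the scale below 1 and thus reduce expected self-scores.
#'
#' @param matrix Scoring matrix from [score_matrix()].
#' @param q_comp,s_comp Probability vectors over the 20 standard residues.
#' @return Adjusted integer scoring matrix (same shape as the input).
#' @export
comp_adjust <- function(matrix, q_comp, s_comp) {
  if (length(q_comp) != 20 || length(s_comp) != 20)
    stop("compositions must cover the 20 standard residues")
  if (any(q_comp < 0) || any(s_comp < 0) ||
      abs(sum(q_comp) - 1) > 1e-6 || abs(sum(s_comp) - 1) > 1e-6)
    stop("compositions must be probability vectors")
  bg <- AA_BACKGROUND
  if (max(abs(q_comp - bg)) < 1e-9 && max(abs(s_comp - bg)) < 1e-9)
    return(matrix)
  mat20 <- matrix[1:20, 1:20]
  lambda_std <- solve_lambda(outer(bg, bg), mat20)
  pair <- (outer(q_comp, s_comp) + outer(s_comp, q_comp)) / 2
  # blend a strongly biased composition toward the background until the
  # expected score is negative and a scale exists
  w <- 1
  lambda_obs <- solve_lambda(pair, mat20)
  while (is.na(lambda_obs) && w > 1 / 64) {
    w <- w / 2
    pair_w <- w * pair + (1 - w) * outer(bg, bg)
    lambda_obs <- solve_lambda(pair_w, mat20)
  }
  if (is.na(lambda_obs)) lambda_obs <- lambda_std / 2  # degenerate fallback
  r <- lambda_obs / lambda_std
  adj <- matrix
  adj[1:20, 1:20] <- as.integer(round(mat20 * r))
  adj
}
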