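# The three early filter stages: Hamming window filter, x-drop ungapped
# extension, leftmost-seed redundancy filter.

#' Hamming window filter
#'
#' Counts identical letters between two equally clipped windows (nominally
#' 48 letters, centred on the seed hit) and passes the hit when the count
#' reaches the cut-off, scaled proportionally (rounded down) for windows
#' clipped at sequence ends.
#'
#' @param q_window,s_window Residue strings or integer code vectors of equal
#'   length.
#' @param cutoff Minimum identities for an unclipped 48-letter window.
#' @return List with `identities` and `pass`.
#' @export
hamming_filter <- function(q_window, s_window, cutoff) {
  if (is.character(q_window)) q_window <- encode_residues(q_window)
  if (is.character(s_window)) s_window <- encode_residues(s_window)
  if (length(q_window) != length(s_window)) stop("unequal window lengths")
  ids <- count_identities_cpp(q_window, s_window)
  eff <- floor(cutoff * length(q_window) / HAMMING_WINDOW)
  list(identities = ids, pass = ids >= eff)
}

# Window bounds for a seed hit: the window starts 24 positions left of the
# seed-pattern start and is clipped identically on both sequences.
hamming_window_bounds <- function(qpos, spos, qlen, slen) {
  left <- min(HAMMING_WINDOW / 2, qpos, spos)
  right_max <- HAMMING_WINDOW - left
  right <- min(right_max, qlen - qpos, slen - spos)
  list(qstart = qpos - left, sstart = spos - left, len = left + right)
}

#' X-drop ungapped extension at a seed hit
#'
#' Greedy two-sided extension along the hit diagonal; each side stops when
#' the running score drops more than `xdrop` below its running maximum, and
#' is trimmed back to its maximal-score point. The seed columns themselves
#' are always included, so the returned score is at least the bare seed
#' score.
#'
#' @param q,s Residue strings or integer code vectors.
#' @param qpos,spos 0-based seed start positions.
#' @param span Seed span in letters.
#' @param matrix Scoring matrix (see [score_matrix()]).
#' @param xdrop X-drop threshold in raw score units.
#' @return A diagonal segment: list with `qstart`, `sstart` (0-based),
#'   `length`, `score`, `diag`.
#' @export
ungapped_extend <- function(q, s, qpos, spos, span,
                            matrix = score_matrix(), xdrop = 20L) {
  if (is.character(q)) q <- encode_residues(q)
  if (is.character(s)) s <- encode_residues(s)
  v <- ungapped_extend_cpp(q, s, qpos, spos, span, matrix, xdrop)
  list(qstart = v[1], sstart = v[2], length = v[3], score = v[4],
       diag = v[2] - v[1])
}

#' Leftmost-seed redundancy filter
#'
#' The double index discovers the same local alignment once per shape and
#' placement; only the first discovery (earliest shape, leftmost placement)
#' is kept. Given the bit-encoded match/mismatch pattern of a window ending
#' at the current seed span, the current hit is discarded if any
#' earlier-indexed shape hits anywhere in the window, or the current shape
#' hits at a strictly earlier offset.
#'
#' @param pattern Logical vector (or 0/1 integer vector) over the window,
#'   `TRUE` = residue match, leftmost position first. Its length must equal
#'   the maximum span of the shape set.
#' @param shape_index 1-based index of the current hit's shape within
#'   `shapes`.
#' @param current_offset 0-based placement offset of the current hit within
#'   the window.
#' @param shapes A `shape_set`.
#' @param table Optional precomputed decision table from [build_hit_table()]
#'   (used by the pipeline); the direct per-shape scan is used otherwise.
#' @return `TRUE` to keep the hit, `FALSE` to discard it as redundant.
#' @export
leftmost_filter <- function(pattern, shape_index, current_offset, shapes,
                            table = NULL) {
  pattern <- as.logical(pattern)
  L <- max_span(shapes)
  if (length(pattern) != L) stop("pattern window length mismatch")
  if (!is.null(table)) {
    code <- pattern_code(pattern)
    return(!table$discard[[shape_index]][code + 1L])
  }
  for (k in seq_len(shape_index)) {
    sh <- shapes[[k]]
    offs <- 0:(L - sh$span)
    if (k == shape_index) offs <- offs[offs < current_offset]
    for (o in offs) {
      if (all(pattern[o + sh$match_pos])) return(FALSE)
    }
  }
  TRUE
}

pattern_code <- function(pattern) {
  sum(2^(which(pattern) - 1L))
}

#' Precompute the leftmost-filter decision table
#'
#' For every bit-encoded window pattern and every shape index, stores whether
#' the hit is redundant, assuming the pipeline's placement of the current
#' seed at the rightmost window offset. Only available for window lengths up
#' to 16 bits (65,536 patterns).
#'
#' @param shapes A `shape_set`.
#' @return A list with `window` (length) and `discard` (per shape index, a
#'   logical vector indexed by pattern code + 1), or `NULL` when the window
#'   exceeds 16 bits.
#' @export
build_hit_table <- function(shapes) {
  L <- max_span(shapes)
  if (L > 16) return(NULL)
  pats <- 0:(2^L - 1)
  hit_at <- function(shape, o) {
    m <- sum(2^(shape$match_pos - 1L + o))
    bitwAnd(pats, m) == m
  }
  # per shape: hits at any offset
  any_hit <- lapply(shapes, function(sh) {
    Reduce(`|`, lapply(0:(L - sh$span), function(o) hit_at(sh, o)))
  })
  discard <- vector("list", length(shapes))
  prev_any <- rep(FALSE, length(pats))
  for (k in seq_along(shapes)) {
    sh <- shapes[[k]]
    own_off <- L - sh$span  # pipeline placement: rightmost
    earlier_own <- if (own_off >= 1)
      Reduce(`|`, lapply(0:(own_off - 1), function(o) hit_at(sh, o)))
    else rep(FALSE, length(pats))
    discard[[k]] <- prev_any | earlier_own
    prev_any <- prev_any | any_hit[[k]]
  }
  list(window = L, discard = discard)
}

# Bit-encoded local hit pattern for the pipeline: the window of length L
# ending at the last letter of the current seed span; out-of-range positions
# count as mismatches.
local_hit_pattern <- function(enc_q, enc_s, qpos, spos, span, L) {
  ends_q <- qpos + span - 1L
  ends_s <- spos + span - 1L
  idx <- (L - 1L):0
  qi <- ends_q - idx
  si <- ends_s - idx
  ok <- qi >= 0L & si >= 0L
  pat <- rep(FALSE, L)
  pat[ok] <- enc_q[qi[ok] + 1L] == enc_s[si[ok] + 1L]
  pat
}
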