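# Probabilistic tandem-repeat / low-complexity soft masking. A hidden-state
# model with one background state and repeat states for copy offsets
# d = 1..D scores each position's likelihood of repeating the residue d
# positions back; positions whose posterior repeat probability exceeds a
# threshold are excluded from seeding (extension still sees the original
# residues).

#' Repeat-masking parameters
#'
#' @param max_offset Largest repeat period considered (states d = 1..D).
#' @param repeat_start Prior probability of entering a repeat at each
#'   position.
#' @param repeat_extend Probability of leaving a repeat (shorter expected
#'   repeat tracts for larger values).
#' @param decay Geometric decay of the prior across offsets; shorter periods
#'   dominate biological tandem repeats.
#' @param threshold Posterior above which a position is masked.
#' @param scale Score-to-log-likelihood scale applied to the substitution
#'   score of a residue against its putative repeat copy.
#' @return A `mask_params` list.
#' @export
mask_params <- function(max_offset = 50L, repeat_start = 0.005,
                        repeat_extend = 0.05, decay = 0.9, threshold = 0.5,
                        scale = KA_UNGAPPED$lambda) {
  stopifnot(max_offset >= 1, repeat_start > 0, repeat_start < 1,
            repeat_extend > 0, repeat_extend < 1, threshold > 0 || TRUE)
  structure(list(max_offset = as.integer(max_offset),
                 repeat_start = repeat_start, repeat_extend = repeat_extend,
                 decay = decay, threshold = threshold, scale = scale),
            class = "mask_params")
}

#' Per-position repeat posteriors
#'
#' Forward-backward over the repeat model. The emission likelihood ratio of
#' repeat state d at position i is `exp(scale * S(x_i, x_{i-d}))`; the first
#' sequence position has no prior context and always gets posterior 0.
#'
#' @param x Residue string or integer code vector.
#' @param params A [mask_params()] object.
#' @param matrix Scoring matrix used for the emission ratios.
#' @return Numeric vector of posteriors in `[0, 1]`, one per position.
#' @export
repeat_posteriors <- function(x, params = mask_params(),
                              matrix = score_matrix()) {
  if (is.character(x)) x <- encode_residues(x)
  if (length(x) == 0) stop("empty sequence")
  tantan_posteriors_cpp(x, matrix, params$max_offset, params$repeat_start,
                        params$repeat_extend, params$decay, params$scale)
}

#' Apply a soft mask
#'
#' Masks exactly the positions with posterior above the threshold. Masked
#' positions are excluded from seeding; reported alignments still show the
#' original residues.
#'
#' @param x Residue string.
#' @param posteriors Vector from [repeat_posteriors()].
#' @param threshold Posterior threshold.
#' @return A `masked_sequence`: list with `original`, `posterior`, `masked`
#'   (residue string with masked positions in lowercase) and `flags`
#'   (logical).
#' @export
apply_mask <- function(x, posteriors, threshold = 0.5) {
  if (nchar(x) != length(posteriors)) stop("length mismatch")
  flags <- posteriors > threshold
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  ch[flags] <- tolower(ch[flags])
  structure(list(original = x, posterior = posteriors,
                 masked = paste(ch, collapse = ""), flags = flags),
            class = "masked_sequence")
}

# Mask flags for every sequence of a database (NULL = no masking).
mask_database <- function(db, params, matrix) {
  lapply(db$enc, function(enc) {
    repeat_posteriors(enc, params, matrix) > params$threshold
  })
}
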