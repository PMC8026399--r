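PRESET_TABLE <- data.frame(
  mode = c("fast", "sensitive", "very-sensitive", "ultra-sensitive"),
  shape_count = c(2L, 16L, 14L, 64L),
  shape_weight = c(10L, 8L, 7L, 7L),
  hamming_cutoff = c(14L, 13L, 12L, 11L),
  stringsAsFactors = FALSE
)

#' Hamming filter window length in letters
#' @export
HAMMING_WINDOW <- 48L

#' Default adaptive-ranking chunk size (targets per extension round)
#' @export
EXT_CHUNK_SIZE_DEFAULT <- 400L

# Nominal packed size of one seed index entry (~5-byte seed code plus 4-byte
# location), used for index-size accounting.
SEED_ENTRY_BYTES <- 9

#' Sensitivity preset
#'
#' Bundles the per-mode seeding and filter parameters. The four modes use
#' 2 shapes of weight 10 (fast), 16 of weight 8 (sensitive), 14 of weight 7
#' (very-sensitive) and 64 of weight 7 (ultra-sensitive). The Hamming-window
#' identity cut-offs and the stage e-value cut-offs are tunable defaults.
#'
#' @param mode One of `"fast"`, `"sensitive"`, `"very-sensitive"`,
#'   `"ultra-sensitive"`.
#' @param hamming_cutoff Minimum identities within the 48-letter window
#'   (scaled down proportionally for windows clipped at sequence ends).
#' @param ungapped_evalue E-value cut-off applied to ungapped extensions.
#' @param gapped_filter_evalue E-value cut-off of the gapped-score heuristic
#'   filter; `0` disables the filter.
#' @param ext_chunk_size Number of ranked targets extended per adaptive
#'   round.
#' @return A `sensitivity_preset` list.
#' @export
sensitivity_preset <- function(mode = c("fast", "sensitive", "very-sensitive",
                                        "ultra-sensitive"),
                               hamming_cutoff = NULL,
                               ungapped_evalue = 1e4,
                               gapped_filter_evalue = 1e3,
                               ext_chunk_size = EXT_CHUNK_SIZE_DEFAULT) {
  mode <- match.arg(mode)
  row <- PRESET_TABLE[PRESET_TABLE$mode == mode, ]
  if (is.null(hamming_cutoff)) hamming_cutoff <- row$hamming_cutoff
  stopifnot(ext_chunk_size >= 1)
  structure(list(mode = mode, shape_count = row$shape_count,
                 shape_weight = row$shape_weight,
                 hamming_cutoff = as.integer(hamming_cutoff),
                 ungapped_evalue = ungapped_evalue,
                 gapped_filter_evalue = gapped_filter_evalue,
                 ext_chunk_size = as.integer(ext_chunk_size)),
            class = "sensitivity_preset")
}

#' Search configuration
#'
#' @param preset A [sensitivity_preset()], or a mode name.
#' @param max_target_seqs Maximum reported targets per query.
#' @param evalue_cutoff Reporting e-value threshold.
#' @param frameshift_penalty `NULL` for protein search; a positive integer
#'   enables frameshift-aware translated alignment (blastx mode).
#' @param masking `"tantan"` (default) or `"none"`.
#' @param comp_based_stats `0` (off) or `1` (simplified composition
#'   adjustment).
#' @param ext_mode `"banded"` (chaining-guided band) or `"full"` (full-matrix
#'   extension).
#' @param gap_open,gap_extend Affine gap penalties (a gap of length k costs
#'   `gap_open + k * gap_extend`).
#' @param matrix Scoring matrix name.
#' @param xdrop Ungapped-extension x-drop in raw score units.
#' @param band_pad Diagonals added on each side of the chain-derived band.
#' @param rng_seed Seed for any stochastic tie-breaking (none by default;
#'   retained for reproducibility bookkeeping).
#' @param mask_params Parameters for the repeat masker, see [mask_params()].
#' @param partition_limit Radix-partition size bound of the seed hash join.
#' @param leftmost_filter Apply the leftmost-seed redundancy filter (a pure
#'   efficiency device: disabling it never changes the final alignments).
#' @return A `search_config` list.
#' @export
search_config <- function(preset = "fast", max_target_seqs = 25L,
                          evalue_cutoff = 1e-3, frameshift_penalty = NULL,
                          masking = c("tantan", "none"),
                          comp_based_stats = 0L,
                          ext_mode = c("banded", "full"),
                          gap_open = 11L, gap_extend = 1L,
                          matrix = "BLOSUM62", xdrop = 20L, band_pad = 16L,
                          rng_seed = 1L, mask_params = NULL,
                          partition_limit = 32768L, leftmost_filter = TRUE) {
  if (is.character(preset)) preset <- sensitivity_preset(preset)
  masking <- match.arg(masking)
  ext_mode <- match.arg(ext_mode)
  stopifnot(evalue_cutoff > 0)
  if (!is.null(frameshift_penalty) && frameshift_penalty <= 0)
    stop("frameshift penalty must be positive")
  if (is.null(mask_params)) mask_params <- mask_params()
  structure(list(preset = preset, max_target_seqs = as.integer(max_target_seqs),
                 evalue_cutoff = evalue_cutoff,
                 frameshift_penalty = frameshift_penalty,
                 masking = masking, comp_based_stats = as.integer(comp_based_stats),
                 ext_mode = ext_mode, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend), matrix = matrix,
                 xdrop = as.integer(xdrop), band_pad = as.integer(band_pad),
                 rng_seed = as.integer(rng_seed), mask_params = mask_params,
                 partition_limit = as.integer(partition_limit),
                 leftmost_filter = isTRUE(leftmost_filter)),
            class = "search_config")
}

#' Seed-index size accounting
#'
#' Size in bytes of the full multi-shape seed index for a database of
#' `letters` residues: one entry of ~9 packed bytes per letter and shape.
#'
#' @param letters Total database letters.
#' @param shape_count Number of spaced-seed shapes.
#' @return Estimated index size in bytes.
#' @export
index_size_bytes <- function(letters, shape_count) {
  letters * SEED_ENTRY_BYTES * shape_count
}
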