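#' @useDynLib seedhit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats uniroot runif setNames
#' @importFrom utils head read.table write.table
NULL

# Canonical residue order. The 20 standard amino acids take codes 0..19 and
# form the seed alphabet; X (ambiguous) and * (stop) are alignable but never
# seeded.
AA_ORDER <- c("A","C","D","E","F","G","H","I","K","L",
              "M","N","P","Q","R","S","T","V","W","Y","X","*")
AA_X <- 20L   # 0-based code of X
AA_STOP <- 21L

# Robinson-Robinson style background frequencies (order as AA_ORDER[1:20]).
AA_BACKGROUND <- c(
  A = 0.07805, C = 0.01925, D = 0.05364, E = 0.06295, F = 0.03856,
  G = 0.07377, H = 0.02199, I = 0.05142, K = 0.05744, L = 0.09019,
  M = 0.02243, N = 0.04487, P = 0.05203, Q = 0.04264, R = 0.05129,
  S = 0.07120, T = 0.05841, V = 0.06441, W = 0.01330, Y = 0.03216)

.pkg_cache <- new.env(parent = emptyenv())

#' Amino acid scoring matrix
#'
#' Returns the substitution matrix in the package's canonical residue order
#' (20 standard residues, then `X`, then `*`). Scores come from the standard
#' BLOSUM62 distribution; the stop character scores -4 against everything,
#' including itself, so that in-frame stops in translated queries are always
#' penalized.
#'
#' @param name Matrix name; only `"BLOSUM62"` is shipped.
#' @return An integer matrix with dimnames over the 22-letter alphabet.
#' @export
score_matrix <- function(name = "BLOSUM62") {
  if (!identical(toupper(name), "BLOSUM62"))
    stop("unknown scoring matrix: ", name)
  key <- "blosum62"
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  full <- env$BLOSUM62
  m <- full[AA_ORDER, AA_ORDER]
  m["*", ] <- -4L
  m[, "*"] <- -4L
  storage.mode(m) <- "integer"
  .pkg_cache[[key]] <- m
  m
}

# Encode a residue string to 0-based integer codes (canonicalized input).
encode_residues <- function(x) {
  codes <- match(strsplit(x, "", fixed = TRUE)[[1]], AA_ORDER) - 1L
  if (anyNA(codes)) stop("residues outside canonical alphabet")
  codes
}

decode_residues <- function(codes) {
  paste(AA_ORDER[codes + 1L], collapse = "")
}

#' Canonicalize protein residues
#'
#' Uppercases letters and maps anything outside the 20 standard amino acids
#' (plus `*`) to `X`.
#'
#' @param x Character vector of residue strings.
#' @return Character vector of canonical residue strings.
#' @export
canonicalize_residues <- function(x) {
  x <- toupper(x)
  x <- chartr(" ", "X", x)  # defensive; spaces should not occur
  vapply(x, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch[!(ch %in% AA_ORDER)] <- "X"
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Standard genetic code as a 0-based lookup: index 16*n1 + 4*n2 + n3 over
# A,C,G,T -> residue code. Built from Biostrings' GENETIC_CODE.
codon_table <- function() {
  key <- "codon_table"
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  nts <- c("A", "C", "G", "T")
  tab <- integer(64)
  gc <- Biostrings::GENETIC_CODE
  for (a in 0:3) for (b in 0:3) for (c in 0:3) {
    codon <- paste0(nts[a + 1], nts[b + 1], nts[c + 1])
    aa <- gc[[codon]]
    tab[16 * a + 4 * b + c + 1] <- match(aa, AA_ORDER) - 1L
  }
  .pkg_cache[[key]] <- tab
  tab
}

encode_nucleotides <- function(x) {
  codes <- match(strsplit(toupper(x), "", fixed = TRUE)[[1]],
                 c("A", "C", "G", "T"))
  codes[is.na(codes)] <- 5L  # ambiguous
  codes - 1L
}

revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "",
                     fixed = TRUE)[[1]]), collapse = "")
}
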