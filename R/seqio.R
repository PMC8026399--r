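#' Read a protein FASTA file into a sequence database
#'
#' Parses a (optionally gzip-compressed) FASTA file into an in-memory
#' sequence database. Residues are canonicalized: lowercase is uppercased and
#' letters outside the 20 standard amino acids (plus `*`) become `X`.
#'
#' @param path Path to a FASTA file.
#' @param type `"protein"` (default) or `"dna"` (for translated search
#'   queries; letters outside `A,C,G,T` become `N`).
#' @return A `seed_db` object: fields `ids`, `desc`, `seq` (canonical
#'   residues), `enc` (0-based integer codes per sequence), `letters_total`,
#'   and `index_by_id`.
#' @export
read_fasta <- function(path, type = c("protein", "dna")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  check_fasta_format(path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no sequences in ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicate sequence id: ", dup)
  }
  seqs <- as.character(set)
  seqs <- if (type == "protein") canonicalize_residues(seqs)
          else gsub("[^ACGT]", "N", toupper(seqs))
  if (any(nchar(seqs) == 0)) {
    bad <- ids[nchar(seqs) == 0][1]
    stop("empty sequence record: ", bad)
  }
  new_seq_db(ids, desc, seqs, type = type)
}

# Reject files whose first non-empty line is not a header, with its line
# number; Biostrings would accept some malformed layouts silently.
check_fasta_format <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lineno <- 0L
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0) stop("no sequences in ", path)
    lineno <- lineno + 1L
    if (nzchar(trimws(ln))) {
      if (!startsWith(ln, ">"))
        stop("malformed FASTA record at line ", lineno, " of ", path)
      return(invisible(TRUE))
    }
  }
}

new_seq_db <- function(ids, desc, seqs, type = "protein") {
  enc <- if (type == "protein") lapply(seqs, encode_residues)
         else lapply(seqs, encode_nucleotides)
  db <- list(ids = ids, desc = desc, seq = seqs, enc = enc,
             letters_total = sum(nchar(seqs)),
             index_by_id = stats::setNames(seq_along(ids), ids),
             type = type)
  class(db) <- "seed_db"
  db
}

#' @export
print.seed_db <- function(x, ...) {
  cat("seed_db:", length(x$ids), "sequences,", x$letters_total, "letters\n")
  invisible(x)
}

#' @export
length.seed_db <- function(x) length(x$ids)

#' Build a disk-based sequence database
#'
#' Writes a self-contained, plain-text database file holding only the
#' canonicalized reference sequences plus a small header (format version,
#' sequence count, total letters). Rebuilding from the same input is
#' byte-identical, and [load_database()] round-trips exactly.
#'
#' @param fasta Path to the input FASTA file.
#' @param out Path of the database file to create.
#' @return Invisibly, a list with `sequences` and `letters_total`.
#' @export
make_database <- function(fasta, out) {
  db <- read_fasta(fasta)
  con <- file(out, "wb")
  on.exit(close(con))
  hdr <- c("#seedhitdb 1",
           paste("#sequences", length(db$ids)),
           paste("#letters", db$letters_total))
  body <- as.vector(rbind(paste0(">", db$ids,
                                 ifelse(nzchar(db$desc), paste0(" ", db$desc), "")),
                          db$seq))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(list(sequences = length(db$ids), letters_total = db$letters_total))
}

#' Load a database written by [make_database()]
#'
#' @param path Database file path.
#' @return A `seed_db` object identical to `read_fasta()` on the original
#'   input.
#' @export
load_database <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || !startsWith(lines[1], "#seedhitdb"))
    stop("not a seedhit database: ", path)
  n <- as.integer(sub("#sequences ", "", lines[2]))
  body <- lines[-(1:3)]
  hdr_i <- seq(1, 2 * n - 1, by = 2)
  headers <- sub("^>", "", body[hdr_i])
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  desc[!grepl("\\s", headers)] <- ""
  new_seq_db(ids, desc, body[hdr_i + 1])
}

#' Six-frame translation of a nucleotide sequence
#'
#' Translates all three reading frames of both strands under the standard
#' genetic code. Stops are emitted as `*`; codons containing ambiguous
#' nucleotides become `X`; trailing incomplete codons are dropped.
#'
#' @param dna Nucleotide string over `A,C,G,T,N` (case-insensitive).
#' @return A list of six elements named `"1","2","3","-1","-2","-3"`, each
#'   with `residues` and `nt_offset`, a vector mapping 0-based protein
#'   position to the 0-based offset of its codon's first nucleotide on the
#'   input (forward) strand.
#' @export
translate_frames <- function(dna) {
  n <- nchar(dna)
  if (n < 3) stop("nucleotide sequence shorter than one codon")
  fwd <- encode_nucleotides(dna)
  rev <- encode_nucleotides(revcomp(dna))
  tab <- codon_table()
  one <- function(codes, off) {
    usable <- length(codes) - off
    naa <- usable %/% 3
    if (naa < 1) return(list(residues = "", nt_offset = integer(0)))
    starts <- off + 3 * (seq_len(naa) - 1)  # 0-based on this strand
    a <- codes[starts + 1]; b <- codes[starts + 2]; c <- codes[starts + 3]
    aa <- integer(naa)
    amb <- a > 3 | b > 3 | c > 3
    aa[amb] <- AA_X
    ok <- !amb
    aa[ok] <- tab[16 * a[ok] + 4 * b[ok] + c[ok] + 1]
    list(residues = decode_residues(aa), nt_offset = starts)
  }
  out <- list()
  for (f in 0:2) {
    r <- one(fwd, f)
    out[[as.character(f + 1)]] <- r
  }
  for (f in 0:2) {
    r <- one(rev, f)
    # map positions on the reverse strand back to forward-strand offsets
    r$nt_offset <- n - 1 - r$nt_offset
    out[[as.character(-(f + 1))]] <- r
  }
  out
}

#' Write alignment records as BLAST tabular (outfmt 6) output
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore. Coordinates are 1-based inclusive; identity is
#' printed to one decimal, bit scores to one decimal, e-values in scientific
#' notation with two significant digits.
#'
#' @param records Data frame of alignment records (as from [run_search()]).
#' @param out Path or connection; the default writes to stdout.
#' @export
write_tabular <- function(records, out = stdout()) {
  if (is.character(out)) {
    con <- file(out, "wb")
    on.exit(close(con))
  } else con <- out
  if (is.null(records) || nrow(records) == 0) {
    return(invisible(NULL))
  }
  lines <- sprintf("%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f",
                   records$qseqid, records$sseqid, records$pident,
                   records$length, records$mismatch, records$gapopen,
                   records$qstart, records$qend, records$sstart, records$send,
                   format_evalue(records$evalue), records$bitscore)
  writeLines(lines, con, sep = "\n")
  invisible(NULL)
}

format_evalue <- function(e) {
  out <- vapply(e, function(x) {
    if (x == 0) return("0.0")
    s <- sprintf("%.1e", x)
    # normalize exponent to two digits (platform differences)
    sub("e([+-])0*(\\d\\d+)$", "e\\1\\2", s)
  }, character(1))
  out
}
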