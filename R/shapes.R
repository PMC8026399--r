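#' Spaced-seed shape sets
#'
#' Loads the fixed, versioned spaced-seed shape set of a sensitivity mode:
#' 2 shapes of weight 10 (fast), 16 of weight 8 (sensitive), 14 of weight 7
#' (very-sensitive), 64 of weight 7 (ultra-sensitive). The patterns shipped
#' with the package were generated once by a seeded greedy minimal-overlap
#' heuristic and are frozen as plain-text data files; only their counts and
#' weights are normative.
#'
#' @param mode Sensitivity mode name.
#' @param file Optional path to a custom shape file (one `1`/`0` pattern per
#'   line), overriding the shipped set.
#' @return A `shape_set`: list of shapes, each with `pattern` (string),
#'   `match_pos` (1-based positions of match columns), `weight`, `span`.
#' @export
load_shape_set <- function(mode = c("fast", "sensitive", "very-sensitive",
                                    "ultra-sensitive"), file = NULL) {
  if (is.null(file)) {
    mode <- match.arg(mode)
    fname <- paste0("shapes_", gsub("-", "_", mode), ".txt")
    file <- system.file("extdata", fname, package = "seedhit")
    if (!nzchar(file)) stop("shape file missing for mode ", mode)
  }
  patterns <- readLines(file)
  patterns <- patterns[nzchar(patterns) & !startsWith(patterns, "#")]
  shapes <- lapply(patterns, parse_shape)
  if (anyDuplicated(patterns)) stop("duplicate shape patterns in ", file)
  structure(shapes, class = "shape_set")
}

parse_shape <- function(pattern) {
  ch <- strsplit(pattern, "", fixed = TRUE)[[1]]
  if (!all(ch %in% c("0", "1"))) stop("shape pattern must be over '0'/'1'")
  bits <- ch == "1"
  if (!bits[1] || !bits[length(bits)])
    stop("shape pattern must start and end with a match position")
  structure(list(pattern = pattern, match_pos = which(bits),
                 weight = sum(bits), span = length(bits)),
            class = "spaced_seed_shape")
}

#' @export
print.shape_set <- function(x, ...) {
  cat("shape_set:", length(x), "shapes, weight",
      paste(unique(vapply(x, `[[`, 1L, "weight")), collapse = "/"), "\n")
  for (s in x) cat(" ", s$pattern, "\n")
  invisible(x)
}

max_span <- function(shapes) max(vapply(shapes, `[[`, 1L, "span"))
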