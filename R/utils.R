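# Internal helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so that seeded package operations do not
#' disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Stable derivation of child seeds from a single run seed, so pipeline stages
# are independently rerunnable. Keeps results inside the 32-bit integer range.
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h * 131 + index) %% 2147483647)
}

str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

chars_str <- function(x) paste0(x, collapse = "")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

hamming <- function(a, b) {
  sum(str_chars(a) != str_chars(b))
}

write_tsv <- function(df, path) {
  df <- drop_list_cols(df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

drop_list_cols <- function(df) {
  df[, !vapply(df, is.list, logical(1L)), drop = FALSE]
}
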