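# Internal helpers: deterministic seed substreams and TSV plumbing shared
# across modules.

#' Derive a deterministic 32-bit seed from a base seed and labels
#'
#' Hashes a base seed together with an arbitrary set of labels (sample ids,
#' iteration indices, stage names) into a seed suitable for `set.seed()`.
#' Substreams keyed by identifiers (not positions) make every stage
#' reproducible and invariant to sample reordering.
#'
#' @param seed Integer base seed.
#' @param ... Labels (coerced to character) identifying the substream.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @keywords internal
seed_stream <- function(seed, ...) {
  parts <- c(as.character(as.integer(seed)), unlist(lapply(list(...), as.character)))
  h <- 0
  for (p in parts) {
    for (cc in utf8ToInt(p)) h <- (h * 31 + cc) %% 2147483647
    h <- (h * 31 + 7) %% 2147483647 # separator so c("ab","c") != c("a","bc")
  }
  as.integer(h)
}

#' Run an expression with a locally seeded RNG
#'
#' Seeds the RNG with `seed` (when non-NULL), evaluates `expr`, and restores
#' the caller's RNG state afterwards so library code never perturbs a user's
#' random stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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
  expr
}

#' Write a data frame as TSV with "#" comment header lines
#'
#' @param x Data frame.
#' @param path Output path.
#' @param comments Character vector written as `#`-prefixed lines before the
#'   header (units, seeds, provenance).
#' @export
write_tsv_commented <- function(x, path, comments = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_tsv_commented()]
#'
#' `#`-prefixed lines are treated as comments; fields are read as character
#' and never coerced silently (callers validate types).
#' @param path Input path.
#' @return Data frame of character columns.
#' @keywords internal
read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    colClasses = "character", check.names = FALSE,
                    quote = "", stringsAsFactors = FALSE, encoding = "UTF-8")
}

# Parse character vector as numeric with a named-cell diagnostic on failure.
parse_numeric <- function(x, what, rows = seq_along(x), col = what,
                          file = "<in-memory>") {
  suppressWarnings(v <- as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) & x != "NA")
  if (length(bad)) {
    stop(sprintf("%s: non-numeric value '%s' in column '%s', row %d",
                 file, x[bad[1]], col, rows[bad[1]]), call. = FALSE)
  }
  v[x == "NA" | is.na(x)] <- NA_real_
  v
}

# Parse character vector as non-negative integers, diagnostics name the cell.
parse_counts <- function(x, col, file = "<in-memory>") {
  v <- parse_numeric(x, col, col = col, file = file)
  bad <- which(!is.na(v) & (v < 0 | v != round(v)))
  if (length(bad)) {
    stop(sprintf("%s: count '%s' in column '%s', row %d is not a non-negative integer",
                 file, x[bad[1]], col, bad[1]), call. = FALSE)
  }
  if (anyNA(v)) {
    stop(sprintf("%s: missing count in column '%s'", file, col), call. = FALSE)
  }
  as.integer(round(v))
}
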