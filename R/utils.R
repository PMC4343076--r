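## Internal helpers shared across modules.

#' Round half away from zero
#'
#' Reporting convention for similarity values: round at `digits`
#' decimals with halves away from zero (base [round()] rounds half to
#' even, which would report 0.125 as 0.12). Internal computations are
#' always full precision; only reported values pass through this.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_to <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run `expr` under a fixed RNG seed without disturbing the caller's
# random state (generators must be pure functions of their config).
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Read a two-column tab-separated file, skipping '#' comments and blank
# lines. Returns a character matrix with `ncol` columns; rows with a
# single field are returned padded with NA (used for node-only lines).
read_tsv_pairs <- function(path, what = "file") {
  if (!file.exists(path)) {
    stop(sprintf("%s not found: '%s'", what, path), call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines, which = "right")
  keep <- nzchar(lines) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n > 2)) {
    stop(sprintf("%s: expected at most two tab-separated columns (line with %d fields)",
                 what, max(n)), call. = FALSE)
  }
  first <- vapply(fields, function(f) f[[1]], character(1))
  second <- vapply(fields, function(f) if (length(f) > 1) f[[2]] else NA_character_,
                   character(1))
  cbind(first, second, deparse.level = 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() treats a length-1 numeric x as 1:x; this always samples from
# the elements of x.
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}
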