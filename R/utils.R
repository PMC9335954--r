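#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# CURIE of the form PREFIX:digits, e.g. "HP:0000118"
is_curie <- function(x) grepl("^[A-Za-z]+:[0-9]+$", x)

# ISO 8601 UTC with seconds precision; `t` may be POSIXct or an
# already-formatted string (passed through unchanged so snapshots stay stable)
iso_utc <- function(t) {
  if (is.character(t)) return(t)
  format(as.POSIXct(t, tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Accept a file path, a single string with embedded newlines, or a character
# vector of lines; return a character vector of lines.
read_text_lines <- function(x) {
  stopifnot(is.character(x), length(x) >= 1)
  if (length(x) == 1 && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

# lowercase + collapse runs of whitespace; the single normalization contract
# shared by search and dictionary extraction
normalize_label <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}
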