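# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so package functions never perturb it.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream of child seeds from one master seed (keeps every derived
# seed well inside 32-bit integer range).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max %/% 2L, n))
}

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

write_tsv_quiet <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

# Split a semicolon-separated field ("1134;1137") into an integer or
# character vector.
split_field <- function(x, as_int = FALSE) {
  parts <- strsplit(as.character(x), ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  if (as_int) as.integer(parts) else parts
}

intensity_cols <- function(tbl, channel = c("light", "heavy")) {
  channel <- match.arg(channel)
  grep(paste0("^", channel, ":"), names(tbl), value = TRUE)
}

sample_ids_from_cols <- function(cols) sub("^(light|heavy):", "", cols)

abort_bad_arg <- function(msg) stop(msg, call. = FALSE)
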