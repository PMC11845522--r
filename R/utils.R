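# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed RNG state, restoring the caller's state afterwards.
# All stochastic stages route their seeds through this so that a single
# top-level seed reproduces every number in a run.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a bounded integer substream seed from a master seed and a label,
# so that stages draw from independent, reproducible streams.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Accept a validated rating_table or any data.frame carrying the columns a
# statistic needs (grades from other sources are the caller's business).
as_rating_df <- function(ratings, need) {
  if (!is.data.frame(ratings)) {
    stopf("`ratings` must be a rating_table or data.frame")
  }
  missing <- setdiff(need, names(ratings))
  if (length(missing)) {
    stopf("`ratings` is missing column(s): %s", paste(missing, collapse = ", "))
  }
  df <- as.data.frame(ratings)
  df$method <- toupper(as.character(df$method))
  df
}
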