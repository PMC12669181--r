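# Internal helpers shared across modules.

# Deterministic per-stage seed derived from a master seed. Keeps every stage
# independently reproducible while all randomness flows from one integer.
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage))) + 131L * as.integer(index)
  as.integer((as.double(seed) * 7919 + h) %% 2147483647) + 1L
}

# Evaluate an expression under a local RNG state so callers' streams are
# untouched; seed = NULL leaves the global stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Region columns of an activation table = everything except id/group columns.
region_columns <- function(table, id_cols = c("animal_id", "group")) {
  setdiff(names(table), id_cols)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name))
  }
  invisible(x)
}
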