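# Internal helpers: seeding, argument checks.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.  All stochastic package code funnels
# through this so that a single master seed makes results reproducible
# without clobbering the user's session RNG.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Deterministically derive a child seed from a master seed and a string
# salt (stage name, subject id, ...).  Plain polynomial string hash folded
# into [0, 2^31 - 2]; documented so stages can be rerun in isolation.
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(salt))
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(paste(salt, collapse = "/"))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

stop_dc <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "dynconn_error")))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_dc("`%s` must be a single finite number in [%s, %s]", name,
            format(lower), format(upper), class = "dynconn_value_error")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

STRATEGY_LEVELS <- c("filt_global", "filt_noglobal", "nofilt_global", "nofilt_noglobal")
ATLAS_LEVELS <- c("AAL", "TT")
REPRESENTATION_LEVELS <- c("FC", "dFC")
KERNEL_LEVELS <- c("lsvm", "lr", "rf", "lgbm")
CLASSIFIER_LEVELS <- c("lsvm", "lr", "rf", "lgbm", "nn", "svm")
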