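#' @keywords internal
"_PACKAGE"

# Deterministic per-stage substream: one user-facing seed, expanded so that
# e.g. enlarging the voxel grid never perturbs the genotype draws.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  chars <- utf8ToInt(stage)
  h <- sum(chars * seq_along(chars))
  as.integer((abs(as.double(seed)) * 48271 + h * 7919) %% 2147483629)
}

with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stage_seed(seed, stage))
  expr
}

# Smallest integer count c such that c / td_num >= s under the same
# double-precision predicate used everywhere else in the package.
# Pinning the predicate (rather than ceiling(s * td_num), whose rounding can
# drift at representable boundaries) keeps threshold semantics consistent
# between mining, support tables, and tests.
min_support_count <- function(s, td_num) {
  stopifnot(s > 0, s <= 1, td_num >= 0)
  if (td_num == 0L) return(1L)
  c0 <- as.integer(min(ceiling(s * td_num), td_num))
  while (c0 > 1L && (c0 - 1L) / td_num >= s) c0 <- c0 - 1L
  while (c0 <= td_num && c0 / td_num < s) c0 <- c0 + 1L
  max(c0, 1L)
}

# Half-up rounding for display columns (base round() is half-to-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
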