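# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All exported stochastic operations funnel through
# this so a single integer seed makes a whole pipeline reproducible.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a deterministic sub-seed from a master seed and a stream label, so
# independent stages (mutagenesis, breeding, pooling, detection) get distinct
# but reproducible streams. Kept below 2^31 - 1.
derive_seed <- function(seed, stream) {
  stopifnot(length(stream) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  (as.integer(seed) %% 1000003L) * 2011L + (h %% 65011L)
}

# Round half away from zero (so 0.305 -> 0.31), unlike base round()'s
# round-half-even. Printed census percentages follow this convention.
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == trunc(x)
}

stop_tk <- function(...) stop(..., call. = FALSE)

DNA_BASES <- c("A", "C", "G", "T")

complement_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A")[b]
}

revcomp <- function(s) {
  paste(rev(unname(complement_base(strsplit(s, "")[[1]]))), collapse = "")
}
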