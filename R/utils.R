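DNA_BASES <- c("A", "C", "G", "T")

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library code never clobbers a user's random stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
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
    set.seed(seed)
  }
  force(code)
}

# Draw `n` random DNA sequences of the given lengths (vectorised).
random_dna <- function(lengths) {
  vapply(lengths, function(l) {
    paste(sample(DNA_BASES, l, replace = TRUE), collapse = "")
  }, character(1))
}

# Round half away from zero (2.5 -> 3, -2.5 -> -3); base round() is
# round-half-even and would turn 160.5 into 160.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  invisible(TRUE)
}

assert_rate <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1]", name))
  }
  invisible(TRUE)
}

is_tag_library <- function(x) {
  is.data.frame(x) && all(c("tag", "count") %in% names(x))
}

assert_tag_library <- function(x, name = "library") {
  if (!is_tag_library(x)) {
    abort(sprintf("`%s` must be a data frame with columns `tag` and `count`", name))
  }
  if (nrow(x) > 0 && any(duplicated(x$tag))) {
    abort(sprintf("`%s` has duplicated tag rows; aggregate counts first", name))
  }
  invisible(TRUE)
}
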