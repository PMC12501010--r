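# Internal helpers shared across modules.

SUBGENOMES <- c("A", "B", "D")

TISSUES <- c("dawn", "dusk", "root", "spike", "flag_leaf", "grain")

# Tissues used for the tau tissue-specificity call (developmental stages;
# the circadian leaf samples dawn/dusk are excluded by default).
TAU_TISSUES <- c("flag_leaf", "root", "spike", "grain")

BIAS_LEVELS <- c("Balanced",
                 "A-dominant", "B-dominant", "D-dominant",
                 "A-suppressed", "B-suppressed", "D-suppressed",
                 "NotExpressed")

STABILITY_LEVELS <- c("stable-balanced", "stable-dominant",
                      "stable-suppressed", "dynamic", "not-expressed")

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x == as.integer(x)

check_fraction <- function(x, name) {
  assert_that(is.numeric(x) && length(x) == 1 && !is.na(x) &&
                x >= 0 && x <= 1,
              sprintf("`%s` must be a single value in [0, 1], got %s",
                      name, paste(format(x), collapse = ", ")))
}

# Deterministic child seeds below 2^31, derived from a user seed so that
# independent stages of a pipeline draw from decorrelated streams.
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + offs) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
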