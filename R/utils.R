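# Bases and complement tables used throughout; N and IUPAC degeneracies are
# complemented correctly so reverse-complement works on patterns too.
DNA_BASES <- c("A", "C", "G", "T")
COMP_FROM <- "ACGTNRYSWKMBDHV"
COMP_TO   <- "TGCANYRSWMKVHDB"

#' Reverse-complement a character DNA string
#'
#' Operates on plain character vectors (including IUPAC degenerate codes);
#' used internally where a full `DNAString` round-trip would be overkill.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  comp <- chartr(COMP_FROM, COMP_TO, toupper(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

complement_base <- function(b) chartr(COMP_FROM, COMP_TO, toupper(b))

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` on exit so generators do not perturb
#' each other's streams.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed per labeled generator substream: adding a generator
# must not perturb existing fixtures drawn from the same master seed.
sub_seed <- function(master, label) {
  h <- sum(utf8ToInt(label) * (seq_along(utf8ToInt(label)) %% 97 + 1))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483629)
}

# Largest-remainder apportionment of n items into named fractions.
# Guarantees sum(counts) == n; ties broken by vector order (deterministic).
apportion <- function(frac, n) {
  stopifnot(abs(sum(frac) - 1) < 1e-8, n >= 0)
  raw <- frac * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(counts), names(frac))
}

# Paper-style display rounding: round half up to integer percent.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_dna <- function(x, extra = "") {
  grepl(paste0("^[ACGTN", extra, "]*$"), toupper(x))
}
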