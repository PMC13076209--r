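# Internal helpers shared across modules.

# The 20 canonical amino acids; '-' is the gap symbol and 'X' the ambiguity
# code. Neither gap nor 'X' ever counts as a residue state downstream.
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
GAP_CHAR <- "-"
AMBIG_CHAR <- "X"

DNA_BASES <- c("T", "C", "A", "G")

# Standard genetic code (translation table 1), codons in TCAG order.
# Stored as data so an alternative table can be passed to the Ka/Ks code.
standard_genetic_code <- function() {
  aa <- strsplit(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
    ""
  )[[1]]
  codons <- paste0(
    rep(DNA_BASES, each = 16L),
    rep(rep(DNA_BASES, each = 4L), times = 4L),
    rep(DNA_BASES, times = 16L)
  )
  setNames(aa, codons)
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. Used by every simulator so that (seed, params) -> output is a
# pure function.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
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
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic per-item seed derivation, kept below 2^31 so the result is a
# valid R integer. Subsets of a benchmark regenerate identically because each
# gene only depends on (top seed, its own index).
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(index)) %% 2147483647)
}

assert_phylo <- function(tree, arg = "tree") {
  if (!inherits(tree, "phylo")) {
    abort(sprintf("`%s` must be an ape 'phylo' object.", arg))
  }
  invisible(tree)
}

# scalar %in% with NA-safety for option checks
is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
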