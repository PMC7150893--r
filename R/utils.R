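# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cryo <- function(...) stop(..., call. = FALSE)

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_cryo(msg)
  invisible(TRUE)
}

# reverse complement for plain character vectors (IUPAC ACGTN only is needed
# for the decoration grammar; anything else passes through Biostrings checks)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_dna <- function(x) {
  grepl("^[ACGTUNRYSWKMBDHVacgtunryswkmbdhv]+$", x)
}

# seeded RNG scope: runs expr with the given seed without clobbering the
# caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# stable integer sub-seed derived from a master seed, kept within 32-bit range
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1013L * as.integer(offset)) %% 2147483647L
}
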