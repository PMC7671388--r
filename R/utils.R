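# Internal helpers shared across modules.

# Nucleotide encoding: A=0, C=1, G=2, T=3 (case-insensitive); everything
# else (IUPAC ambiguity codes, gaps) maps to NA and invalidates any window
# that covers it.
.CODE_TABLE <- local({
  tab <- rep(NA_integer_, 256L)
  tab[utf8ToInt("A") + 1L] <- 0L
  tab[utf8ToInt("C") + 1L] <- 1L
  tab[utf8ToInt("G") + 1L] <- 2L
  tab[utf8ToInt("T") + 1L] <- 3L
  tab[utf8ToInt("a") + 1L] <- 0L
  tab[utf8ToInt("c") + 1L] <- 1L
  tab[utf8ToInt("g") + 1L] <- 2L
  tab[utf8ToInt("t") + 1L] <- 3L
  tab
})

.BASES <- c("A", "C", "G", "T")

# DNA string -> integer codes (0..3, NA for non-ACGT)
encode_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  .CODE_TABLE[utf8ToInt(x) + 1L]
}

decode_dna <- function(codes) {
  out <- rep("N", length(codes))
  ok <- !is.na(codes)
  out[ok] <- .BASES[codes[ok] + 1L]
  paste(out, collapse = "")
}

# reverse complement on the integer code scale (A<->T, C<->G => 3 - code)
revcomp_codes <- function(codes) rev(3L - codes)

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards. seed = NULL uses (and
# advances) the current RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
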