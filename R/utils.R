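# internal helpers shared across modules

# evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state
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
    set.seed(as.integer(seed))
  }
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# crude but reliable for our inputs: pure ACGT(N/U) means nucleotide
guess_alphabet <- function(seq) {
  ch <- unique(strsplit(toupper(paste(seq, collapse = "")), "")[[1]])
  ch <- setdiff(ch, c("-", "*", "N", "X"))
  if (length(ch) == 0 || all(ch %in% c("A", "C", "G", "T", "U"))) "dna" else "protein"
}

revcomp <- function(seq) {
  comp <- chartr("ACGTUNacgtun", "TGCANNtgcann", seq)
  vapply(strsplit(comp, ""), function(x) paste(rev(x), collapse = ""), "",
         USE.NAMES = FALSE)
}

# all k-mers of a single sequence, in order
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1), k:n)
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES[c(1, 2, 3, 4)], n, replace = TRUE,
               prob = c(p[1], p[2], p[3], p[4])), collapse = "")
}

random_protein <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

stopifnot_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single string", call. = FALSE)
}
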