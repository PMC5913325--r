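#' Scoring scheme for local and global sequence alignment
#'
#' Bundles the substitution matrix, affine gap penalties, seed length for the
#' k-mer-seeded local search, and the raw-score reporting threshold. A gap of
#' length L costs `gap_open + L * gap_ext`. Raw-score thresholds (not
#' E-values) are the reporting criterion throughout the package.
#'
#' Protein schemes use BLOSUM62 (from Biostrings) restricted to the 20
#' standard residues; `X`, `*` and other symbols outside the matrix alphabet
#' score 0 against everything. Nucleotide schemes use the familiar
#' +2/-3 match/mismatch scores with gap open 5 / extend 2; `N` scores 0.
#'
#' @param type "protein" or "dna".
#' @param matrix substitution matrix name; only used for protein schemes.
#'   Any matrix shipped with Biostrings (e.g. "BLOSUM62", "BLOSUM45",
#'   "PAM250") is accepted.
#' @param gap_open,gap_ext positive gap penalties.
#' @param seed_k exact-match seed length for the seeded search
#'   (default 4 aa / 12 nt).
#' @param band half-width, in alignment columns, of the band around the seed
#'   diagonals used during local extension.
#' @param min_score minimum raw score for a local hit to be reported.
#' @return an object of class `scoring_scheme`.
#' @examples
#' scoring_scheme("protein")
#' scoring_scheme("dna", min_score = 30)
#' @export
scoring_scheme <- function(type = c("protein", "dna"), matrix = "BLOSUM62",
                           gap_open = NULL, gap_ext = NULL, seed_k = NULL,
                           band = 16L, min_score = NULL) {
  type <- match.arg(type)
  if (type == "protein") {
    mat <- get_biostrings_matrix(matrix)
    mat <- mat[AA20, AA20]
    if (is.null(gap_open)) gap_open <- 10
    if (is.null(gap_ext)) gap_ext <- 1
    if (is.null(seed_k)) seed_k <- 4L
    if (is.null(min_score)) min_score <- 40
    alphabet <- AA20
  } else {
    mat <- matrix(-3, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
    diag(mat) <- 2
    if (is.null(gap_open)) gap_open <- 5
    if (is.null(gap_ext)) gap_ext <- 2
    if (is.null(seed_k)) seed_k <- 12L
    if (is.null(min_score)) min_score <- 40
    alphabet <- DNA_BASES
    matrix <- "DNA+2/-3"
  }
  stopifnot(gap_open > 0, gap_ext > 0, seed_k >= 2)
  structure(list(type = type, matrix_name = matrix, matrix = mat,
                 alphabet = alphabet, gap_open = gap_open, gap_ext = gap_ext,
                 seed_k = as.integer(seed_k), band = as.integer(band),
                 min_score = min_score),
            class = "scoring_scheme")
}

get_biostrings_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("scoring_scheme: %s, %s, gap %g/%g, seed_k %d, band %d, min_score %g\n",
              x$type, x$matrix_name, x$gap_open, x$gap_ext, x$seed_k,
              x$band, x$min_score))
  invisible(x)
}
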