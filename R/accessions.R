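#' Verify a recovered gene against public database records
#'
#' Desk verification of a recovered candidate uses two public records: the
#' deposited coding sequence of the recovered gene and a well-characterized
#' mammalian ortholog protein. Because this package performs no network
#' access, the records must be supplied by the user as plain FASTA files in
#' a directory (defaults to the package's `extdata/accessions`, which ships
#' empty): `cds.fasta` holding the nucleotide CDS of the candidate and
#' `ortholog.fasta` holding the ortholog protein. The function translates
#' the CDS, predicts the transmembrane segment of each protein, partitions
#' both under type-II topology, and reports the candidate protein length
#' together with the global percent similarity of the two extracellular
#' domains.
#'
#' @param dir directory containing `cds.fasta` and `ortholog.fasta`.
#' @return list with `protein_length` (aa, stop excluded) and
#'   `extracellular_similarity` (percent), or NULL (with a warning) when
#'   the records are not available.
#' @export
check_accession_targets <- function(dir = system.file("extdata", "accessions",
                                                      package = "gcrescue")) {
  cds_f <- file.path(dir, "cds.fasta")
  orth_f <- file.path(dir, "ortholog.fasta")
  if (!file.exists(cds_f) || !file.exists(orth_f)) {
    warning("accession records not found under ", dir,
            "; supply cds.fasta and ortholog.fasta to run this check")
    return(NULL)
  }
  cds <- read_fasta(cds_f)[[1]]
  orth <- read_fasta(orth_f)[[1]]
  prot <- translate_cds(cds)
  ec <- function(p) {
    dom <- suppressWarnings(partition_domains(p, predict_tm(p)))
    r <- if (!is.null(dom$extracellular)) dom$extracellular else c(0L, nchar(p))
    substring(p, r[1] + 1L, r[2])
  }
  sim <- percent_similarity(ec(prot), ec(orth))
  list(protein_length = nchar(prot),
       extracellular_similarity = sim$similarity)
}
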