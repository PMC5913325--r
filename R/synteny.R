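#' Assign orthologs between two gene tables
#'
#' All-vs-all seeded protein search between the query and reference
#' proteins; a pair is kept iff each gene is the other's best hit
#' (reciprocal best hit). Ties on raw score break by higher percent
#' identity, then lexicographic subject id. `one_way = TRUE` relaxes the
#' criterion to the literal one-directional best hit of the query against
#' the reference.
#'
#' @param query,reference [gene_table()]s with a `protein` column.
#' @param scheme protein [scoring_scheme()].
#' @param one_way keep plain best hits instead of reciprocal best hits.
#' @return data frame of pairs: `query_gene`, `reference_gene`, `score`,
#'   `identity`.
#' @export
assign_orthologs <- function(query, reference, scheme = scoring_scheme("protein"),
                             one_way = FALSE) {
  if (nrow(query) == 0 || nrow(reference) == 0)
    return(data.frame(query_gene = character(0), reference_gene = character(0),
                      score = numeric(0), identity = numeric(0),
                      stringsAsFactors = FALSE))
  stopifnot("protein" %in% names(query), "protein" %in% names(reference))
  best_hits <- function(from, to) {
    tos <- setNames(to$protein, to$id)
    hits <- lapply(seq_len(nrow(from)), function(i) {
      h <- search_hsps(from$protein[i], tos, scheme, bait_id = from$id[i])
      if (nrow(h) == 0) return(NULL)
      h <- h[order(-h$raw_score, -h$percent_identity, h$subject_id), ]
      h[1, c("query_id", "subject_id", "raw_score", "percent_identity")]
    })
    do.call(rbind, hits)
  }
  fw <- best_hits(query, reference)
  if (is.null(fw)) return(assign_orthologs(query[0, ], reference, scheme))
  if (!one_way) {
    bw <- best_hits(reference, query)
    keep <- vapply(seq_len(nrow(fw)), function(i) {
      any(bw$query_id == fw$subject_id[i] & bw$subject_id == fw$query_id[i])
    }, TRUE)
    fw <- fw[keep, , drop = FALSE]
  }
  out <- data.frame(query_gene = fw$query_id, reference_gene = fw$subject_id,
                    score = fw$raw_score, identity = fw$percent_identity,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$query_gene), , drop = FALSE]
}

#' Compare gene order and orientation of paired genes
#'
#' Ranks the paired genes by start coordinate in each table and reports a
#' Kendall-tau order concordance in [-1, 1], and the fraction of pairs
#' whose strands agree. When the raw concordance is negative, a globally
#' flipped view (reversed order, inverted strands) is also reported, since
#' a translocated segment may have been inverted as a unit.
#'
#' @param pairs data frame from [assign_orthologs()].
#' @param query,reference the two [gene_table()]s.
#' @return a `synteny_result` list: `pairs`, `shared_count`,
#'   `order_concordance` (NA for fewer than 2 pairs),
#'   `orientation_agreement`, and optionally `flip_adjusted`.
#' @export
compare_order <- function(pairs, query, reference) {
  sc <- nrow(pairs)
  if (sc == 0)
    return(structure(list(pairs = pairs, shared_count = 0L,
                          order_concordance = NA_real_,
                          orientation_agreement = NA_real_),
                     class = "synteny_result"))
  qi <- match(pairs$query_gene, query$id)
  ri <- match(pairs$reference_gene, reference$id)
  stopifnot(!anyNA(qi), !anyNA(ri))
  qrank <- rank(query$start[qi])
  rrank <- rank(reference$start[ri])
  tau <- if (sc >= 2) suppressWarnings(cor(qrank, rrank, method = "kendall"))
         else NA_real_
  agree <- mean(query$strand[qi] == reference$strand[ri])
  res <- list(pairs = pairs, shared_count = sc, order_concordance = tau,
              orientation_agreement = agree)
  if (!is.na(tau) && tau < 0)
    res$flip_adjusted <- list(order_concordance = -tau,
                              orientation_agreement = 1 - agree)
  structure(res, class = "synteny_result")
}

#' Write a synteny result as TSV (pairs) plus JSON (summary)
#' @param result a `synteny_result`.
#' @param tsv,json output paths.
#' @export
write_synteny <- function(result, tsv, json) {
  write.table(result$pairs, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result[setdiff(names(result), "pairs")], json,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(tsv)
}
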