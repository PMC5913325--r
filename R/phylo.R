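#' Progressive multiple protein alignment
#'
#' A deterministic simplified progressive aligner: sequences are sorted by
#' id, pairwise distances are computed from shared 3-mer fractions, an
#' average-linkage guide tree orders the merges, and profiles are aligned
#' with profile-profile global alignment (mean pairwise substitution score
#' per column pair, affine gaps). Degapping any output row reproduces the
#' corresponding input exactly.
#'
#' @param seqs named character vector of protein sequences.
#' @param scheme protein [scoring_scheme()].
#' @return named character vector of aligned rows (equal length, gap "-"),
#'   class `msa`.
#' @export
align_progressive <- function(seqs, scheme = scoring_scheme("protein")) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), length(seqs) >= 1)
  seqs <- seqs[order(names(seqs))]
  n <- length(seqs)
  if (n == 1) return(structure(seqs, class = "msa"))
  k <- 3L
  km <- lapply(seqs, function(s) table(seq_kmers(s, k)))
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- sum(pmin(km[[i]][names(km[[j]])], km[[j]]), na.rm = TRUE)
      denom <- max(1L, min(sum(km[[i]]), sum(km[[j]])))
      D[i, j] <- D[j, i] <- 1 - shared / denom
    }
  }
  hc <- hclust(as.dist(D), method = "average")
  profiles <- as.list(seqs) # grown into character vectors of rows
  for (i in seq_along(profiles)) names(profiles[[i]]) <- names(seqs)[i]
  merged <- vector("list", nrow(hc$merge))
  getp <- function(x) if (x < 0) profiles[[-x]] else merged[[x]]
  for (m in seq_len(nrow(hc$merge))) {
    a <- getp(hc$merge[m, 1])
    b <- getp(hc$merge[m, 2])
    merged[[m]] <- merge_profiles(a, b, scheme)
  }
  out <- merged[[nrow(hc$merge)]]
  structure(out[order(names(out))], class = "msa")
}

merge_profiles <- function(a, b, scheme) {
  path <- cpp_profile_align(unname(a), unname(b), scheme$matrix,
                            scheme$alphabet, scheme$gap_open, scheme$gap_ext)
  achr <- strsplit(a, "")
  bchr <- strsplit(b, "")
  take_a <- path != 2L
  take_b <- path != 1L
  ai <- cumsum(take_a)
  bi <- cumsum(take_b)
  build <- function(chv, take, idx) {
    col <- rep("-", length(path))
    col[take] <- chv[idx[take]]
    paste(col, collapse = "")
  }
  out <- c(vapply(achr, build, "", take = take_a, idx = ai),
           vapply(bchr, build, "", take = take_b, idx = bi))
  names(out) <- c(names(a), names(b))
  out
}

#' Discard alignment columns dominated by gaps
#'
#' A column is removed iff its gap fraction is strictly greater than
#' `max_gap_frac` ("more than 80% gaps" under the default).
#'
#' @param msa named character vector of aligned rows.
#' @param max_gap_frac retention threshold.
#' @return filtered `msa`.
#' @export
filter_gap_columns <- function(msa, max_gap_frac = 0.8) {
  m <- msa_matrix(msa)
  if (ncol(m) == 0) return(msa)
  gapfrac <- colMeans(m == "-")
  keep <- gapfrac <= max_gap_frac
  out <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  structure(setNames(out, names(msa)), class = "msa")
}

msa_matrix <- function(msa) {
  stopifnot(length(unique(nchar(msa))) == 1)
  m <- do.call(rbind, strsplit(unname(msa), ""))
  if (is.null(m)) m <- matrix(character(0), nrow = length(msa), ncol = 0)
  rownames(m) <- names(msa)
  m
}

#' Poisson-corrected pairwise distance matrix from an alignment
#'
#' For each pair, the p-distance (mismatch fraction) is computed over the
#' columns where both rows are ungapped and corrected for multiple hits as
#' d = -ln(1 - p). Saturated pairs (p >= 0.95) are capped at p = 0.95 with
#' a warning; pairs with fewer than 20 shared columns are flagged in the
#' `"low_overlap"` attribute.
#'
#' @param msa named character vector of aligned rows.
#' @return symmetric numeric matrix with a `low_overlap` logical attribute.
#' @export
distance_matrix <- function(msa) {
  m <- msa_matrix(msa)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  low <- matrix(FALSE, n, n, dimnames = dimnames(D))
  saturated <- FALSE
  for (i in seq_len(max(0, n - 1))) {
    for (j in (i + 1):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      shared <- sum(ok)
      if (shared < 20) low[i, j] <- low[j, i] <- TRUE
      p <- if (shared == 0) 0 else sum(m[i, ok] != m[j, ok]) / shared
      if (p >= 0.95) { p <- 0.95; saturated <- TRUE }
      D[i, j] <- D[j, i] <- -log(1 - p)
    }
  }
  if (saturated)
    warning("saturated pair(s): p-distance capped at 0.95 before correction")
  attr(D, "low_overlap") <- low
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining with a deterministic tie-break: among pairs
#' minimizing the Q criterion, the smallest (i, j) index pair in the
#' current label order is joined. Negative branch-length estimates are
#' clamped to zero (with a message). Returns an unrooted `ape::phylo`
#' tree.
#'
#' @param D symmetric distance matrix with row/column names.
#' @return an `ape::phylo` object.
#' @export
nj_tree <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D), !is.null(rownames(D)))
  n <- nrow(D)
  labels <- rownames(D)
  if (n == 1) stop("need at least 2 taxa")
  clamp <- FALSE
  br <- function(x) {
    if (x < 0) { clamp <<- TRUE; 0 } else x
  }
  fmt <- function(x) format(br(x), digits = 12, scientific = FALSE, trim = TRUE)
  if (n == 2) {
    tr <- ape::read.tree(text = sprintf("(%s:%s,%s:%s);", labels[1],
                                        fmt(D[1, 2] / 2), labels[2],
                                        fmt(D[1, 2] / 2)))
    if (clamp) message("negative NJ branch length(s) clamped to 0")
    return(tr)
  }
  node <- labels # newick fragments for active nodes
  Dm <- D
  while (length(node) > 3) {
    nn <- length(node)
    r <- rowSums(Dm)
    # Q(i,j) = (n-2) d(i,j) - r_i - r_j; first minimal (i,j) in scan order
    besti <- 1L; bestj <- 2L; bestq <- Inf
    for (i in seq_len(nn - 1)) {
      for (j in (i + 1):nn) {
        q <- (nn - 2) * Dm[i, j] - r[i] - r[j]
        if (q < bestq - 1e-12) { bestq <- q; besti <- i; bestj <- j }
      }
    }
    i <- besti; j <- bestj
    vi <- 0.5 * Dm[i, j] + (r[i] - r[j]) / (2 * (nn - 2))
    vj <- Dm[i, j] - vi
    newlab <- sprintf("(%s:%s,%s:%s)", node[i], fmt(vi), node[j], fmt(vj))
    dnew <- 0.5 * (Dm[i, ] + Dm[j, ] - Dm[i, j])
    keep <- setdiff(seq_len(nn), c(i, j))
    Dm2 <- matrix(0, nn - 1, nn - 1)
    Dm2[seq_along(keep), seq_along(keep)] <- Dm[keep, keep]
    Dm2[nn - 1, seq_along(keep)] <- Dm2[seq_along(keep), nn - 1] <- dnew[keep]
    Dm <- Dm2
    node <- c(node[keep], newlab)
  }
  if (length(node) == 3) {
    v1 <- 0.5 * (Dm[1, 2] + Dm[1, 3] - Dm[2, 3])
    v2 <- 0.5 * (Dm[1, 2] + Dm[2, 3] - Dm[1, 3])
    v3 <- 0.5 * (Dm[1, 3] + Dm[2, 3] - Dm[1, 2])
    txt <- sprintf("(%s:%s,%s:%s,%s:%s);", node[1], fmt(v1), node[2],
                   fmt(v2), node[3], fmt(v3))
  } else { # n == 2 handled above; defensive
    txt <- sprintf("(%s:%s,%s:%s);", node[1], fmt(Dm[1, 2] / 2), node[2],
                   fmt(Dm[1, 2] / 2))
  }
  if (clamp) message("negative NJ branch length(s) clamped to 0")
  ape::read.tree(text = txt)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds
#' the distance matrix and NJ tree per replicate, and reports, for each
#' internal edge of the full-alignment tree, the percentage of replicate
#' trees containing the same bipartition. Supports are stored as internal
#' node labels of the returned tree.
#'
#' @param msa named character vector of aligned rows.
#' @param n_reps number of bootstrap replicates.
#' @param seed integer seed; supports are reproducible given (msa, seed).
#' @return list with `tree` (node labels = integer percent supports) and
#'   `supports` (numeric vector, one per internal node).
#' @export
bootstrap_nj <- function(msa, n_reps = 1000L, seed = 1L) {
  ref <- nj_tree(suppressWarnings(distance_matrix(msa)))
  m <- msa_matrix(msa)
  nc <- ncol(m)
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(nc, nc, replace = TRUE)
      sub <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
      suppressMessages(nj_tree(suppressWarnings(
        distance_matrix(setNames(sub, rownames(m))))))
    })
  })
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  supports <- 100 * counts / n_reps
  ref$node.label <- as.character(round(supports))
  list(tree = ref, supports = supports)
}

#' Is a focal set of tips monophyletic with respect to an outgroup?
#'
#' Roots the tree on the outgroup and asks whether the focal tips form a
#' clade. A focal set of size one (or covering all non-outgroup tips) is
#' monophyletic by convention.
#'
#' @param tree an `ape::phylo` tree.
#' @param focal_ids tip labels of the putative clade.
#' @param outgroup_id tip label to root on.
#' @export
clade_test <- function(tree, focal_ids, outgroup_id) {
  stopifnot(inherits(tree, "phylo"), outgroup_id %in% tree$tip.label,
            all(focal_ids %in% tree$tip.label))
  if (length(focal_ids) <= 1) return(TRUE)
  rooted <- ape::root(tree, outgroup = outgroup_id, resolve.root = TRUE)
  ape::is.monophyletic(rooted, focal_ids)
}

#' Write an alignment as FASTA and a tree as newick
#' @param msa named character vector of aligned rows.
#' @param file output path.
#' @export
write_msa <- function(msa, file) write_fasta(unclass(msa), file)

#' @rdname write_msa
#' @param tree an `ape::phylo`.
#' @export
write_newick <- function(tree, file) {
  ape::write.tree(tree, file)
  invisible(file)
}
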