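#' Per-codon nucleotide conservation stars
#'
#' Counts how many of the three intra-codon nucleotide positions carry an
#' identical base across all codons in the column (0-3). Three stars mean
#' the codon is fully conserved.
#'
#' @param codons Character vector of lower-case triplets (>= 2).
#' @return Integer in 0..3.
#' @export
#' @examples
#' conservation_stars(c("tgg", "tgg", "tgg"))  # 3
conservation_stars <- function(codons) {
  codons <- tolower(codons)
  if (length(codons) < 2L) stop("need >= 2 codons", call. = FALSE)
  if (any(nchar(codons) != 3L)) stop("codons must be triplets",
                                     call. = FALSE)
  sum(vapply(1:3, function(k) {
    length(unique(substr(codons, k, k))) == 1L
  }, logical(1)))
}

#' Conservation star profile across window positions
#'
#' Applies [conservation_stars()] column-wise to a codon matrix.
#'
#' @param codon_matrix Matrix of codons, isoforms x positions (as returned
#'   by [cambd_codon_table()]).
#' @return Integer vector, one star count per position.
#' @export
star_profile <- function(codon_matrix) {
  apply(codon_matrix, 2L, conservation_stars)
}

#' Weighted column identity
#'
#' Weighted frequency of the modal residue in an alignment column. Gaps
#' (`"-"`) are excluded from the mode; their weight is discarded and the
#' remaining weights renormalized.
#'
#' @param column Character vector of single residues (one per row).
#' @param weights Optional non-negative weights (default equal); need not
#'   be pre-normalized.
#' @return Fraction in (0, 1].
#' @export
column_identity <- function(column, weights = NULL) {
  column <- toupper(column)
  if (is.null(weights)) weights <- rep(1, length(column))
  stopifnot(length(column) == length(weights), all(weights >= 0))
  keep <- column != "-"
  if (!any(keep)) stop("all-gap column", call. = FALSE)
  w <- weights[keep] / sum(weights[keep])
  max(tapply(w, column[keep], sum))
}

#' Henikoff position-based sequence weights
#'
#' Position-based weighting: within each column every residue type shares
#' unit weight equally among the rows that carry it (a row in a column
#' with `r` distinct symbols, its symbol carried by `s` rows, receives
#' `1/(r*s)`); a row's weight is its mean over columns, normalized to sum
#' to one. Gaps count as a symbol type.
#'
#' @param msa Character matrix (rows x aligned columns) or a character
#'   vector of equal-length aligned strings (names become row labels).
#' @return Numeric weight vector summing to 1.
#' @export
sequence_weights <- function(msa) {
  m <- as_msa_matrix(msa)
  if (nrow(m) == 0L) stop("empty alignment", call. = FALSE)
  if (nrow(m) == 1L) return(1)
  w <- rowMeans(apply(m, 2L, function(col) {
    tab <- table(col)
    1 / (length(tab) * as.numeric(tab[col]))
  }))
  w / sum(w)
}

#' Coerce an alignment to a character matrix
#'
#' @param msa Character matrix of single characters, or character vector
#'   of equal-length aligned strings.
#' @return Character matrix with one column per alignment position.
#' @export
as_msa_matrix <- function(msa) {
  if (is.matrix(msa)) return(msa)
  stopifnot(is.character(msa))
  if (length(unique(nchar(msa))) != 1L) {
    stop("aligned rows must have equal length", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(toupper(msa), ""))
  rownames(m) <- names(msa)
  m
}

#' Read an aligned FASTA into an alignment matrix
#'
#' @param path Path to an aligned multi-FASTA (gap symbol `"-"`).
#' @return Character matrix, rows named by FASTA headers.
#' @export
read_msa_fasta <- function(path) {
  aln <- Biostrings::readAAStringSet(path)
  as_msa_matrix(stats::setNames(as.character(aln), names(aln)))
}

#' Weighted mutual-information covariation matrix
#'
#' For each column pair the mutual information (log base 2) is computed
#' from weighted joint symbol frequencies and normalized by the smaller of
#' the two weighted column entropies, giving scores in 0-1; a pair where
#' either column is invariant scores 0. Rows with a gap in either column
#' of a pair are dropped from that pair's counts and the remaining weights
#' renormalized. An optional pseudocount is added to every observed joint
#' cell before normalization.
#'
#' @param msa Alignment (see [as_msa_matrix()]).
#' @param weights Optional row weights (default [sequence_weights()]);
#'   supplying externally derived weights, e.g. from a phylogeny, is
#'   supported.
#' @param pseudocount Non-negative count added per observed joint cell
#'   (default 0).
#' @param column_labels Labels for matrix rows/columns (default
#'   consensus residue + position).
#' @return Symmetric numeric matrix with `NA` diagonal, off-diagonal
#'   entries in `[0, 1]`.
#' @export
weighted_mutual_information <- function(msa, weights = NULL,
                                        pseudocount = 0,
                                        column_labels = NULL) {
  m <- as_msa_matrix(msa)
  stopifnot(pseudocount >= 0)
  n <- nrow(m); p <- ncol(m)
  if (is.null(weights)) weights <- sequence_weights(m)
  if (length(weights) != n) {
    stop("weights length must match alignment rows", call. = FALSE)
  }
  weights <- weights / sum(weights)
  if (is.null(column_labels)) {
    cons <- apply(m, 2L, function(col) {
      col <- col[col != "-"]
      if (!length(col)) "-" else names(which.max(table(col)))
    })
    column_labels <- paste0(cons, seq_len(p))
  }
  scores <- matrix(NA_real_, p, p,
                   dimnames = list(column_labels, column_labels))
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      scores[i, j] <- scores[j, i] <-
        .pair_nmi(m[, i], m[, j], weights, pseudocount)
    }
  }
  scores
}

# Normalized weighted MI for one column pair.
.pair_nmi <- function(ci, cj, w, pseudocount) {
  keep <- ci != "-" & cj != "-"
  if (sum(keep) < 2L) return(0)
  ci <- ci[keep]; cj <- cj[keep]; w <- w[keep] / sum(w[keep])
  joint <- tapply(w, list(ci, cj), sum, default = 0)
  joint[joint > 0] <- joint[joint > 0] + pseudocount
  joint <- joint / sum(joint)
  pi <- rowSums(joint); pj <- colSums(joint)
  hi <- .entropy(pi); hj <- .entropy(pj)
  hmin <- min(hi, hj)
  if (hmin == 0) return(0)
  mi <- sum(joint * log2(joint / outer(pi, pj)), na.rm = TRUE)
  max(0, min(1, mi / hmin))
}

.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Hierarchically cluster a covariation matrix
#'
#' Average-linkage agglomerative clustering on the distance
#' `d(i, j) = 1 - score(i, j)`.
#'
#' @param scores Symmetric covariation matrix (see
#'   [weighted_mutual_information()]).
#' @return An object of class `hclust` (merge heights non-decreasing).
#' @export
cluster_covariation <- function(scores) {
  if (!is.matrix(scores) || nrow(scores) != ncol(scores)) {
    stop("scores must be a square matrix", call. = FALSE)
  }
  d <- 1 - scores
  diag(d) <- 0
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Export a covariation dendrogram as Newick
#'
#' @param hc An `hclust` object from [cluster_covariation()].
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return Newick string (invisibly when written to a file).
#' @export
covariation_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Write a covariation matrix as TSV
#'
#' @param scores Covariation matrix.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_matrix_tsv <- function(scores, path) {
  utils::write.table(
    data.frame(position = rownames(scores), scores,
               check.names = FALSE, stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
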