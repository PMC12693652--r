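#' Categorize a damaging-effect predictor score
#'
#' Scores in `[0, 1]`: `< 0.2` benign, `[0.2, 0.85)` possibly damaging,
#' `>= 0.85` probably damaging (half-open intervals; 0.85 itself is
#' probably damaging).
#'
#' @param score Numeric scores in `[0, 1]` (vectorized).
#' @return Ordered factor with levels
#'   `benign < possibly_damaging < probably_damaging`.
#' @export
#' @examples
#' categorize_score(c(0.1, 0.5, 0.85))
categorize_score <- function(score) {
  if (any(!is.finite(score)) || any(score < 0 | score > 1)) {
    stop("score must lie in [0, 1]", call. = FALSE)
  }
  cut(score, breaks = c(-Inf, 0.2, 0.85, Inf), right = FALSE,
      labels = c("benign", "possibly_damaging", "probably_damaging"),
      ordered_result = TRUE)
}

#' Filter gene-disease association records
#'
#' Keeps records with `score_gda >= min_score` and `association_type` in
#' `types`, preserving input order.
#'
#' @param records Data frame with `score_gda` and `association_type`
#'   columns.
#' @param min_score Minimum association score (0.3 for general analyses;
#'   0.5 for high-confidence).
#' @param types Association types to keep (default causal-mutation and
#'   genetic-variation classes).
#' @return The filtered data frame.
#' @export
filter_gda <- function(records, min_score = 0.3,
                       types = c("CausalMutation", "GeneticVariation")) {
  stopifnot(all(c("score_gda", "association_type") %in% names(records)))
  records[records$score_gda >= min_score &
            records$association_type %in% types, , drop = FALSE]
}

#' Polygenicity class and stratum of a disease
#'
#' `n = 1` monogenic, `n = 2` oligogenic, `n >= 3` polygenic; the stratum
#' is `low` for `n <= 30` genes and `high` above (an empirical
#' visualization split).
#'
#' @param n_genes_disease Positive integer count(s) of genes linked to
#'   the disease.
#' @return Data frame with `n_genes_disease`, `class` and `stratum`.
#' @export
#' @examples
#' polygenicity_class(c(1, 2, 7, 31))
polygenicity_class <- function(n_genes_disease) {
  n <- as.integer(n_genes_disease)
  if (any(is.na(n)) || any(n < 1L)) {
    stop("n_genes_disease must be >= 1", call. = FALSE)
  }
  data.frame(
    n_genes_disease = n,
    class = ifelse(n == 1L, "monogenic",
                   ifelse(n == 2L, "oligogenic", "polygenic")),
    stratum = ifelse(n <= 30L, "low", "high"),
    stringsAsFactors = FALSE
  )
}

#' Gene x tissue high-expression presence/absence matrix
#'
#' @param flags Data frame with `gene`, `tissue` and logical `high`
#'   columns. Duplicate identical flags are deduplicated; contradictory
#'   duplicates (same gene/tissue, different `high`) are an error.
#' @return Binary integer matrix, rows = genes (input order of first
#'   appearance), columns = union of tissues in lexicographic order.
#' @export
expression_matrix <- function(flags) {
  if (!nrow(flags)) {
    return(matrix(integer(0), 0, 0))
  }
  stopifnot(all(c("gene", "tissue", "high") %in% names(flags)))
  flags <- unique(flags[, c("gene", "tissue", "high")])
  key <- paste(flags$gene, flags$tissue, sep = "\r")
  if (anyDuplicated(key)) {
    stop("contradictory expression flags for ",
         paste(unique(sub("\r", "/", key[duplicated(key)])),
               collapse = ", "), call. = FALSE)
  }
  genes <- unique(flags$gene)
  tissues <- sort(unique(flags$tissue))
  m <- matrix(0L, length(genes), length(tissues),
              dimnames = list(genes, tissues))
  hit <- flags[flags$high, , drop = FALSE]
  m[cbind(match(hit$gene, genes), match(hit$tissue, tissues))] <- 1L
  m
}

#' Join an organ-system lookup onto disease records
#'
#' Applies a user-supplied two-column mapping (`disease_id`,
#' `organ_system`) as a left join; unmapped diseases get `NA`.
#'
#' @param records Data frame with a `disease_id` column.
#' @param lookup Data frame with `disease_id` and `organ_system`.
#' @return `records` with an `organ_system` column appended.
#' @export
map_organ_system <- function(records, lookup) {
  stopifnot("disease_id" %in% names(records),
            all(c("disease_id", "organ_system") %in% names(lookup)))
  records$organ_system <-
    lookup$organ_system[match(records$disease_id, lookup$disease_id)]
  records
}
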