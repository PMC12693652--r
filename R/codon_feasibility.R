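.BASES <- c("a", "c", "g", "t")

# Translate one codon; "*" for stop.
.codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[toupper(codon)])
}

#' Enumerate single-nucleotide codon edits
#'
#' Returns the three codons obtained by substituting each alternative base
#' at one codon position, classified by the amino-acid change they
#' realize. Stop gains are labelled `nonsense` with `aa_after = "*"`.
#'
#' @param codon Lower-case triplet.
#' @param codon_position Position 1-3 to edit (default 2; the middle base
#'   is the most determinative of amino-acid identity, making
#'   second-position edits the canonical route to missense variants).
#' @return Data frame with one row per edit: `codon_before`,
#'   `codon_position`, `base_after`, `codon_after`, `aa_before`,
#'   `aa_after`, `edit_class` in `{synonymous, missense, nonsense}`.
#' @export
#' @examples
#' enumerate_edits("atc", 2)
enumerate_edits <- function(codon, codon_position = 2L) {
  codon <- tolower(codon)
  if (nchar(codon) != 3L || grepl("[^acgt]", codon)) {
    stop("codon must be a triplet over {a,c,g,t}", call. = FALSE)
  }
  codon_position <- as.integer(codon_position)
  if (!codon_position %in% 1:3) {
    stop("codon_position must be 1, 2 or 3", call. = FALSE)
  }
  ref <- substr(codon, codon_position, codon_position)
  alts <- setdiff(.BASES, ref)
  after <- vapply(alts, function(b) {
    out <- codon
    substr(out, codon_position, codon_position) <- b
    out
  }, character(1), USE.NAMES = FALSE)
  aa_before <- .codon_aa(codon)
  aa_after <- vapply(after, .codon_aa, character(1), USE.NAMES = FALSE)
  edit_class <- ifelse(aa_after == "*", "nonsense",
                       ifelse(aa_after == aa_before, "synonymous",
                              "missense"))
  data.frame(codon_before = codon, codon_position = codon_position,
             base_after = alts, codon_after = after,
             aa_before = aa_before, aa_after = aa_after,
             edit_class = edit_class, stringsAsFactors = FALSE)
}

#' Default substitution plan
#'
#' The packaged plan mapping motif positions 5, 6, 8, 14 and 18 to the
#' target codons reachable by one second-position base change in human
#' PMCA CaMBDs (realizing L5R, N6I, I8T, V14E/D and F18S).
#'
#' @return Named list: motif position (character) -> character vector of
#'   target codons.
#' @export
default_substitution_plan <- function() {
  read_substitution_plan(system.file("extdata", "substitution_plan.yaml",
                                     package = "cambdscan",
                                     mustWork = TRUE))
}

#' Read a substitution plan from YAML
#'
#' @param path YAML file mapping motif position -> list of target codons.
#' @return Named list of lower-case codon vectors.
#' @export
read_substitution_plan <- function(path) {
  plan <- yaml::read_yaml(path)
  plan <- lapply(plan, function(x) tolower(unlist(x)))
  if (any(vapply(plan, function(x) any(nchar(x) != 3L), logical(1)))) {
    stop("plan targets must be codon triplets", call. = FALSE)
  }
  plan
}

#' Realize a substitution plan across window groups
#'
#' For each window group and planned motif position, selects the plan
#' codon that differs from the group's codon by exactly one base at
#' `codon_position` (and nowhere else), translates it, and emits the
#' realized substitution class. Plan positions with no reachable target
#' for a group are reported via a warning and the `unmatched` attribute.
#'
#' @param windows List of [cambd_window()] objects carrying codons
#'   (typically the output of [delimit_cambd()] or
#'   [windows_from_codon_table()]).
#' @param plan Substitution plan, see [default_substitution_plan()].
#' @param codon_position Codon position edited by the plan (default 2).
#' @return Data frame with columns `group`, `motif_position`,
#'   `codon_before`, `codon_after`, `aa_before`, `aa_after`, `label`
#'   (e.g. `"V14E"`), `edit_class`; attribute `unmatched` lists skipped
#'   (group, position) pairs.
#' @export
realize_plan <- function(windows, plan = default_substitution_plan(),
                         codon_position = 2L) {
  stopifnot(all(vapply(windows, inherits, logical(1), "cambd_window")))
  if (any(vapply(windows, function(w) is.null(w$codons), logical(1)))) {
    stop("all windows must carry codons", call. = FALSE)
  }
  rows <- list(); unmatched <- list()
  for (w in windows) {
    grp <- window_group_label(w$member_isoforms)
    for (pos_chr in names(plan)) {
      pos <- as.integer(pos_chr)
      if (pos < 1L || pos > 18L) {
        stop("plan positions must lie in 1-18", call. = FALSE)
      }
      before <- w$codons[pos]
      hits <- Filter(function(t) .is_single_edit(before, t,
                                                 codon_position),
                     plan[[pos_chr]])
      if (!length(hits)) {
        unmatched[[length(unmatched) + 1L]] <-
          data.frame(group = grp, motif_position = pos,
                     codon_before = before, stringsAsFactors = FALSE)
        next
      }
      after <- hits[[1]]
      aa_b <- .codon_aa(before); aa_a <- .codon_aa(after)
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, motif_position = pos, codon_before = before,
        codon_after = after, aa_before = aa_b, aa_after = aa_a,
        label = if (aa_a == "*") NA_character_ else
          paste0(aa_b, pos, aa_a),
        edit_class = ifelse(aa_a == "*", "nonsense",
                            ifelse(aa_a == aa_b, "synonymous",
                                   "missense")),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(), motif_position = integer(),
               codon_before = character(), codon_after = character(),
               aa_before = character(), aa_after = character(),
               label = character(), edit_class = character(),
               stringsAsFactors = FALSE)
  un <- if (length(unmatched)) do.call(rbind, unmatched) else NULL
  if (!is.null(un)) {
    warning(sprintf("%d plan entr%s had no single-edit target",
                    nrow(un), if (nrow(un) == 1) "y" else "ies"),
            call. = FALSE)
  }
  attr(out, "unmatched") <- un
  out
}

# TRUE when target differs from codon at exactly `pos` and nowhere else.
.is_single_edit <- function(codon, target, pos) {
  a <- strsplit(codon, "")[[1]]; b <- strsplit(target, "")[[1]]
  diffs <- which(a != b)
  identical(diffs, as.integer(pos))
}

#' Distinct substitution classes
#'
#' Deduplicates realized substitutions by
#' `(motif_position, aa_before, aa_after)`, dropping synonymous and
#' nonsense edits (a stop never forms a substitution class).
#'
#' @param realized Data frame from [realize_plan()].
#' @return Data frame of distinct classes ordered by position then
#'   replacement residue, with the `label` column (e.g. `"V14E"`).
#' @export
distinct_classes <- function(realized) {
  mis <- realized[realized$edit_class == "missense", , drop = FALSE]
  key <- paste(mis$motif_position, mis$aa_before, mis$aa_after)
  out <- mis[!duplicated(key),
             c("motif_position", "aa_before", "aa_after", "label")]
  out <- out[order(out$motif_position, out$aa_after), , drop = FALSE]
  rownames(out) <- NULL
  out
}
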