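#' Default CaMBD motif library
#'
#' The scanning references used to locate the calmodulin-binding domain
#' (CaMBD) in PMCA isoforms: the 28-residue PMCA4b peptide (C28, present in
#' the NMR complex 2KNE) and the two consensus patterns that delimit the
#' N- and C-terminal halves of the 1-18 window.
#'
#' @return A list with elements `c28`, `pattern1` and `pattern2`
#'   (amino-acid strings).
#' @export
#' @examples
#' motif_library()$c28
motif_library <- function() {
  list(
    c28      = "LRRGQILWFRGLNRIQTQIKVVKAFHSS",
    pattern1 = "GQILWFRGLNRIQTQ",
    pattern2 = "IRVVNAFR"
  )
}

# Offset of the W1 anchor within C28: window position 1 is the W at C28
# position 8, so the 1-18 window spans C28 positions 8..25.
.C28_W_OFFSET <- 8L

.AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct an isoform record
#'
#' Bundles a protein sequence with optional coding sequence and metadata.
#' Nucleotides are normalized to lower case and amino acids to upper case.
#' When a CDS is supplied it must be exactly 3x the protein length (or 3x+3
#' with a trailing stop) and must translate to the protein under the
#' standard genetic code.
#'
#' @param gene_symbol Gene symbol, e.g. `"ATP2B1"`.
#' @param isoform_label Isoform label, e.g. `"PMCA1a"`.
#' @param accession Sequence accession (metadata only; never fetched).
#' @param protein_seq Amino-acid string over the 20-letter alphabet.
#' @param cds_seq Optional nucleotide string over `{a,c,g,t}`.
#' @return An object of class `isoform_record`.
#' @export
isoform_record <- function(gene_symbol, isoform_label, accession,
                           protein_seq, cds_seq = NULL) {
  protein_seq <- toupper(protein_seq)
  if (!nzchar(protein_seq)) {
    stop("protein_seq must be non-empty", call. = FALSE)
  }
  bad <- setdiff(strsplit(protein_seq, "")[[1]], .AA_ALPHABET)
  if (length(bad)) {
    stop("protein_seq contains non-standard residues: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  if (!is.null(cds_seq)) {
    cds_seq <- tolower(cds_seq)
    np <- nchar(protein_seq)
    if (!nchar(cds_seq) %in% c(3L * np, 3L * np + 3L)) {
      stop("cds_seq length must be 3x protein length, ",
           "optionally plus a trailing stop codon", call. = FALSE)
    }
    core <- substr(cds_seq, 1L, 3L * np)
    if (!identical(translate_cds(core), protein_seq)) {
      stop("cds_seq does not translate to protein_seq", call. = FALSE)
    }
  }
  structure(
    list(gene_symbol = gene_symbol, isoform_label = isoform_label,
         accession = accession, protein_seq = protein_seq,
         cds_seq = cds_seq),
    class = "isoform_record"
  )
}

#' @export
print.isoform_record <- function(x, ...) {
  cat(sprintf("<isoform_record> %s (%s, %s): %d aa%s\n",
              x$isoform_label, x$gene_symbol, x$accession,
              nchar(x$protein_seq),
              if (is.null(x$cds_seq)) "" else ", with CDS"))
  invisible(x)
}

#' Translate a coding sequence under the standard genetic code
#'
#' A trailing stop codon is accepted and dropped; an internal stop is an
#' error. Input is case-insensitive over `{a,c,g,t}`.
#'
#' @param cds Nucleotide string whose length is a multiple of 3.
#' @return Amino-acid string (upper case).
#' @export
#' @examples
#' translate_cds("tggttc")  # "WF"
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  if (!nzchar(cds)) return("")
  cds <- tolower(cds)
  if (grepl("[^acgt]", cds)) {
    stop("cds contains characters outside {a,c,g,t}", call. = FALSE)
  }
  if (nchar(cds) %% 3L != 0L) {
    stop("cds length must be a multiple of 3", call. = FALSE)
  }
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds), no.init.codon = TRUE))
  stops <- gregexpr("*", aa, fixed = TRUE)[[1]]
  if (stops[1] != -1L) {
    if (length(stops) > 1L || stops[1] != nchar(aa)) {
      stop("internal stop codon in cds", call. = FALSE)
    }
    aa <- substr(aa, 1L, nchar(aa) - 1L)
  }
  aa
}

#' Scan a protein for an ungapped motif match
#'
#' Slides the motif along the protein and scores each window by fractional
#' identity (matches / motif length). Returns the leftmost window among
#' those attaining the maximal identity, provided that identity reaches
#' `min_identity`.
#'
#' @param protein Amino-acid string.
#' @param motif Amino-acid string (non-empty).
#' @param min_identity Minimum fractional identity in (0, 1]; default 0.6,
#'   permissive enough for cross-isoform scanning with the PMCA4b C28
#'   reference.
#' @return A list with `start` (1-based) and `identity`.
#' @export
#' @examples
#' scan_for_motif("AAAWFRGAAA", "WFRG", 0.9)
scan_for_motif <- function(protein, motif, min_identity = 0.6) {
  protein <- toupper(protein); motif <- toupper(motif)
  stopifnot(nzchar(motif), min_identity > 0, min_identity <= 1)
  lp <- nchar(protein); lm <- nchar(motif)
  if (lp < lm) {
    stop("motif not found: protein shorter than motif", call. = FALSE)
  }
  pv <- strsplit(protein, "")[[1]]
  mv <- strsplit(motif, "")[[1]]
  starts <- seq_len(lp - lm + 1L)
  ident <- vapply(starts, function(s) {
    sum(pv[s:(s + lm - 1L)] == mv) / lm
  }, numeric(1))
  best <- max(ident)
  if (best < min_identity) {
    stop(sprintf("motif not found: best identity %.3f < %.3f",
                 best, min_identity), call. = FALSE)
  }
  list(start = starts[which.max(ident)], identity = best)
}

#' Extract the 18-residue CaMBD window from an isoform record
#'
#' The window starts at the W anchor (`anchor_start`) and spans 18
#' residues, ending at the F anchor in canonical windows. Codons are sliced
#' from the CDS when available. `reference_offset` maps window position 1
#' onto a reference numbering (1092 places the PMCA4b window at 1093-1110).
#'
#' @param record An [isoform_record()].
#' @param anchor_start 1-based protein position of window residue 1.
#' @param strict_anchors One of `"warn"` (default), `"error"`, `"none"`:
#'   what to do when residues 1/18 are not W/F.
#' @param reference_offset Integer added to window positions to obtain
#'   reference numbering (default `NA`).
#' @return An object of class `cambd_window` with fields
#'   `member_isoforms`, `residues`, `codons` (18 triplets or `NULL`),
#'   `start_pos_protein`, `reference_numbering_offset`.
#' @export
extract_window <- function(record, anchor_start,
                           strict_anchors = c("warn", "error", "none"),
                           reference_offset = NA_integer_) {
  stopifnot(inherits(record, "isoform_record"))
  strict_anchors <- match.arg(strict_anchors)
  anchor_start <- as.integer(anchor_start)
  if (anchor_start < 1L ||
      anchor_start + 17L > nchar(record$protein_seq)) {
    stop("18-residue window exceeds protein bounds", call. = FALSE)
  }
  residues <- substr(record$protein_seq, anchor_start, anchor_start + 17L)
  if (substr(residues, 1, 1) != "W" || substr(residues, 18, 18) != "F") {
    msg <- sprintf("window anchors are %s1/%s18, expected W1/F18 (%s)",
                   substr(residues, 1, 1), substr(residues, 18, 18),
                   record$isoform_label)
    if (strict_anchors == "error") stop(msg, call. = FALSE)
    if (strict_anchors == "warn") warning(msg, call. = FALSE)
  }
  codons <- NULL
  if (!is.null(record$cds_seq)) {
    idx <- anchor_start + 0:17
    codons <- substring(record$cds_seq, 3L * (idx - 1L) + 1L, 3L * idx)
  }
  cambd_window(member_isoforms = record$isoform_label,
               residues = residues, codons = codons,
               start_pos_protein = anchor_start,
               reference_numbering_offset = reference_offset)
}

#' Construct a CaMBD window object
#'
#' @param member_isoforms Character vector of isoform labels.
#' @param residues 18-residue string.
#' @param codons Optional character vector of 18 lower-case codons; each
#'   must translate to the matching residue.
#' @param start_pos_protein 1-based start of the window in the protein.
#' @param reference_numbering_offset Integer offset onto reference
#'   numbering.
#' @return An object of class `cambd_window`.
#' @export
cambd_window <- function(member_isoforms, residues, codons = NULL,
                         start_pos_protein = NA_integer_,
                         reference_numbering_offset = NA_integer_) {
  residues <- toupper(residues)
  if (nchar(residues) != 18L) {
    stop("residues must be an 18-residue string", call. = FALSE)
  }
  if (!is.null(codons)) {
    codons <- tolower(codons)
    if (length(codons) != 18L || any(nchar(codons) != 3L)) {
      stop("codons must be 18 triplets", call. = FALSE)
    }
    tr <- vapply(codons, translate_cds, character(1), USE.NAMES = FALSE)
    if (!identical(paste(tr, collapse = ""), residues)) {
      stop("codons do not translate to residues", call. = FALSE)
    }
  }
  structure(
    list(member_isoforms = member_isoforms, residues = residues,
         codons = codons, start_pos_protein = start_pos_protein,
         reference_numbering_offset = reference_numbering_offset),
    class = "cambd_window"
  )
}

#' @export
print.cambd_window <- function(x, ...) {
  cat(sprintf("<cambd_window> %s: %s%s\n",
              window_group_label(x$member_isoforms), x$residues,
              if (is.null(x$codons)) "" else " [+codons]"))
  invisible(x)
}

#' Group label for a set of isoform labels
#'
#' Joins members with `"_"`. When all members share the same leading
#' letter prefix (e.g. `"PMCA"`), members after the first are shown from
#' their first digit, reproducing labels such as `"PMCA2a_2b_3b"`.
#'
#' @param members Character vector of isoform labels (input order kept).
#' @return A single label string.
#' @export
window_group_label <- function(members) {
  if (length(members) <= 1L) return(members)
  pref <- sub("^([^0-9]*).*$", "\\1", members)
  if (length(unique(pref)) == 1L && nzchar(pref[1])) {
    paste(c(members[1],
            substring(members[-1], nchar(pref[1]) + 1L)),
          collapse = "_")
  } else {
    paste(members, collapse = "_")
  }
}

#' Collapse redundant CaMBD windows across splice variants
#'
#' Windows with identical residue strings are merged into one group whose
#' `member_isoforms` concatenates the members in input order; the group
#' keeps the first member's codons, start position and offset as
#' representative values.
#'
#' @param windows List of [cambd_window()] objects.
#' @return List of grouped `cambd_window` objects (one per distinct
#'   residue string, in order of first appearance).
#' @export
dedup_windows <- function(windows) {
  stopifnot(all(vapply(windows, inherits, logical(1), "cambd_window")))
  res <- vapply(windows, `[[`, character(1), "residues")
  out <- list()
  for (r in unique(res)) {
    idx <- which(res == r)
    w <- windows[[idx[1]]]
    w$member_isoforms <- unlist(lapply(windows[idx], `[[`,
                                       "member_isoforms"))
    out[[length(out) + 1L]] <- w
  }
  out
}

#' Delimit CaMBD windows across a set of isoform records
#'
#' Scans each record for the C28 reference peptide, anchors the 18-residue
#' window at the W aligned to C28 position 8, extracts it (with codons when
#' a CDS is present) and optionally collapses redundant windows.
#'
#' @param records List of [isoform_record()] objects.
#' @param motifs Motif library, see [motif_library()].
#' @param min_identity Scan threshold passed to [scan_for_motif()].
#' @param strict_anchors Passed to [extract_window()].
#' @param dedup Collapse identical windows (default `TRUE`).
#' @param reference_offset Reference numbering offset recorded on each
#'   window (default 1092, the PMCA4b convention).
#' @return List of `cambd_window` objects.
#' @export
delimit_cambd <- function(records, motifs = motif_library(),
                          min_identity = 0.6,
                          strict_anchors = "warn", dedup = TRUE,
                          reference_offset = 1092L) {
  windows <- lapply(records, function(rec) {
    hit <- scan_for_motif(rec$protein_seq, motifs$c28, min_identity)
    extract_window(rec, hit$start + .C28_W_OFFSET - 1L,
                   strict_anchors = strict_anchors,
                   reference_offset = reference_offset)
  })
  if (dedup) dedup_windows(windows) else windows
}

#' Convert windows to a data frame
#'
#' @param windows List of `cambd_window` objects.
#' @return A data frame with columns `group_label`, `members`, `residues`,
#'   `codons` (comma-joined or `NA`), `start_pos`, `offset`.
#' @export
windows_as_data_frame <- function(windows) {
  data.frame(
    group_label = vapply(windows, function(w)
      window_group_label(w$member_isoforms), character(1)),
    members = vapply(windows, function(w)
      paste(w$member_isoforms, collapse = ","), character(1)),
    residues = vapply(windows, `[[`, character(1), "residues"),
    codons = vapply(windows, function(w)
      if (is.null(w$codons)) NA_character_ else
        paste(w$codons, collapse = ","), character(1)),
    start_pos = vapply(windows, function(w)
      as.integer(w$start_pos_protein), integer(1)),
    offset = vapply(windows, function(w)
      as.integer(w$reference_numbering_offset), integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Write a window table as TSV
#'
#' @param windows List of `cambd_window` objects.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_window_tsv <- function(windows, path) {
  utils::write.table(windows_as_data_frame(windows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read isoform records from multi-FASTA files
#'
#' Headers are parsed as `"accession|gene|isoform_label"`. When a CDS
#' FASTA is given, records are matched by isoform label.
#'
#' @param protein_path Path to a protein multi-FASTA.
#' @param cds_path Optional path to a CDS multi-FASTA.
#' @return List of [isoform_record()] objects.
#' @export
read_isoform_fasta <- function(protein_path, cds_path = NULL) {
  prot <- Biostrings::readAAStringSet(protein_path)
  meta <- .parse_isoform_headers(names(prot))
  cds <- NULL
  if (!is.null(cds_path)) {
    dna <- Biostrings::readDNAStringSet(cds_path)
    cmeta <- .parse_isoform_headers(names(dna))
    cds <- stats::setNames(as.character(dna), cmeta$isoform_label)
  }
  lapply(seq_along(prot), function(i) {
    lbl <- meta$isoform_label[i]
    isoform_record(gene_symbol = meta$gene[i], isoform_label = lbl,
                   accession = meta$accession[i],
                   protein_seq = as.character(prot[[i]]),
                   cds_seq = if (!is.null(cds) && lbl %in% names(cds))
                     cds[[lbl]] else NULL)
  })
}

.parse_isoform_headers <- function(headers) {
  parts <- strsplit(sub("\\s.*$", "", headers), "|", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) {
    stop("FASTA headers must be 'accession|gene|isoform_label'; bad: ",
         paste(headers[bad], collapse = "; "), call. = FALSE)
  }
  data.frame(accession = vapply(parts, `[`, character(1), 1),
             gene = vapply(parts, `[`, character(1), 2),
             isoform_label = vapply(parts, `[`, character(1), 3),
             stringsAsFactors = FALSE)
}

#' Write isoform records to FASTA
#'
#' Inverse of [read_isoform_fasta()]; headers are
#' `"accession|gene|isoform_label"`.
#'
#' @param records List of [isoform_record()] objects.
#' @param protein_path Output protein FASTA path.
#' @param cds_path Optional output CDS FASTA path (records lacking a CDS
#'   are skipped there).
#' @return `protein_path`, invisibly.
#' @export
write_isoform_fasta <- function(records, protein_path, cds_path = NULL) {
  hdr <- vapply(records, function(r)
    paste(r$accession, r$gene_symbol, r$isoform_label, sep = "|"),
    character(1))
  aa <- Biostrings::AAStringSet(vapply(records, `[[`, character(1),
                                       "protein_seq"))
  names(aa) <- hdr
  Biostrings::writeXStringSet(aa, protein_path)
  if (!is.null(cds_path)) {
    has <- !vapply(records, function(r) is.null(r$cds_seq), logical(1))
    dna <- Biostrings::DNAStringSet(vapply(records[has], `[[`,
                                           character(1), "cds_seq"))
    names(dna) <- hdr[has]
    Biostrings::writeXStringSet(dna, cds_path)
  }
  invisible(protein_path)
}
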