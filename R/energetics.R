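#' Binding free-energy change upon substitution
#'
#' `ddg = dg_sbs - dg_wt` (kcal/mol); positive values mean less favorable
#' binding of the substituted complex.
#'
#' @param dg_sbs Binding free energy of the substituted complex.
#' @param dg_wt Binding free energy of the wild-type complex.
#' @return Numeric ddG (vectorized).
#' @export
#' @examples
#' compute_ddg(-59.94, -61.92)  # 1.98
compute_ddg <- function(dg_sbs, dg_wt) {
  if (any(!is.finite(dg_sbs)) || any(!is.finite(dg_wt))) {
    stop("binding energies must be finite", call. = FALSE)
  }
  dg_sbs - dg_wt
}

#' Method-specific ddG cutoff
#'
#' `foldx`: 1.7 kcal/mol (twice the reported 0.85 kcal/mol FoldX error);
#' `mutabind2`: 1.5 kcal/mol (the server's meaningful-effect criterion).
#'
#' @param method `"foldx"` or `"mutabind2"` (vectorized).
#' @return Cutoff in kcal/mol.
#' @export
ddg_cutoff <- function(method) {
  cutoffs <- c(foldx = 1.7, mutabind2 = 1.5)
  bad <- setdiff(unique(method), names(cutoffs))
  if (length(bad)) {
    stop("unknown method: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(cutoffs[method])
}

#' Classify a ddG against its method cutoff
#'
#' `|ddg| <= cutoff` is `within_error` (a value exactly at the cutoff is
#' not counted as an effect); `ddg > cutoff` is `weakening`;
#' `ddg < -cutoff` is `strengthening`.
#'
#' @param ddg Numeric ddG values (kcal/mol).
#' @param method Method name(s), see [ddg_cutoff()]; recycled.
#' @return Character vector of labels.
#' @export
#' @examples
#' classify_ddg(c(16.12, -3.92, 0.85), c("foldx", "foldx", "mutabind2"))
classify_ddg <- function(ddg, method) {
  if (any(!is.finite(ddg))) stop("ddg must be finite", call. = FALSE)
  cutoff <- ddg_cutoff(method)
  ifelse(abs(ddg) <= cutoff, "within_error",
         ifelse(ddg > cutoff, "weakening", "strengthening"))
}

#' Classify a ddG table
#'
#' Adds `cutoff` and `label` columns to a long table of ddG estimates.
#'
#' @param ddg_table Data frame with at least `ddg` and `method` columns
#'   (e.g. [cambd_ddg_table()]).
#' @return The input with `cutoff` and `label` appended.
#' @export
classify_ddg_table <- function(ddg_table) {
  stopifnot(all(c("ddg", "method") %in% names(ddg_table)))
  ddg_table$cutoff <- ddg_cutoff(ddg_table$method)
  ddg_table$label <- classify_ddg(ddg_table$ddg, ddg_table$method)
  ddg_table
}

#' Cohort-level ddG classification summary
#'
#' @param classified Data frame with `label` and `method` columns (see
#'   [classify_ddg_table()]), or a bare character vector of labels.
#' @return List with `n_total`, `n_within`, `n_weakening`,
#'   `n_strengthening` and a `by_method` data frame of per-method counts.
#' @export
summarize_cohort <- function(classified) {
  if (is.character(classified)) {
    classified <- data.frame(label = classified,
                             method = rep("all", length(classified)),
                             stringsAsFactors = FALSE)
  }
  stopifnot("label" %in% names(classified))
  lv <- c("within_error", "weakening", "strengthening")
  bad <- setdiff(unique(classified$label), lv)
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cnt <- function(df) {
    tab <- table(factor(df$label, levels = lv))
    c(n_total = nrow(df), n_within = unname(tab["within_error"]),
      n_weakening = unname(tab["weakening"]),
      n_strengthening = unname(tab["strengthening"]))
  }
  tot <- cnt(classified)
  by_method <- do.call(rbind, lapply(
    split(classified, classified$method), function(df) {
      data.frame(method = df$method[1], t(cnt(df)),
                 stringsAsFactors = FALSE)
    }))
  rownames(by_method) <- NULL
  c(as.list(tot), list(by_method = by_method))
}

#' Parse FoldX AnalyseComplex-style output
#'
#' Locates the header row (the line containing an interaction-energy
#' column), then reads one record per complex. Header naming is handled
#' tolerantly (`"Interaction Energy"`, `"interaction_energy"`, `"Total"`);
#' numeric parsing is strict.
#'
#' @param path Path to a FoldX-style tab-separated summary, or a character
#'   vector of its lines.
#' @return Data frame with `complex_id` and `dg` (kcal/mol), input order
#'   preserved.
#' @export
parse_foldx_output <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path))
    readLines(path) else as.character(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FoldX output", call. = FALSE)
  is_energy_col <- function(x) {
    x <- tolower(trimws(x))
    x %in% c("interaction energy", "interaction_energy",
             "interactionenergy", "total energy", "total")
  }
  hdr_idx <- NA_integer_
  for (i in seq_along(lines)) {
    if (any(is_energy_col(strsplit(lines[i], "\t")[[1]]))) {
      hdr_idx <- i; break
    }
  }
  if (is.na(hdr_idx)) {
    stop("no interaction-energy column found", call. = FALSE)
  }
  hdr <- strsplit(lines[hdr_idx], "\t")[[1]]
  col <- which(is_energy_col(hdr))[1]
  body <- lines[-seq_len(hdr_idx)]
  if (!length(body)) stop("FoldX output has no data rows", call. = FALSE)
  recs <- lapply(body, function(ln) {
    f <- strsplit(ln, "\t")[[1]]
    if (length(f) < col) stop("short FoldX record: ", ln, call. = FALSE)
    dg <- suppressWarnings(as.numeric(f[col]))
    if (is.na(dg)) stop("non-numeric energy cell: ", f[col],
                        call. = FALSE)
    id <- sub("(_Repair)?\\.pdb$", "", f[1], ignore.case = TRUE)
    data.frame(complex_id = id, dg = dg, stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Read a MutaBind2-style ddG CSV
#'
#' @param path CSV with columns `chain`, `mutation` and `ddg` (extra
#'   columns kept). Positive ddG means decreased binding affinity; no sign
#'   flipping is applied on ingest.
#' @return Data frame of records.
#' @export
read_mutabind_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("chain", "mutation", "ddg")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!is.numeric(df$ddg)) stop("ddg column must be numeric",
                                call. = FALSE)
  df
}
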