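# Seeded generators that emulate every external input of the workflow:
# an isoform family sharing the 18-residue CaMBD motif, replicate ipTM
# scores, FoldX/MutaBind2-style energy tables with planted effect labels,
# and gene-disease association exports. Each generator is a pure function
# of (seed, parameters); generators draw from independent substreams so
# adding one fixture does not shift another.

# Deterministic substream seed, kept below 2^31.
.sub_seed <- function(seed, stream) {
  (as.integer(seed) %% 100000L) * 7919L + stream * 104729L
}

.CODONS_BY_AA <- local({
  gc <- Biostrings::GENETIC_CODE
  split(tolower(names(gc)), gc)
})

#' Synthetic fixture specification
#'
#' Bundles the generator parameters. Defaults mirror the study
#' conditions: an 11-member isoform family around the PMCA4b window with
#' anchors W1/F18 fixed, five ipTM replicates per complex near 0.65 with
#' replicate noise 0.03, and an effect mix matching the published cohort
#' proportions (51 weakening, 5 strengthening, 14 within-error of 70).
#'
#' @param seed Integer master seed.
#' @param n_isoforms Family size (default 11).
#' @param motif 18-residue window embedded in every isoform (default the
#'   PMCA4b window).
#' @param divergence Per-site substitution probability in `[0, 1]` at
#'   non-anchor window positions (default 0.1).
#' @param iptm_mu,iptm_sigma Gaussian ipTM replicate model (default
#'   0.65, 0.03).
#' @param energy_effect_mix Named proportions
#'   `(weakening, strengthening, within_error)` summing to 1.
#' @param n_gda Number of gene-disease association records (default 20).
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_isoforms = 11L,
                         motif = "WFRGLNRIQTQIKVVKAF",
                         divergence = 0.1,
                         iptm_mu = 0.65, iptm_sigma = 0.03,
                         energy_effect_mix = c(weakening = 51 / 70,
                                               strengthening = 5 / 70,
                                               within_error = 14 / 70),
                         n_gda = 20L) {
  stopifnot(nchar(motif) == 18L, divergence >= 0, divergence <= 1,
            iptm_sigma >= 0, n_gda >= 0)
  if (abs(sum(energy_effect_mix) - 1) > 1e-8) {
    stop("energy_effect_mix must sum to 1", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_isoforms = n_isoforms,
                 motif = toupper(motif), divergence = divergence,
                 iptm_mu = iptm_mu, iptm_sigma = iptm_sigma,
                 energy_effect_mix = energy_effect_mix, n_gda = n_gda),
            class = "fixture_spec")
}

#' Reverse-translate a protein with seeded synonymous codon choice
#'
#' Each residue is encoded by a codon drawn uniformly among its
#' synonymous codons; the caller controls the RNG state.
#'
#' @param protein Amino-acid string.
#' @return Lower-case nucleotide string of length `3 * nchar(protein)`.
#' @export
reverse_translate <- function(protein) {
  aa <- strsplit(toupper(protein), "")[[1]]
  paste(vapply(aa, function(a) {
    opts <- .CODONS_BY_AA[[a]]
    if (is.null(opts)) stop("cannot encode residue: ", a, call. = FALSE)
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

#' Generate a synthetic isoform family
#'
#' Each isoform embeds the motif — per-site mutated with probability
#' `divergence`, with the W1/F18 anchors preserved — inside the C28
#' flanking context (`LRRGQIL` upstream, `HSS` downstream) and random
#' flank sequence, and carries a CDS produced by seeded reverse
#' translation. Byte-identical output for identical specs.
#'
#' @param spec A [fixture_spec()].
#' @param flank_lengths Lengths of the random N- and C-terminal flanks
#'   (default 40 and 10 residues).
#' @return List of [isoform_record()] objects.
#' @export
gen_isoform_family <- function(spec, flank_lengths = c(40L, 10L)) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(.sub_seed(spec$seed, 1L))
  motif <- strsplit(spec$motif, "")[[1]]
  lapply(seq_len(spec$n_isoforms), function(i) {
    win <- motif
    for (k in 2:17) {
      if (stats::runif(1) < spec$divergence) {
        win[k] <- sample(setdiff(.AA_ALPHABET, win[k]), 1L)
      }
    }
    protein <- paste(c(
      sample(.AA_ALPHABET, flank_lengths[1], replace = TRUE),
      strsplit("LRRGQIL", "")[[1]], win, strsplit("HSS", "")[[1]],
      sample(.AA_ALPHABET, flank_lengths[2], replace = TRUE)),
      collapse = "")
    isoform_record(gene_symbol = "GENE1",
                   isoform_label = sprintf("iso%02d", i),
                   accession = sprintf("SYN%04d", i),
                   protein_seq = protein,
                   cds_seq = reverse_translate(protein))
  })
}

#' Generate Gaussian replicate ipTM score tables
#'
#' Per-complex replicates drawn from `N(mu, sigma)` and clamped to
#' `[0, 1]`.
#'
#' @param seed Integer seed.
#' @param mu,sigma Gaussian parameters.
#' @param n_models Replicates per complex (default 5).
#' @param n_complexes Number of complexes (default 1).
#' @return Data frame with `complex_id`, `model_index`, `iptm`.
#' @export
gen_iptm_replicates <- function(seed, mu = 0.65, sigma = 0.03,
                                n_models = 5L, n_complexes = 1L) {
  stopifnot(sigma >= 0)
  set.seed(.sub_seed(seed, 2L))
  data.frame(
    complex_id = rep(sprintf("cx%04d", seq_len(n_complexes)),
                     each = n_models),
    model_index = rep(seq_len(n_models) - 1L, n_complexes),
    iptm = pmin(1, pmax(0, stats::rnorm(n_models * n_complexes,
                                        mu, sigma))),
    stringsAsFactors = FALSE
  )
}

# Exact integer allocation of n among proportions (largest remainder).
.allocate_counts <- function(n, mix) {
  base <- floor(mix * n)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(mix * n - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Generate FoldX- and MutaBind2-style energy tables with planted labels
#'
#' For each method, draws `n` ddG values whose true classification
#' matches the planted effect mix exactly (weakening:
#' `U(cutoff + 0.1, 10)`; strengthening mirrored; within-error:
#' `U(-cutoff, cutoff)`). FoldX records additionally carry a wild-type
#' binding energy and the implied substituted-complex energy.
#'
#' @param seed Integer seed.
#' @param n Records per method (default 70).
#' @param mix Named proportions
#'   `(weakening, strengthening, within_error)` summing to 1.
#' @param methods Methods to generate (default both).
#' @return List with one data frame per method (`complex_id`, `ddg`,
#'   `true_label`, plus `dg_wt`/`dg_sbs` for foldx) and `truth`, the
#'   combined label table.
#' @export
gen_energy_tables <- function(seed, n = 70L,
                              mix = c(weakening = 51 / 70,
                                      strengthening = 5 / 70,
                                      within_error = 14 / 70),
                              methods = c("foldx", "mutabind2")) {
  if (abs(sum(mix) - 1) > 1e-8) stop("mix must sum to 1", call. = FALSE)
  mix <- mix[c("weakening", "strengthening", "within_error")]
  set.seed(.sub_seed(seed, 3L))
  out <- list()
  for (method in methods) {
    cutoff <- ddg_cutoff(method)
    counts <- .allocate_counts(n, mix)
    labels <- sample(rep(names(mix), counts))
    ddg <- vapply(labels, function(lb) {
      switch(lb,
             weakening = stats::runif(1, cutoff + 0.1, 10),
             strengthening = stats::runif(1, -10, -cutoff - 0.1),
             within_error = stats::runif(1, -cutoff, cutoff))
    }, numeric(1), USE.NAMES = FALSE)
    df <- data.frame(
      complex_id = sprintf("%s_cx%04d", method, seq_len(n)),
      method = method, ddg = round(ddg, 2), true_label = labels,
      stringsAsFactors = FALSE)
    if (method == "foldx") {
      df$dg_wt <- round(stats::runif(n, -65, -45), 2)
      df$dg_sbs <- df$dg_wt + df$ddg
    }
    out[[method]] <- df
  }
  out$truth <- do.call(rbind, lapply(out, function(df)
    df[, c("complex_id", "method", "true_label")]))
  rownames(out$truth) <- NULL
  out
}

#' Generate a gene-disease association table
#'
#' Seeded records spanning all polygenicity classes and both strata
#' (when `n >= 6`), with association scores on a 0.05 grid and a mix of
#' association types.
#'
#' @param seed Integer seed.
#' @param n_gda Number of records (>= 0).
#' @return Data frame with `gene`, `disease_id`, `disease_name`,
#'   `score_gda`, `association_type`, `n_genes_disease`.
#' @export
gen_gda_table <- function(seed, n_gda = 20L) {
  stopifnot(n_gda >= 0)
  cols <- c("gene", "disease_id", "disease_name", "score_gda",
            "association_type", "n_genes_disease")
  if (n_gda == 0L) {
    df <- data.frame(gene = character(), disease_id = character(),
                     disease_name = character(), score_gda = numeric(),
                     association_type = character(),
                     n_genes_disease = integer(),
                     stringsAsFactors = FALSE)
    return(df[, cols])
  }
  set.seed(.sub_seed(seed, 4L))
  planted <- c(1L, 2L, 7L, 31L, 50L, 2L)
  ngenes <- if (n_gda >= length(planted)) {
    c(planted, sample.int(100L, n_gda - length(planted),
                          replace = TRUE))
  } else {
    sample.int(100L, n_gda, replace = TRUE)
  }
  data.frame(
    gene = sample(paste0("ATP2B", 1:4), n_gda, replace = TRUE),
    disease_id = sprintf("D%04d", seq_len(n_gda)),
    disease_name = sprintf("synthetic disease %02d", seq_len(n_gda)),
    score_gda = round(stats::runif(n_gda), 2),
    association_type = sample(c("CausalMutation", "GeneticVariation",
                                "Biomarker"), n_gda, replace = TRUE),
    n_genes_disease = ngenes,
    stringsAsFactors = FALSE
  )[, cols]
}

#' Write a complete synthetic fixture set to a directory
#'
#' Emits every file format the workflow ingests: protein and CDS FASTA,
#' a replicate ipTM CSV, a FoldX AnalyseComplex-style TSV (wild-type and
#' substituted rows per complex), a MutaBind2-style CSV, a gene-disease
#' CSV, and a `truth.json` with the planted energy labels.
#'
#' @param spec A [fixture_spec()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(spec, outdir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  fam <- gen_isoform_family(spec)
  write_isoform_fasta(fam, p("protein.fasta"), p("cds.fasta"))
  utils::write.csv(gen_iptm_replicates(spec$seed, spec$iptm_mu,
                                       spec$iptm_sigma,
                                       n_complexes = spec$n_isoforms) |>
                     transform(ptm = NA_real_),
                   p("iptm.csv"), row.names = FALSE)
  en <- gen_energy_tables(spec$seed, mix = spec$energy_effect_mix)
  writeLines(c("Pdb\tGroup1\tGroup2\tInteraction Energy",
               sprintf("%s_WT_Repair.pdb\tA\tB\t%.2f",
                       en$foldx$complex_id, en$foldx$dg_wt),
               sprintf("%s_SBS_Repair.pdb\tA\tB\t%.2f",
                       en$foldx$complex_id, en$foldx$dg_sbs)),
             p("foldx.tsv"))
  utils::write.csv(
    data.frame(chain = "B", mutation = en$mutabind2$complex_id,
               ddg = en$mutabind2$ddg, stringsAsFactors = FALSE),
    p("mutabind.csv"), row.names = FALSE)
  utils::write.csv(gen_gda_table(spec$seed, spec$n_gda), p("gda.csv"),
                   row.names = FALSE)
  jsonlite::write_json(en$truth, p("truth.json"), dataframe = "rows")
  invisible(c(protein = p("protein.fasta"), cds = p("cds.fasta"),
              iptm = p("iptm.csv"), foldx = p("foldx.tsv"),
              mutabind = p("mutabind.csv"), gda = p("gda.csv"),
              truth = p("truth.json")))
}
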