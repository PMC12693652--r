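test_that("conservation stars count identical intra-codon positions", {
  tab <- cambd_codon_table()
  expect_equal(conservation_stars(tab[, "T1"]), 3L)   # all tgg
  expect_equal(conservation_stars(tab[, "T3"]), 1L)   # arg codons
  expect_equal(conservation_stars(tab[, "T13"]), 0L)  # fully variable
  # 3 stars iff all codons identical
  expect_equal(conservation_stars(c("atg", "atg")), 3L)
  expect_lt(conservation_stars(c("atg", "ata")), 3L)
  expect_error(conservation_stars("atg"), ">= 2")
})

test_that("the star profile reproduces the published conservation row", {
  expect_identical(unname(star_profile(cambd_codon_table())),
                   unname(as.integer(cambd_star_profile())))
  expect_true(all(star_profile(cambd_codon_table()) %in% 0:3))
})

test_that("column identity is the weighted modal residue frequency", {
  expect_equal(column_identity(rep("L", 5)), 1)
  expect_equal(column_identity(c("W", "F")), 0.5)
  # hand-computed weighted mode
  expect_equal(column_identity(c("N", "N", "S"), c(0.25, 0.25, 0.5)), 0.5)
  # gap weight discarded and remaining renormalized
  expect_equal(column_identity(c("N", "-", "S"), c(0.5, 0.25, 0.25)),
               2 / 3)
  expect_error(column_identity(c("-", "-")), "all-gap")
})

test_that("Henikoff weights favor divergent rows and normalize to 1", {
  # hand computation on the 2-column toy {AA, AA, AT}:
  # col1 gives 1/3 each; col2 gives (1/4, 1/4, 1/2)
  w <- sequence_weights(c("AA", "AA", "AT"))
  expect_equal(sum(w), 1)
  expect_equal(w, c(7, 7, 10) / 24)
  # identical rows share weight equally
  expect_equal(sequence_weights(c("LKV", "LKV", "LKV", "LKV")),
               rep(0.25, 4))
  expect_equal(sequence_weights("LKV"), 1)
})

test_that("weighted MI matches hand-derived cases", {
  msa <- c("AC", "AC", "BD", "BD")
  m <- weighted_mutual_information(msa, weights = rep(0.25, 4))
  expect_equal(m[1, 2], 1)  # MI = 1 bit = min entropy
  msa2 <- c("AC", "AD", "BC", "BD")
  m2 <- weighted_mutual_information(msa2, weights = rep(0.25, 4))
  expect_equal(m2[1, 2], 0)  # independent columns
  # invariant column forces score 0 regardless of the partner
  msa3 <- c("AC", "AD", "AC", "AD")
  m3 <- weighted_mutual_information(msa3, weights = rep(0.25, 4))
  expect_equal(m3[1, 2], 0)
  expect_error(weighted_mutual_information(msa, weights = c(1, 1)),
               "weights length")
})

test_that("weighted MI equals a brute-force joint-count oracle", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:6, 1); p <- sample(2:6, 1)
    m <- matrix(sample(c("A", "B", "C"), n * p, replace = TRUE), n, p)
    scores <- weighted_mutual_information(m, weights = rep(1 / n, n),
                                          pseudocount = 0)
    for (i in seq_len(p - 1)) {
      for (j in (i + 1):p) {
        expect_equal(scores[i, j], min(1, mi_oracle(m[, i], m[, j])),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("the MI matrix is symmetric, bounded and row-permutation invariant", {
  set.seed(7)
  m <- matrix(sample(c("A", "B", "C", "D"), 8 * 6, replace = TRUE), 8, 6)
  w <- sequence_weights(m)
  s <- weighted_mutual_information(m, w)
  expect_true(isSymmetric(unname(s)))
  off <- s[upper.tri(s)]
  expect_true(all(off >= 0 & off <= 1))
  expect_true(all(is.na(diag(s))))
  perm <- sample(nrow(m))
  s2 <- weighted_mutual_information(m[perm, ], w[perm])
  expect_equal(unname(s2), unname(s), tolerance = 1e-12)
})

test_that("gap handling drops pair rows and renormalizes", {
  # rows with a gap in either column are excluded from that pair
  msa <- c("AC", "AC", "B-", "BD")
  s <- weighted_mutual_information(msa, weights = rep(0.25, 4))
  expect_equal(s[1, 2], min(1, mi_oracle(c("A", "A", "B"),
                                         c("C", "C", "D"))),
               tolerance = 1e-12)
})

test_that("covariation clustering matches a brute-force agglomeration oracle", {
  set.seed(13)
  for (rep in 1:5) {
    p <- sample(4:7, 1)
    s <- matrix(runif(p * p), p, p)
    s <- (s + t(s)) / 2
    dimnames(s) <- list(paste0("C", 1:p), paste0("C", 1:p))
    hc <- cluster_covariation(s)
    expect_true(all(diff(hc$height) >= -1e-12))  # monotone merges
    d <- 1 - s; diag(d) <- 0
    expect_equal(unname(as.matrix(stats::cophenetic(hc))),
                 avg_linkage_cophenetic(d), tolerance = 1e-12)
  }
})

test_that("perfect within-block covariation merges blocks before crossing", {
  s <- rbind(c(NA, 1, 0, 0), c(1, NA, 0, 0),
             c(0, 0, NA, 1), c(0, 0, 1, NA))
  dimnames(s) <- list(paste0("C", 1:4), paste0("C", 1:4))
  hc <- cluster_covariation(s)
  expect_equal(hc$height, c(0, 0, 1), tolerance = 1e-12)
  # two-column case: single merge at 1 - score
  s2 <- matrix(c(NA, 0.3, 0.3, NA), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  hc2 <- cluster_covariation(s2)
  expect_equal(hc2$height, 0.7)
  expect_error(cluster_covariation(matrix(0, 2, 3)), "square")
})

test_that("matrix TSV and Newick exports round-trip structure", {
  set.seed(5)
  m <- matrix(sample(c("A", "B"), 5 * 4, replace = TRUE), 5, 4)
  s <- weighted_mutual_information(m)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(s, path)
  back <- read.delim(path, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), unname(s), tolerance = 1e-6,
               ignore_attr = TRUE)
  nwk <- covariation_newick(cluster_covariation(s))
  expect_match(nwk, "^\\(.*\\);$")
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, colnames(s))
})

test_that("aligned FASTA reading yields a labelled alignment matrix", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">row1", "WF-G", ">row2", "WFRG"), path)
  m <- read_msa_fasta(path)
  expect_identical(dim(m), c(2L, 4L))
  expect_identical(rownames(m), c("row1", "row2"))
  expect_identical(m[[1, 3]], "-")
})
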