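test_that("summarize_iptm reproduces published interval bounds", {
  s <- summarize_iptm(c(0.71, 0.68, 0.67, 0.65, 0.65))
  expect_identical(s$display, "[0.64-0.7]")
  expect_equal(round(c(s$ci_lo, s$ci_hi), 2), c(0.64, 0.70))
  s2 <- summarize_iptm(c(0.74, 0.65, 0.65, 0.62, 0.59))
  expect_identical(s2$display, "[0.58-0.72]")
  # degenerate: zero spread gives a zero-width interval at the mean
  s3 <- summarize_iptm(rep(0.5, 5))
  expect_equal(c(s3$ci_lo, s3$mean, s3$ci_hi), c(0.5, 0.5, 0.5))
  expect_error(summarize_iptm(0.5), "n >= 2")
  expect_error(summarize_iptm(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("interval width grows with level and spread, and contains the mean", {
  v <- c(0.6, 0.62, 0.66, 0.7, 0.72)
  widths <- vapply(c(0.8, 0.9, 0.95, 0.99), function(lv) {
    s <- summarize_iptm(v, lv)
    expect_lte(s$ci_lo, s$mean); expect_gte(s$ci_hi, s$mean)
    s$ci_hi - s$ci_lo
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
  wider <- summarize_iptm(c(0.5, 0.55, 0.66, 0.75, 0.8))
  expect_gt(wider$ci_hi - wider$ci_lo,
            summarize_iptm(v)$ci_hi - summarize_iptm(v)$ci_lo)
})

test_that("the full replicate grid reproduces every published interval", {
  tab <- cambd_iptm_table()
  out <- summarize_iptm_table(tab)
  expect_equal(nrow(out), 45L)
  expect_equal(round(out$ci_lo, 2), tab$printed_lo)
  expect_equal(round(out$ci_hi, 2), tab$printed_hi)
})

test_that("select_best takes the ipTM argmax with lowest-index ties", {
  expect_equal(select_best(c(0.71, 0.68, 0.67, 0.65, 0.65)), 0L)
  expect_equal(select_best(rep(0.6, 5)), 0L)
  expect_equal(select_best(c(0.2, 0.9)), 1L)
  expect_error(select_best(numeric(0)), "no models")
})

test_that("kabsch_rmsd is zero under congruence and rigid-motion invariant", {
  set.seed(21)
  a <- matrix(rnorm(36), 12, 3)
  expect_equal(kabsch_rmsd(a, a), 0)
  for (rep in 1:5) {
    b <- rigid_motion(a)
    expect_lt(kabsch_rmsd(a, b), 1e-6)
    # symmetry and invariance under motions of either argument
    p <- a + matrix(rnorm(36, sd = 0.5), 12, 3)
    expect_equal(kabsch_rmsd(a, p), kabsch_rmsd(p, a),
                 tolerance = 1e-9)
    expect_equal(kabsch_rmsd(rigid_motion(a), p), kabsch_rmsd(a, p),
                 tolerance = 1e-6)
  }
  expect_error(kabsch_rmsd(a[1:2, ], a[1:2, ]), ">= 3")
})

test_that("kabsch_rmsd matches the bio3d fitted-superposition oracle", {
  set.seed(22)
  for (rep in 1:5) {
    n <- sample(4:20, 1)
    a <- matrix(rnorm(3 * n), n, 3)
    b <- rigid_motion(a) + matrix(rnorm(3 * n, sd = 0.4), n, 3)
    expect_equal(kabsch_rmsd(a, b),
                 bio3d::rmsd(as.vector(t(a)), as.vector(t(b)),
                             fit = TRUE),
                 tolerance = 1e-3)
  }
})

test_that("coordinate data frames are matched by chain/residue/atom", {
  set.seed(23)
  xyz <- matrix(rnorm(15), 5, 3)
  df <- data.frame(chain = "A", resno = 1:5, resname = "ALA",
                   atom = "CA", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  df2 <- df[sample(5), ]  # order must not matter
  df2[, c("x", "y", "z")] <- rigid_motion(
    as.matrix(df2[, c("x", "y", "z")]))
  expect_lt(kabsch_rmsd(df, df2), 1e-6)
  expect_error(kabsch_rmsd(df, transform(df, atom = "CB")),
               "no matching atoms")
})

test_that("dihedral_angle matches the bio3d torsion oracle", {
  set.seed(24)
  for (rep in 1:10) {
    p <- matrix(rnorm(12), 4, 3)
    expect_equal(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 as.numeric(bio3d::torsion.xyz(as.vector(t(p)))),
                 tolerance = 1e-6)
  }
  expect_warning(
    out <- dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                          c(3, 1, 0)),
    "collinear")
  expect_true(is.na(out))
})

test_that("backbone dihedrals recover the torsions a chain was built with", {
  n <- 8L
  helix <- build_backbone(rep(-57, n), rep(-47, n))
  dih <- backbone_dihedrals(helix)
  expect_equal(nrow(dih), n)
  expect_true(is.na(dih$phi[1]))   # no preceding C at the N-terminus
  expect_true(is.na(dih$psi[n]))   # no following N at the C-terminus
  expect_equal(dih$phi[-1], rep(-57, n - 1), tolerance = 1e-6)
  expect_equal(dih$psi[-n], rep(-47, n - 1), tolerance = 1e-6)
  # two-residue chain: one defined phi and one defined psi
  two <- build_backbone(rep(-57, 2), rep(-47, 2))
  d2 <- backbone_dihedrals(two)
  expect_equal(sum(!is.na(d2$phi)), 1L)
  expect_equal(sum(!is.na(d2$psi)), 1L)
})

test_that("residues missing backbone atoms are skipped with a warning", {
  helix <- build_backbone(rep(-57, 5), rep(-47, 5))
  broken <- helix[!(helix$resno == 3 & helix$atom == "CA"), ]
  expect_warning(dih <- backbone_dihedrals(broken), "missing backbone")
  expect_false(3 %in% dih$resno)
})

test_that("favored_fraction counts residues inside the region boxes", {
  helix <- build_backbone(rep(-57, 8), rep(-47, 8))
  expect_equal(favored_fraction(backbone_dihedrals(helix)), 100)
  # mixed chain: 3 of 4 defined residues favored
  mixed <- build_backbone(c(-57, -57, -120, -57, 0, -57),
                          c(-47, -47, 130, -47, -120, -47))
  frac <- favored_fraction(backbone_dihedrals(mixed))
  expect_equal(frac, 75)
  expect_error(favored_fraction(data.frame(phi = NA_real_,
                                           psi = NA_real_)),
               "no residues")
})

test_that("confidence score files round-trip from CSV and JSON", {
  df <- data.frame(complex_id = "cx1", model_index = 0:4,
                   iptm = c(0.71, 0.68, 0.67, 0.65, 0.65),
                   ptm = 0.6)
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, csv, row.names = FALSE)
  expect_equal(read_confidence_scores(csv)$iptm, df$iptm)
  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(df, js, dataframe = "columns")
  expect_equal(read_confidence_scores(js)$iptm, df$iptm)
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(iptm = 0.5), bad, row.names = FALSE)
  expect_error(read_confidence_scores(bad), "missing fields")
})
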