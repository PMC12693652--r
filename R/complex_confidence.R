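#' Student-t confidence interval for replicate ipTM scores
#'
#' Mean and two-sided `level` confidence interval
#' `mean +/- t * sd / sqrt(n)` over model replicates of the interface
#' predicted TM-score.
#'
#' @param values Numeric ipTM replicates in `[0, 1]`, `n >= 2`.
#' @param level Confidence level (default 0.95).
#' @return A list of class `confidence_summary`: `n`, `mean`, `sd`,
#'   `ci_lo`, `ci_hi`, `level` and `display` (bounds rounded to 2 decimals
#'   with trailing zeros trimmed, e.g. `"[0.64-0.7]"`).
#' @export
#' @examples
#' summarize_iptm(c(0.71, 0.68, 0.67, 0.65, 0.65))
summarize_iptm <- function(values, level = 0.95) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need n >= 2 replicates", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0 | values > 1)) {
    stop("ipTM values must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(level > 0, level < 1)
  n <- length(values); m <- mean(values); s <- stats::sd(values)
  half <- stats::qt((1 + level) / 2, df = n - 1L) * s / sqrt(n)
  structure(
    list(n = n, mean = m, sd = s, ci_lo = m - half, ci_hi = m + half,
         level = level, display = format_ci(m - half, m + half)),
    class = "confidence_summary"
  )
}

#' @export
print.confidence_summary <- function(x, ...) {
  cat(sprintf("<confidence_summary> n=%d mean=%.3f sd=%.3f %d%% CI %s\n",
              x$n, x$mean, x$sd, round(100 * x$level), x$display))
  invisible(x)
}

#' Format a confidence interval for display
#'
#' Rounds both bounds to 2 decimals and trims a trailing zero, matching
#' the `[0.64-0.7]` reporting style.
#'
#' @param lo,hi Interval bounds.
#' @return A string `"[lo-hi]"`.
#' @export
format_ci <- function(lo, hi) {
  trim <- function(x) sub("(\\.\\d)0$", "\\1", sprintf("%.2f", x))
  sprintf("[%s-%s]", trim(lo), trim(hi))
}

#' Select the best model by ipTM
#'
#' Argmax of ipTM; ties broken by the lowest model index.
#'
#' @param iptm Numeric ipTM values, one per model.
#' @param model_index Model identifiers (default `0:(n-1)`).
#' @return The selected model index.
#' @export
#' @examples
#' select_best(c(0.71, 0.68, 0.67, 0.65, 0.65))  # 0
select_best <- function(iptm, model_index = seq_along(iptm) - 1L) {
  if (!length(iptm)) stop("no models supplied", call. = FALSE)
  stopifnot(length(iptm) == length(model_index))
  model_index[which.max(iptm)]
}

#' Summarize a replicate ipTM table
#'
#' Applies [summarize_iptm()] and [select_best()] row-wise to a wide
#' table of model replicates.
#'
#' @param scores Data frame with identifier columns plus
#'   `model_0 ... model_k` replicate columns (e.g. [cambd_iptm_table()]).
#' @param level Confidence level (default 0.95).
#' @return The identifier columns plus `n`, `mean`, `sd`, `ci_lo`,
#'   `ci_hi`, `display`, `best_model`.
#' @export
summarize_iptm_table <- function(scores, level = 0.95) {
  mcols <- grep("^model_\\d+$", names(scores), value = TRUE)
  if (length(mcols) < 2L) {
    stop("need >= 2 model_* replicate columns", call. = FALSE)
  }
  idx <- as.integer(sub("^model_", "", mcols))
  out <- lapply(seq_len(nrow(scores)), function(i) {
    v <- as.numeric(scores[i, mcols])
    s <- summarize_iptm(v, level)
    data.frame(n = s$n, mean = s$mean, sd = s$sd, ci_lo = s$ci_lo,
               ci_hi = s$ci_hi, display = s$display,
               best_model = select_best(v, idx),
               stringsAsFactors = FALSE)
  })
  cbind(scores[, setdiff(names(scores), mcols), drop = FALSE],
        do.call(rbind, out))
}

#' Read per-model confidence scores
#'
#' CSV input needs columns `complex_id`, `model_index`, `iptm` (optional
#' `ptm`); JSON input is a list of per-model objects with the same fields
#' (optionally `plddt`, a per-residue vector in `[0, 100]`).
#'
#' @param path CSV or JSON file.
#' @return Data frame of model confidence records (a `plddt` list column
#'   for JSON input carrying per-residue values).
#' @export
read_confidence_scores <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(recs[setdiff(names(recs), "plddt")],
                        stringsAsFactors = FALSE)
    if (!is.null(recs$plddt)) df$plddt <- recs$plddt
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("complex_id", "model_index", "iptm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing fields: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$iptm < 0 | df$iptm > 1)) {
    stop("iptm out of [0, 1]", call. = FALSE)
  }
  df
}

# ---- coordinates, superposition, dihedrals ----

#' Read a coordinate set from PDB or mmCIF
#'
#' @param path Structure file (`.pdb` or `.cif`).
#' @return Data frame of atoms: `chain`, `resno`, `resname`, `atom`,
#'   `x`, `y`, `z` (Angstrom).
#' @export
read_coords <- function(path) {
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    bio3d::read.cif(path)
  } else {
    bio3d::read.pdb(path)
  }
  a <- pdb$atom
  data.frame(chain = a$chain, resno = a$resno, resname = a$resid,
             atom = a$elety, x = a$x, y = a$y, z = a$z,
             stringsAsFactors = FALSE)
}

#' Optimal rigid-body superposition RMSD (Kabsch)
#'
#' Least-squares superposition by centroid removal and the SVD-based
#' optimal rotation (reflections disallowed), returning the post-fit
#' RMSD. Inputs are either n x 3 coordinate matrices in matched row order
#' or coordinate data frames (see [read_coords()]) matched by
#' `(chain, resno, atom)` after applying `selection`.
#'
#' @param a,b Coordinate matrices or data frames.
#' @param selection Atom-name filter applied to data-frame input
#'   (default `"CA"`; `NULL` keeps every atom).
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(a, b, selection = "CA") {
  if (is.data.frame(a) || is.data.frame(b)) {
    m <- .match_atoms(a, b, selection)
    a <- m$a; b <- m$b
  }
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b)) || ncol(a) != 3L) {
    stop("coordinate sets must be matched n x 3 matrices", call. = FALSE)
  }
  if (nrow(a) < 3L) stop("need >= 3 atom pairs", call. = FALSE)
  ac <- sweep(a, 2L, colMeans(a))
  bc <- sweep(b, 2L, colMeans(b))
  s <- svd(crossprod(bc, ac))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fit <- bc %*% rot
  sqrt(mean(rowSums((ac - fit)^2)))
}

.match_atoms <- function(a, b, selection) {
  sel <- function(df) {
    stopifnot(all(c("chain", "resno", "atom", "x", "y", "z") %in%
                    names(df)))
    if (!is.null(selection)) df <- df[df$atom %in% selection, ,
                                      drop = FALSE]
    df$key <- paste(df$chain, df$resno, df$atom, sep = "/")
    if (anyDuplicated(df$key)) {
      stop("duplicate (chain, resno, atom) keys", call. = FALSE)
    }
    df
  }
  a <- sel(a); b <- sel(b)
  common <- intersect(a$key, b$key)
  if (!length(common)) stop("no matching atoms between selections",
                            call. = FALSE)
  list(a = as.matrix(a[match(common, a$key), c("x", "y", "z")]),
       b = as.matrix(b[match(common, b$key), c("x", "y", "z")]))
}

#' Dihedral angle of four points
#'
#' Signed torsion in degrees in `(-180, 180]`; `NA` (with a warning) for
#' degenerate, collinear geometry.
#'
#' @param p1,p2,p3,p4 Numeric xyz vectors.
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9) {
    warning("collinear atoms: torsion undefined", call. = FALSE)
    return(NA_real_)
  }
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  # IUPAC sign: positive for clockwise rotation viewed along p2 -> p3
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Backbone phi/psi dihedrals
#'
#' Standard phi (C-, N, CA, C) and psi (N, CA, C, N+) torsions per
#' residue, in degrees. Chain termini yield `NA` phi (first residue) and
#' `NA` psi (last residue); residues missing any of N, CA, C are skipped
#' with a warning.
#'
#' @param coords Coordinate data frame (see [read_coords()]).
#' @return Data frame with `chain`, `resno`, `resname`, `phi`, `psi`.
#' @export
backbone_dihedrals <- function(coords) {
  stopifnot(all(c("chain", "resno", "atom", "x", "y", "z") %in%
                  names(coords)))
  out <- lapply(split(coords, coords$chain), .chain_dihedrals)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.chain_dihedrals <- function(df) {
  resnos <- sort(unique(df$resno))
  get <- function(rn, at) {
    r <- df[df$resno == rn & df$atom == at, c("x", "y", "z")]
    if (nrow(r) != 1L) return(NULL)
    as.numeric(r)
  }
  ok <- vapply(resnos, function(rn) {
    !is.null(get(rn, "N")) && !is.null(get(rn, "CA")) &&
      !is.null(get(rn, "C"))
  }, logical(1))
  if (any(!ok)) {
    warning(sprintf("skipping %d residue(s) with missing backbone atoms",
                    sum(!ok)), call. = FALSE)
    resnos <- resnos[ok]
  }
  n <- length(resnos)
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    rn <- resnos[i]
    if (i > 1L && resnos[i - 1L] == rn - 1L) {
      phi[i] <- dihedral_angle(get(rn - 1L, "C"), get(rn, "N"),
                               get(rn, "CA"), get(rn, "C"))
    }
    if (i < n && resnos[i + 1L] == rn + 1L) {
      psi[i] <- dihedral_angle(get(rn, "N"), get(rn, "CA"),
                               get(rn, "C"), get(rn + 1L, "N"))
    }
  }
  resname <- vapply(resnos, function(rn) {
    df$resname[df$resno == rn][1]
  }, character(1))
  data.frame(chain = df$chain[1], resno = resnos, resname = resname,
             phi = phi, psi = psi, stringsAsFactors = FALSE)
}

#' Coarse Ramachandran favored-region boxes
#'
#' Rectangular phi/psi boxes covering the right-handed alpha-helical,
#' beta/extended (including the psi wrap-around near -180) and
#' left-handed alpha regions. Deliberately coarse: a documented map for
#' favored-fraction QC, not a PROCHECK-calibrated density.
#'
#' @return Data frame with `region`, `phi_min`, `phi_max`, `psi_min`,
#'   `psi_max` (degrees).
#' @export
ramachandran_regions <- function() {
  data.frame(
    region  = c("alpha", "beta", "beta_wrap", "alpha_L"),
    phi_min = c(-160, -180, -180, 30),
    phi_max = c(-30, -45, -45, 90),
    psi_min = c(-90, 90, -180, -20),
    psi_max = c(45, 180, -150, 80),
    stringsAsFactors = FALSE
  )
}

#' Fraction of residues in favored Ramachandran regions
#'
#' Percent of residues with both phi and psi defined that fall inside any
#' favored-region box; undefined terminal dihedrals are excluded from the
#' denominator.
#'
#' @param dihedrals Data frame from [backbone_dihedrals()] (columns
#'   `phi`, `psi`).
#' @param regions Region boxes (default [ramachandran_regions()]).
#' @return Percentage in `[0, 100]`.
#' @export
favored_fraction <- function(dihedrals, regions = ramachandran_regions()) {
  def <- stats::complete.cases(dihedrals[, c("phi", "psi")])
  if (!any(def)) stop("no residues with defined phi and psi",
                      call. = FALSE)
  phi <- dihedrals$phi[def]; psi <- dihedrals$psi[def]
  inside <- rep(FALSE, length(phi))
  for (k in seq_len(nrow(regions))) {
    inside <- inside |
      (phi >= regions$phi_min[k] & phi <= regions$phi_max[k] &
         psi >= regions$psi_min[k] & psi <= regions$psi_max[k])
  }
  100 * mean(inside)
}
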