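# Superposition-based ensemble statistics and restraint bookkeeping.

#' Parse a residue selection
#'
#' Selections use the compact notation `"A:173-186,190-194,197 B:10-20"`:
#' per-chain comma-separated residue ranges, chains separated by whitespace.
#' Alternatively pass a data.frame with columns `chain_id`, `res_num`.
#'
#' @param spec selection string or data.frame.
#' @param atom_set one of `"backbone"` (N, CA, C, O), `"heavy"` (non-H),
#'   `"CA"`, `"all"`.
#' @return List of class `residue_selection`.
#' @export
residue_selection <- function(spec, atom_set = c("backbone", "heavy", "CA", "all")) {
  atom_set <- match.arg(atom_set)
  if (is.character(spec)) {
    parts <- strsplit(trimws(spec), "\\s+")[[1]]
    rows <- do.call(rbind, lapply(parts, function(p) {
      bits <- strsplit(p, ":", fixed = TRUE)[[1]]
      if (length(bits) != 2L) stop("bad selection term: ", p)
      ranges <- strsplit(bits[2], ",", fixed = TRUE)[[1]]
      res <- unlist(lapply(ranges, function(r) {
        ab <- as.integer(strsplit(r, "-", fixed = TRUE)[[1]])
        if (length(ab) == 1L) ab else seq(ab[1], ab[2])
      }))
      data.frame(chain_id = bits[1], res_num = res, stringsAsFactors = FALSE)
    }))
  } else {
    rows <- as.data.frame(spec)
    stopifnot(all(c("chain_id", "res_num") %in% names(rows)))
  }
  if (!nrow(rows)) stop("empty selection")
  structure(list(residues = rows, atom_set = atom_set), class = "residue_selection")
}

# indices of atoms matched by a residue_selection in an atoms data.frame
select_atoms <- function(atoms, sel) {
  stopifnot(inherits(sel, "residue_selection"))
  in_res <- paste(atoms$chain_id, atoms$res_num) %in%
    paste(sel$residues$chain_id, sel$residues$res_num)
  keep <- switch(sel$atom_set,
    backbone = atoms$name %in% c("N", "CA", "C", "O"),
    heavy    = toupper(atoms$element) != "H",
    CA       = atoms$name == "CA",
    all      = rep(TRUE, nrow(atoms)))
  idx <- which(in_res & keep)
  if (!length(idx)) stop("selection matches no atoms (atom_set = ", sel$atom_set, ")")
  idx
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation (det = +1) and translation minimising the RMSD
#' of `mobile` onto `reference`, via SVD of the covariance of the centred
#' point sets.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3.
#' @return List with `rotation` (3 x 3), `translation` (length 3; the fitted
#'   mobile is `mobile %*% rotation + translation`), `rmsd` (post-fit, in the
#'   coordinate units), and `fitted` coordinates.
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3L || ncol(reference) != 3L)
    stop("coordinate sets must be equal-sized n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  X <- sweep(mobile, 2, cm); Y <- sweep(reference, 2, cr)
  if (qr(X)$rank < 2L || qr(Y)$rank < 2L) stop("degenerate (collinear) point set")
  s <- svd(crossprod(X, Y))                 # X^T Y = U D V^T
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)  # proper rotation
  fitted <- X %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  list(rotation = R, translation = as.numeric(cr - cm %*% R),
       rmsd = rmsd, fitted = sweep(fitted, 2, cr, `+`))
}

#' Pairwise RMSD over an ensemble
#'
#' Every model pair is superposed on the selection's atoms and the RMSD
#' evaluated on the same atoms (self-consistent fit/evaluation).  Mean and
#' standard deviation are taken over the strict upper triangle of the pair
#' matrix, with denominator `n_pairs - 1` for the sd.
#'
#' @param ens an `ensemble`.
#' @param selection a [residue_selection()].
#' @return List of class `rmsd_report`: `mean`, `sd` (Angstrom) and the
#'   symmetric `pair_matrix`.
#' @export
pairwise_rmsd <- function(ens, selection) {
  stopifnot(inherits(ens, "ensemble"))
  idx <- select_atoms(ens$atoms, selection)
  m <- n_models(ens)
  pm <- matrix(0, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    pm[i, j] <- pm[j, i] <-
      superpose(ens$xyz[idx, , i], ens$xyz[idx, , j])$rmsd
  }
  vals <- pm[upper.tri(pm)]
  structure(list(mean = mean(vals), sd = stats::sd(vals), pair_matrix = pm,
                 n_atoms = length(idx)),
            class = "rmsd_report")
}

#' @export
print.rmsd_report <- function(x, ...) {
  cat(sprintf("Pairwise RMSD: %.2f +/- %.2f A over %d pairs (%d atoms)\n",
              x$mean, x$sd, sum(upper.tri(x$pair_matrix)), x$n_atoms))
  invisible(x)
}

#' Per-residue root-mean-square fluctuation
#'
#' Models are iteratively superposed (on the selection's atoms) onto the
#' weighted mean structure until the mean structure moves less than `tol`;
#' the RMSF of a residue is the square root of the weighted mean squared
#' deviation of its selected atoms from the converged mean structure.
#'
#' @param ens an `ensemble` (a trajectory).
#' @param selection a [residue_selection()].
#' @param weights optional per-model weights (non-negative, sum 1); default
#'   uniform.
#' @param tol convergence threshold on the mean-structure shift, Angstrom.
#' @return Named numeric vector: RMSF (Angstrom) per selected residue, names
#'   `chain:res`.
#' @export
rmsf <- function(ens, selection, weights = NULL, tol = 1e-4) {
  stopifnot(inherits(ens, "ensemble"))
  idx <- select_atoms(ens$atoms, selection)
  m <- n_models(ens)
  if (is.null(weights)) weights <- rep(1 / m, m)
  if (length(weights) != m || any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be non-negative, one per model, summing to 1")
  if (m == 1L) {
    warning("single-model ensemble: RMSF is zero everywhere")
  }
  coords <- lapply(seq_len(m), function(k) ens$xyz[idx, , k, drop = TRUE])
  wmean <- function(cs) Reduce(`+`, Map(function(c, w) c * w, cs, weights))
  mean_str <- wmean(coords)
  repeat {
    coords <- lapply(coords, function(c) superpose(c, mean_str)$fitted)
    new_mean <- wmean(coords)
    shift <- sqrt(mean(rowSums((new_mean - mean_str)^2)))
    mean_str <- new_mean
    if (shift < tol || m == 1L) break
  }
  sqdev <- Reduce(`+`, Map(function(c, w) w * rowSums((c - mean_str)^2), coords, weights))
  rkey <- paste(ens$atoms$chain_id[idx], ens$atoms$res_num[idx], sep = ":")
  res_ms <- tapply(sqdev, factor(rkey, levels = unique(rkey)), mean)
  sqrt(res_ms)[unique(rkey)]
}

#' Classify NOE distance restraints by sequence separation
#'
#' Counts: `total`, `intra` (i = j), `inter` (i != j), `sequential`
#' (|i - j| = 1), `medium` (2 <= |i - j| <= 4), `long` (|i - j| >= 5), and
#' `intermolecular` (different chains; also included in the |i - j| classes
#' of its residue indices).  intra + sequential + medium + long = total.
#'
#' @param table a `restraint_table` from [read_restraints()].
#' @return Named integer vector of counts.
#' @export
classify_restraints <- function(table) {
  stopifnot(inherits(table, "restraint_table"))
  d <- table$distance
  sep <- abs(d$res_i - d$res_j)
  c(total = nrow(d),
    intra = sum(sep == 0),
    inter = sum(sep != 0),
    sequential = sum(sep == 1),
    medium = sum(sep >= 2 & sep <= 4),
    long = sum(sep >= 5),
    intermolecular = sum(d$chain_i != d$chain_j))
}

#' Restraint violation statistics over an ensemble
#'
#' For each model and distance restraint, the violation is
#' `max(0, d - upper, lower - d)` where `d` is the model's atom-pair
#' distance.  Mean and sd are computed either over all restraint-model pairs
#' (`violated_only = FALSE`) or over the violated ones only; `max` is the
#' single largest violation.
#'
#' @param ens an `ensemble`.
#' @param table a `restraint_table`.
#' @param violated_only restrict mean/sd to violated restraint-model pairs.
#' @return Named numeric vector `mean`, `sd`, `max` (Angstrom) plus
#'   `n_violated`.
#' @export
restraint_violations <- function(ens, table, violated_only = FALSE) {
  stopifnot(inherits(ens, "ensemble"), inherits(table, "restraint_table"))
  d <- table$distance
  if (!nrow(d)) return(c(mean = 0, sd = 0, max = 0, n_violated = 0))
  akey <- paste(ens$atoms$chain_id, ens$atoms$res_num, ens$atoms$name)
  ai <- match(paste(d$chain_i, d$res_i, d$atom_i), akey)
  aj <- match(paste(d$chain_j, d$res_j, d$atom_j), akey)
  if (anyNA(ai) || anyNA(aj)) {
    bad <- which(is.na(ai) | is.na(aj))[1]
    miss <- if (is.na(ai[bad])) paste(d$chain_i[bad], d$res_i[bad], d$atom_i[bad])
            else paste(d$chain_j[bad], d$res_j[bad], d$atom_j[bad])
    stop("restraint atom not found in structure: ", miss)
  }
  viol <- sapply(seq_len(n_models(ens)), function(k) {
    dist <- sqrt(rowSums((ens$xyz[ai, , k, drop = FALSE] -
                          ens$xyz[aj, , k, drop = FALSE])^2))
    pmax(0, dist - d$upper, d$lower - dist)
  })
  v <- as.numeric(viol)
  pool <- if (violated_only) v[v > 0] else v
  if (!length(pool)) pool <- 0
  c(mean = mean(pool), sd = if (length(pool) > 1) stats::sd(pool) else 0,
    max = max(v), n_violated = sum(v > 0))
}
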