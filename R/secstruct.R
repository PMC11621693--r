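# Backbone dihedrals, dihedral-region secondary-structure assignment,
# ensemble propensities (optionally reweighted) and the chemical shift index.

#' Random-coil Halpha chemical shifts (ppm)
#'
#' Standard published random-coil Halpha reference shifts per residue type
#' (referenced to DSS), used as the default for [csi_classify()].
#'
#' @format Named numeric vector, one-letter residue codes.
#' @export
RANDOM_COIL_HA <- c(A = 4.35, C = 4.65, D = 4.76, E = 4.29, F = 4.66,
                    G = 3.97, H = 4.63, I = 3.95, K = 4.36, L = 4.17,
                    M = 4.52, N = 4.75, P = 4.44, Q = 4.37, R = 4.38,
                    S = 4.50, T = 4.35, V = 3.95, W = 4.70, Y = 4.60)

crossv <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                           u[3] * v[1] - u[1] * v[3],
                           u[1] * v[2] - u[2] * v[1])

# dihedral about b-c for points a-b-c-d, degrees in (-180, 180];
# IUPAC sign convention (cis = 0, clockwise positive looking b -> c)
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- crossv(b1, b2)
  n2 <- crossv(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(crossv(n1, n2) * b2) / sqrt(sum(b2^2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone phi/psi dihedrals of a structure model
#'
#' Standard torsions: phi about N-CA from C(i-1)-N-CA-C, psi about CA-C from
#' N-CA-C-N(i+1).  Terminal or incomplete residues get `NA` (flagged, not an
#' error).  Residues are taken per chain in file order.
#'
#' @param model a [structure_model()] with backbone N, CA, C atoms.
#' @return data.frame: `chain_id`, `res_num`, `res_name`, `phi`, `psi`
#'   (degrees in (-180, 180]).
#' @export
backbone_dihedrals <- function(model) {
  at <- model$atoms
  out <- list()
  for (ch in unique(at$chain_id)) {
    rows <- which(at$chain_id == ch)
    resf <- unique(at$res_index[rows])
    get_atom <- function(res, name) {
      i <- rows[at$res_index[rows] == res & at$name[rows] == name]
      if (length(i) != 1L) return(NULL)
      model$xyz[i, ]
    }
    nres <- length(resf)
    phi <- psi <- rep(NA_real_, nres)
    for (r in seq_len(nres)) {
      N <- get_atom(resf[r], "N"); CA <- get_atom(resf[r], "CA")
      C <- get_atom(resf[r], "C")
      if (r > 1) {
        Cm <- get_atom(resf[r - 1], "C")
        if (!is.null(Cm) && !is.null(N) && !is.null(CA) && !is.null(C))
          phi[r] <- dihedral_angle(Cm, N, CA, C)
      }
      if (r < nres) {
        Np <- get_atom(resf[r + 1], "N")
        if (!is.null(N) && !is.null(CA) && !is.null(C) && !is.null(Np))
          psi[r] <- dihedral_angle(N, CA, C, Np)
      }
    }
    idx1 <- rows[match(resf, at$res_index[rows])]
    out[[ch]] <- data.frame(chain_id = ch, res_num = at$res_num[idx1],
                            res_name = at$res_name[idx1],
                            phi = phi, psi = psi, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Dihedral-region secondary-structure assignment
#'
#' Assigns per residue: `H` (helix) if phi in `helix_phi` and psi in
#' `helix_psi`; `E` (extended) if phi in `strand_phi` and psi in either
#' strand psi region; otherwise `C` (coil).  Residues with undefined
#' dihedrals (termini) are `C`.
#'
#' @param model a [structure_model()], or a data.frame from
#'   [backbone_dihedrals()].
#' @param helix_phi,helix_psi,strand_phi,strand_psi,strand_psi2 numeric
#'   `c(low, high)` region bounds in degrees.
#' @return Character string, one letter per residue (chains concatenated in
#'   file order).
#' @export
assign_secondary_structure <- function(model,
                                       helix_phi = c(-100, -30),
                                       helix_psi = c(-80, -5),
                                       strand_phi = c(-180, -90),
                                       strand_psi = c(90, 180),
                                       strand_psi2 = c(-180, -150)) {
  tab <- if (is.data.frame(model)) model else backbone_dihedrals(model)
  inreg <- function(x, r) !is.na(x) & x >= r[1] & x <= r[2]
  lab <- rep("C", nrow(tab))
  lab[inreg(tab$phi, strand_phi) &
        (inreg(tab$psi, strand_psi) | inreg(tab$psi, strand_psi2))] <- "E"
  lab[inreg(tab$phi, helix_phi) & inreg(tab$psi, helix_psi)] <- "H"
  paste(lab, collapse = "")
}

#' Secondary-structure propensity over a trajectory
#'
#' Weighted fraction of frames in which each residue is H, E or C.  With
#' weights from [unbias_weights()] this is the reweighted observable that
#' corrects the bias of density-guided adaptive sampling.
#'
#' @param ens an `ensemble` (trajectory) with full backbone atoms.
#' @param weights optional per-frame weights (non-negative, sum 1).
#' @return List of class `ss_propensity`: `fractions` (residues x 3 matrix,
#'   columns H/E/C, rows summing to 1) and `frames` (per-frame label
#'   strings).
#' @export
ss_propensity <- function(ens, weights = NULL) {
  stopifnot(inherits(ens, "ensemble"))
  m <- n_models(ens)
  if (is.null(weights)) weights <- rep(1 / m, m)
  if (length(weights) != m || abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1, one per frame")
  labs <- vapply(seq_len(m), function(k)
    assign_secondary_structure(get_model(ens, k)), character(1))
  mat <- do.call(rbind, strsplit(labs, ""))      # frames x residues
  frac <- sapply(c("H", "E", "C"), function(s)
    colSums((mat == s) * weights))
  frac <- matrix(frac, ncol = 3, dimnames = list(NULL, c("H", "E", "C")))
  structure(list(fractions = frac, frames = labs), class = "ss_propensity")
}

#' Chemical-shift-index classification from Halpha shifts
#'
#' The secondary shift is observed minus random coil.  State is -1 where the
#' secondary shift is below `-threshold` ppm, +1 above `+threshold`, else 0;
#' missing shifts give state 0 and are flagged.  A helix segment is a run of
#' at least 4 consecutive -1 states; a strand segment a run of at least 3
#' consecutive +1 states.
#'
#' @param ha_shifts named numeric vector of observed Halpha shifts (ppm),
#'   names = residue index.
#' @param residue_types named character vector of one-letter residue types,
#'   same names.
#' @param rc_table per-type random-coil reference shifts; default
#'   [RANDOM_COIL_HA].
#' @param threshold secondary-shift threshold, ppm.
#' @return List of class `csi_result`: `states` (-1/0/+1 per residue),
#'   `delta` (secondary shifts), `missing` (residues with no shift),
#'   `segments` (data.frame type/start/end).
#' @export
csi_classify <- function(ha_shifts, residue_types, rc_table = RANDOM_COIL_HA,
                         threshold = 0.1) {
  res <- names(residue_types)
  if (is.null(res)) res <- as.character(seq_along(residue_types))
  rc <- rc_table[residue_types]
  if (anyNA(rc)) stop("random-coil reference missing for residue type(s): ",
                      paste(unique(residue_types[is.na(rc)]), collapse = ", "))
  obs <- ha_shifts[res]
  delta <- as.numeric(obs) - as.numeric(rc)
  miss <- is.na(delta)
  states <- integer(length(delta))
  states[!miss & delta < -threshold] <- -1L
  states[!miss & delta > threshold] <- 1L
  segs <- list()
  r <- rle(states)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] == -1L && r$lengths[k] >= 4L)
      segs[[length(segs) + 1L]] <- data.frame(type = "helix",
                                              start = res[starts[k]], end = res[ends[k]])
    if (r$values[k] == 1L && r$lengths[k] >= 3L)
      segs[[length(segs) + 1L]] <- data.frame(type = "strand",
                                              start = res[starts[k]], end = res[ends[k]])
  }
  structure(list(states = setNames(states, res), delta = setNames(delta, res),
                 missing = res[miss],
                 segments = if (length(segs)) do.call(rbind, segs)
                            else data.frame(type = character(), start = character(),
                                            end = character())),
            class = "csi_result")
}

#' Build an ideal-geometry backbone helix or strand fixture
#'
#' Constructs a poly-alanine chain with N, CA, C atoms from exact target
#' (phi, psi) torsions using standard bond lengths and angles — the
#' geometric inverse of [backbone_dihedrals()], used for testing and as a
#' template for dihedral-based analyses.
#'
#' @param n_res number of residues.
#' @param phi,psi target torsions, degrees (default ideal alpha helix).
#' @param chain_id chain identifier.
#' @return A [structure_model()] with N/CA/C per residue.
#' @export
build_backbone_from_dihedrals <- function(n_res, phi = -57, psi = -47,
                                          chain_id = "A") {
  # bond lengths (A) and angles (deg): N-CA 1.458, CA-C 1.525, C-N 1.329;
  # N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7; omega fixed at 180.
  phi <- rep_len(phi, n_res); psi <- rep_len(psi, n_res)
  place <- function(a, b, c, bond, angle, torsion) {
    # position d with |c-d| = bond, angle b-c-d, torsion a-b-c-d
    ang <- angle * pi / 180; tor <- torsion * pi / 180
    bc <- c - b; bc <- bc / sqrt(sum(bc^2))
    ab <- b - a
    n <- crossv(ab, bc); n <- n / sqrt(sum(n^2))
    m <- crossv(n, bc)
    d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
    c + d2[1] * bc + d2[2] * m + d2[3] * n
  }
  coords <- matrix(NA_real_, 3 * n_res, 3)
  coords[1, ] <- c(0, 0, 0)                       # N1
  coords[2, ] <- c(1.458, 0, 0)                   # CA1
  coords[3, ] <- place(c(-1, 1, 0), coords[1, ], coords[2, ], 1.525, 111.2, phi[1])
  for (r in 2:n_res) {
    i <- 3 * (r - 1)
    coords[i + 1, ] <- place(coords[i - 2, ], coords[i - 1, ], coords[i, ],
                             1.329, 116.2, psi[r - 1])            # N(r)
    coords[i + 2, ] <- place(coords[i - 1, ], coords[i, ], coords[i + 1, ],
                             1.458, 121.7, 180)                   # CA(r), omega
    coords[i + 3, ] <- place(coords[i, ], coords[i + 1, ], coords[i + 2, ],
                             1.525, 111.2, phi[r])                # C(r)
  }
  atoms <- data.frame(name = rep(c("N", "CA", "C"), n_res),
                      element = rep(c("N", "C", "C"), n_res),
                      chain_id = chain_id,
                      res_index = as.character(rep(seq_len(n_res), each = 3)),
                      res_num = rep(seq_len(n_res), each = 3),
                      res_name = "ALA", stringsAsFactors = FALSE)
  structure_model(atoms, coords)
}
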