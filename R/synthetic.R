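# Synthetic inputs with known ground truth: parametric coiled-coil dimers,
# Gaussian-perturbed ensembles, planted symmetric motif families, and
# two-state Gaussian clouds for the adaptive-sampling tests.

HYDROPHOBIC_SET <- c("A", "C", "F", "I", "L", "M", "V", "W", "Y")
POLAR_SET <- c("D", "E", "G", "H", "K", "N", "P", "Q", "R", "S", "T")
AA20 <- c(HYDROPHOBIC_SET, POLAR_SET)
AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
         H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
         P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
         W = "TRP", Y = "TYR")

#' Geometry parameters for a synthetic coiled-coil dimer
#'
#' Defaults follow canonical left-handed two-stranded coiled-coil geometry:
#' helix axes at `superhelix_radius` (Angstrom) from the common superhelical
#' axis, a minor helix of radius `helix_radius` with `residues_per_turn`
#' residues per turn, and an axial `rise_per_res` per residue.
#'
#' @param n_res residues per helix (>= 7).
#' @param superhelix_radius,helix_radius radii in Angstrom (> 0).
#' @param rise_per_res axial rise per residue, Angstrom.
#' @param residues_per_turn minor-helix periodicity.
#' @param antiparallel build chain B running opposite to chain A.
#' @param zipper_offsets signed residue offsets from the helix centre that
#'   carry hydrophobic (Leu) residues with inward-pointing side chains.
#' @param superhelix_pitch axial length of one superhelical turn, Angstrom;
#'   sets the slight left-handed winding of the helix axes.
#' @return List of class `coil_params`.
#' @export
coil_params <- function(n_res = 56L, superhelix_radius = 4.9, helix_radius = 2.26,
                        rise_per_res = 1.51, residues_per_turn = 3.62,
                        antiparallel = TRUE, zipper_offsets = c(-14, -7, 0, 7, 14),
                        superhelix_pitch = 150) {
  stopifnot(n_res >= 7L, superhelix_radius > 0, helix_radius > 0,
            rise_per_res > 0, residues_per_turn > 1, superhelix_pitch > 0)
  structure(list(n_res = as.integer(n_res), superhelix_radius = superhelix_radius,
                 helix_radius = helix_radius, rise_per_res = rise_per_res,
                 residues_per_turn = residues_per_turn, antiparallel = antiparallel,
                 zipper_offsets = as.integer(zipper_offsets),
                 superhelix_pitch = superhelix_pitch),
            class = "coil_params")
}

# Calpha trace of one helix wound about the z axis.  phase0 places the helix
# axis in the xy plane; z runs 0 .. rise*(n-1).  theta is the Calpha phase in
# the local (radial, binormal) frame about the helix axis; the phase is set
# so theta = pi (facing the superhelical axis, hence the partner helix) at
# geometric position center_pos.  Returns Calpha coords, the side-chain
# direction sc_dir (unit vector from the local helix axis through the
# Calpha), and the outward radial unit vector e_r.
crick_helix <- function(p, phase0, center_pos) {
  i <- seq_len(p$n_res) - 1
  w0 <- 2 * pi * p$rise_per_res / p$superhelix_pitch   # superhelical phase/res
  w1 <- 2 * pi / p$residues_per_turn                   # minor-helix phase/res
  phi <- phase0 - w0 * i                               # left-handed supercoil
  ax <- cbind(p$superhelix_radius * cos(phi),
              p$superhelix_radius * sin(phi),
              p$rise_per_res * i)
  # local frame: e_t axis tangent, e_r outward radial, e_b = e_t x e_r
  e_r <- cbind(cos(phi), sin(phi), 0)
  d_ax <- cbind(p$superhelix_radius * w0 * sin(phi),
                -p$superhelix_radius * w0 * cos(phi),
                rep(p$rise_per_res, length(i)))
  e_t <- d_ax / sqrt(rowSums(d_ax^2))
  e_b <- cbind(e_t[, 2] * e_r[, 3] - e_t[, 3] * e_r[, 2],
               e_t[, 3] * e_r[, 1] - e_t[, 1] * e_r[, 3],
               e_t[, 1] * e_r[, 2] - e_t[, 2] * e_r[, 1])
  # phase chosen so the centre residue faces the superhelical axis (theta=pi)
  theta <- pi + w1 * (i - (center_pos - 1))
  sc_dir <- cos(theta) * e_r + sin(theta) * e_b
  ca <- ax + p$helix_radius * sc_dir
  list(ca = ca, sc_dir = sc_dir, e_r = e_r, axis = ax)
}

#' Build a synthetic two-chain coiled-coil dimer
#'
#' Calpha-trace dimer (chains A and B) with one CB pseudo side-chain atom per
#' residue, 1.53 Angstrom from the Calpha.  Residues at `zipper_offsets` from
#' the helix centre are Leu with the CB pointing toward the partner helix
#' (into the interface); all other residues are polar with the CB rotated
#' outward.  With `antiparallel = TRUE` chain B residue indices descend along
#' the axis so that offset +k of A faces offset -k of B.
#'
#' @param params a [coil_params()] object.
#' @return A [structure_model()] with chains `A` and `B`.
#' @export
build_coiled_coil_dimer <- function(params = coil_params()) {
  stopifnot(inherits(params, "coil_params"))
  p <- params
  center <- (p$n_res + 1L) %/% 2L
  zip_idx <- center + p$zipper_offsets
  if (any(zip_idx < 1L | zip_idx > p$n_res)) stop("zipper offsets out of range")
  # geometric position runs 1..n_res along +z; residue index per position:
  # ascending for chain A, descending for chain B when antiparallel.  The
  # helix phase is centred where the centre residue index sits geometrically.
  hA <- crick_helix(p, phase0 = 0, center_pos = center)
  hB <- crick_helix(p, phase0 = pi,
                    center_pos = if (p$antiparallel) p$n_res + 1L - center else center)
  build_chain <- function(h, chain, res_index_by_pos) {
    n <- p$n_res
    zip <- res_index_by_pos %in% zip_idx       # per geometric position
    resn <- ifelse(zip, "LEU",
                   AA3[POLAR_SET[(res_index_by_pos %% length(POLAR_SET)) + 1L]])
    # zipper side chains continue outward from the local helix axis (facing
    # the partner near the interface); others point away from the dimer axis
    cb_dir <- h$sc_dir
    cb_dir[!zip, ] <- h$e_r[!zip, ]
    cb <- h$ca + 1.53 * cb_dir
    xyz <- matrix(NA_real_, 2 * n, 3)
    xyz[seq(1, 2 * n, 2), ] <- h$ca
    xyz[seq(2, 2 * n, 2), ] <- cb
    atoms <- data.frame(
      name = rep(c("CA", "CB"), n),
      element = "C",
      chain_id = chain,
      res_index = as.character(rep(res_index_by_pos, each = 2)),
      res_num = rep(res_index_by_pos, each = 2),
      res_name = rep(resn, each = 2),
      stringsAsFactors = FALSE)
    list(atoms = atoms, xyz = xyz)
  }
  idx <- seq_len(p$n_res)
  a <- build_chain(hA, "A", idx)
  b <- build_chain(hB, "B", if (p$antiparallel) rev(idx) else idx)
  structure_model(rbind(a$atoms, b$atoms), rbind(a$xyz, b$xyz))
}

#' Perturb a structure into a synthetic ensemble
#'
#' Each model is the base structure plus i.i.d. Gaussian displacement per
#' atom and coordinate.  The per-residue `amplitude_profile` is the target
#' RMSF in Angstrom, so the per-coordinate standard deviation is
#' amplitude / sqrt(3).
#'
#' @param base a [structure_model()].
#' @param amplitude_profile non-negative numeric, one value per residue (in
#'   order of first appearance of `(chain_id, res_index)` in `base`).
#' @param n_models number of models to generate.
#' @param seed RNG seed (deterministic output).
#' @return An [as_ensemble()] object of `n_models` models.
#' @export
perturb_ensemble <- function(base, amplitude_profile, n_models = 10L, seed = 1L) {
  stopifnot(inherits(base, "structure_model"), all(amplitude_profile >= 0))
  rkey <- paste(base$atoms$chain_id, base$atoms$res_index)
  resid <- match(rkey, unique(rkey))
  if (length(amplitude_profile) != max(resid))
    stop("amplitude profile length ", length(amplitude_profile),
         " != residue count ", max(resid))
  sd_atom <- amplitude_profile[resid] / sqrt(3)
  natom <- nrow(base$xyz)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  models <- lapply(seq_len(n_models), function(k) {
    disp <- matrix(rnorm(natom * 3, sd = rep(sd_atom, 3)), natom, 3)
    structure_model(base$atoms, base$xyz + disp, model_id = k)
  })
  as_ensemble(models)
}

#' Specification of a planted symmetric motif family
#'
#' @param n_homologs number of homolog sequences.
#' @param length sequence length.
#' @param center_positions centre residue position per homolog (recycled).
#' @param planted_offsets signed offsets from the centre carrying hydrophobic
#'   residues; must be symmetric about 0 (0 itself is always planted).
#' @param hydrophobic_alphabet residues considered hydrophobic.
#' @param substitution_noise per-position probability of replacement by a
#'   uniformly random amino acid, in `[0, 1)`.
#' @param seed RNG seed.
#' @return List of class `motif_family_spec`.
#' @export
motif_family_spec <- function(n_homologs = 19L, length = 160L,
                              center_positions = 80L,
                              planted_offsets = c(-72, -31, -12, 0, 12, 31, 72),
                              hydrophobic_alphabet = HYDROPHOBIC_SET,
                              substitution_noise = 0, seed = 1L) {
  off <- sort(unique(c(0L, as.integer(planted_offsets))))
  if (!setequal(off, -off)) stop("planted offsets must be symmetric about 0")
  stopifnot(substitution_noise >= 0, substitution_noise < 1)
  structure(list(n_homologs = as.integer(n_homologs), length = as.integer(length),
                 center_positions = rep_len(as.integer(center_positions), n_homologs),
                 planted_offsets = off, hydrophobic_alphabet = hydrophobic_alphabet,
                 substitution_noise = substitution_noise, seed = as.integer(seed)),
            class = "motif_family_spec")
}

#' Generate a homolog family with a planted symmetric hydrophobic motif
#'
#' Hydrophobic residues (drawn from the family's hydrophobic alphabet) are planted at the
#' centre and at each planted offset; all other positions are drawn from the
#' non-hydrophobic residues.  Each position is then independently replaced by
#' a uniformly random amino acid with probability `substitution_noise`.
#'
#' @param spec a [motif_family_spec()].
#' @return List with `sequences` (named character vector) and `centers`
#'   (named integer vector of centre positions).
#' @export
generate_motif_family <- function(spec = motif_family_spec()) {
  stopifnot(inherits(spec, "motif_family_spec"))
  pos <- outer(spec$center_positions, spec$planted_offsets, `+`)
  if (any(pos < 1L | pos > spec$length)) stop("planted offsets out of range")
  polar <- setdiff(AA20, spec$hydrophobic_alphabet)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)
  seqs <- character(spec$n_homologs)
  for (h in seq_len(spec$n_homologs)) {
    s <- sample(polar, spec$length, replace = TRUE)
    s[pos[h, ]] <- sample(spec$hydrophobic_alphabet, length(spec$planted_offsets),
                          replace = TRUE)
    hit <- runif(spec$length) < spec$substitution_noise
    s[hit] <- sample(AA20, sum(hit), replace = TRUE)
    seqs[h] <- paste(s, collapse = "")
  }
  ids <- sprintf("hom%02d", seq_len(spec$n_homologs))
  list(sequences = setNames(seqs, ids),
       centers = setNames(spec$center_positions, ids))
}

#' Simulate a low-dimensional two-state (Gaussian mixture) cloud
#'
#' Stand-in for a conformational landscape with a major and a minor state,
#' used to exercise the adaptive-sampling seed selection and reweighting.
#'
#' @param n number of points.
#' @param dims dimensionality.
#' @param weights mixture weights (must sum to 1).
#' @param means matrix of component means (one row per component).
#' @param sigmas isotropic standard deviation per component.
#' @param seed RNG seed.
#' @return List with `points` (n x dims matrix) and `labels` (component
#'   index per point).
#' @export
simulate_two_state_cloud <- function(n = 10000L, dims = 2L,
                                     weights = c(0.9, 0.1),
                                     means = rbind(rep(0, dims),
                                                   c(4, rep(0, dims - 1))),
                                     sigmas = c(1, 1), seed = 1L) {
  means <- as.matrix(means)
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (ncol(means) != dims) stop("dimension mismatch: means have ", ncol(means),
                                " columns, dims = ", dims)
  if (nrow(means) != length(weights) || length(sigmas) != length(weights))
    stop("weights, means and sigmas must describe the same components")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  labels <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  pts <- means[labels, , drop = FALSE] +
    matrix(rnorm(n * dims), n, dims) * sigmas[labels]
  list(points = unname(pts), labels = labels)
}
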