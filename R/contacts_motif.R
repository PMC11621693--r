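# Intermolecular contact quantification, center-anchored homolog alignment,
# cumulative contact profiles and symmetric motif extraction.

# atom-mode pairings between two chains:
#   all_heavy              all non-hydrogen atoms on both sides
#   ca_vs_all              Calpha of the first chain vs all atoms of the other
#   ca_vs_sidechain_carbon Calpha of the first chain vs carbon atoms outside
#                          the backbone (side-chain carbons incl. CB)
atom_mode_rows <- function(atoms, chain, role, mode) {
  in_chain <- atoms$chain_id == chain
  pick <- switch(mode,
    all_heavy = toupper(atoms$element) != "H",
    ca_vs_all = if (role == "first") atoms$name == "CA"
                else rep(TRUE, nrow(atoms)),
    ca_vs_sidechain_carbon = if (role == "first") atoms$name == "CA"
                else toupper(atoms$element) == "C" & !atoms$name %in% c("C", "CA"),
    stop("unknown atom_mode: ", mode))
  which(in_chain & pick)
}

pair_dist <- function(xa, xb) {
  # |a - b| for all pairs: rows of xa vs rows of xb
  sqrt(outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * tcrossprod(xa, xb))
}

#' Intermolecular contact counts per residue
#'
#' Counts atom pairs across two chains strictly closer than `cutoff`
#' Angstrom.  The count of residue r in chain A is the number of qualifying
#' pairs with the A-side atom in r, and symmetrically for chain B (for the
#' asymmetric atom modes the roles are swapped when counting for B, so each
#' chain is the "Calpha side" of its own counts).
#'
#' @param model a [structure_model()].
#' @param chainA,chainB chain identifiers.
#' @param cutoff distance cutoff, Angstrom (strict `<`).
#' @param atom_mode `"all_heavy"`, `"ca_vs_all"` or
#'   `"ca_vs_sidechain_carbon"`.
#' @return List with named count vectors `A` and `B` (names are residue
#'   indices), and the metadata `cutoff`, `atom_mode`.
#' @export
contact_counts <- function(model, chainA = "A", chainB = "B", cutoff = 3.0,
                           atom_mode = c("all_heavy", "ca_vs_all",
                                         "ca_vs_sidechain_carbon")) {
  atom_mode <- match.arg(atom_mode)
  at <- model$atoms
  for (ch in c(chainA, chainB))
    if (!any(at$chain_id == ch)) stop("unknown chain: ", ch)
  count_side <- function(first, second) {
    ia <- atom_mode_rows(at, first, "first", atom_mode)
    ib <- atom_mode_rows(at, second, "second", atom_mode)
    dm <- pair_dist(model$xyz[ia, , drop = FALSE], model$xyz[ib, , drop = FALSE])
    hits <- rowSums(dm < cutoff)
    res <- factor(at$res_index[ia], levels = unique(at$res_index[at$chain_id == first]))
    cnt <- tapply(hits, res, sum, default = 0)
    setNames(as.integer(cnt), levels(res))
  }
  list(A = count_side(chainA, chainB), B = count_side(chainB, chainA),
       cutoff = cutoff, atom_mode = atom_mode)
}

#' Minimal inter-residue distance map over a trajectory
#'
#' Cell (i, j) holds the minimum over frames and over the atom-mode pairing
#' of the distance between residue i of `chainA` and residue j of `chainB`.
#' Cells outside `band` are masked (`NA`) in `$map` while the raw minima are
#' retained in `$raw`.
#'
#' @param ens an `ensemble` (trajectory frames share one topology).
#' @param chainA,chainB chain identifiers.
#' @param atom_mode see [contact_counts()]; default `"ca_vs_all"`.
#' @param band numeric `c(low, high)` in Angstrom, `low < high`.
#' @return List of class `contact_map`: `raw` and `map` matrices (rows =
#'   residues of chainA, cols = residues of chainB), `band`, `atom_mode`.
#' @export
min_distance_map <- function(ens, chainA = "A", chainB = "B",
                             atom_mode = c("ca_vs_all", "all_heavy",
                                           "ca_vs_sidechain_carbon"),
                             band = c(3, 10)) {
  atom_mode <- match.arg(atom_mode)
  stopifnot(inherits(ens, "ensemble"), length(band) == 2L, band[1] < band[2])
  at <- ens$atoms
  ia <- atom_mode_rows(at, chainA, "first", atom_mode)
  ib <- atom_mode_rows(at, chainB, "second", atom_mode)
  resA <- factor(at$res_index[ia], levels = unique(at$res_index[at$chain_id == chainA]))
  resB <- factor(at$res_index[ib], levels = unique(at$res_index[at$chain_id == chainB]))
  nA <- nlevels(resA); nB <- nlevels(resB)
  raw <- matrix(Inf, nA, nB, dimnames = list(levels(resA), levels(resB)))
  gi <- as.integer(resA); gj <- as.integer(resB)
  for (k in seq_len(n_models(ens))) {
    dm <- pair_dist(matrix(ens$xyz[ia, , k], ncol = 3),
                    matrix(ens$xyz[ib, , k], ncol = 3))
    # per residue-pair minimum via grouped reduction
    for (i in seq_len(nA)) {
      rows <- gi == i
      if (!any(rows)) next
      sub <- dm[rows, , drop = FALSE]
      mins <- tapply(apply(sub, 2, min), gj, min)
      raw[i, as.integer(names(mins))] <- pmin(raw[i, as.integer(names(mins))], mins)
    }
  }
  masked <- raw
  masked[raw < band[1] | raw > band[2]] <- NA_real_
  structure(list(raw = raw, map = masked, band = band, atom_mode = atom_mode,
                 mode = "min_distance"),
            class = "contact_map")
}

#' Per-frame distance series for selected atom pairs
#'
#' @param ens an `ensemble` (trajectory).
#' @param pairs list of pairs; each element is a list/character vector of two
#'   atom specs `c(chain, res, atom)`, e.g.
#'   `list(c("A", 137, "CA"), c("B", 137, "CA"))`.
#' @return Matrix frames x pairs of distances (Angstrom), frame order
#'   preserved; column names `chain:res:atom-chain:res:atom`.
#' @export
pair_distance_series <- function(ens, pairs) {
  stopifnot(inherits(ens, "ensemble"))
  akey <- paste(ens$atoms$chain_id, ens$atoms$res_num, ens$atoms$name)
  resolve <- function(spec) {
    i <- match(paste(spec[1], spec[2], spec[3]), akey)
    if (is.na(i)) stop("atom not found: ", paste(spec, collapse = ":"))
    i
  }
  out <- vapply(pairs, function(p) {
    i <- resolve(p[[1]]); j <- resolve(p[[2]])
    sqrt(colSums((ens$xyz[i, , ] - ens$xyz[j, , ])^2))
  }, numeric(n_models(ens)))
  out <- matrix(out, nrow = n_models(ens))
  colnames(out) <- vapply(pairs, function(p)
    paste(paste(p[[1]], collapse = ":"), paste(p[[2]], collapse = ":"), sep = "-"),
    character(1))
  out
}

#' Center-anchored ("inverse") alignment of homologs
#'
#' Homolog correspondence by signed offset from a per-homolog centre residue
#' (the conserved central hydrophobic residue of the zipper), without gaps:
#' offset = res_index - centre.
#'
#' @param sequences named character vector of homolog sequences.
#' @param centers named (or positional) integer vector of centre positions,
#'   1-based, one per sequence.
#' @return List of class `centered_alignment`: per homolog a list with
#'   `id`, `center`, `offsets` (named integer vector res_index -> offset) and
#'   `residues` (one-letter residue per offset).
#' @export
center_alignment <- function(sequences, centers) {
  stopifnot(length(sequences) == length(centers))
  if (!is.null(names(sequences)) && !is.null(names(centers)))
    centers <- centers[names(sequences)]
  homs <- lapply(seq_along(sequences), function(h) {
    s <- strsplit(sequences[[h]], "")[[1]]
    ctr <- as.integer(centers[[h]])
    if (ctr < 1L || ctr > length(s))
      stop("center ", ctr, " outside sequence ", names(sequences)[h])
    idx <- seq_along(s)
    list(id = if (is.null(names(sequences))) as.character(h) else names(sequences)[h],
         center = ctr,
         offsets = setNames(idx - ctr, idx),
         residues = setNames(s, idx - ctr))
  })
  structure(homs, class = "centered_alignment")
}

#' Cumulative contact counts per alignment offset
#'
#' Sums per-residue contact counts over homologs and, by default, over both
#' monomers of each homolog dimer, at each signed offset of the centred
#' alignment.  Homologs lacking an offset contribute 0 there.
#'
#' @param counts list, one element per homolog, each a list of per-monomer
#'   named count vectors (names = residue indices), e.g. the `A`/`B`
#'   elements of [contact_counts()].
#' @param alignment a [center_alignment()] of the same homologs, same order.
#' @param monomer_mode `"both"` (sum the monomers), `"first"`, or `"max"`
#'   (elementwise maximum across monomers).
#' @return Named numeric vector: cumulative count per offset (sorted).
#' @export
cumulate_counts <- function(counts, alignment,
                            monomer_mode = c("both", "first", "max")) {
  monomer_mode <- match.arg(monomer_mode)
  stopifnot(inherits(alignment, "centered_alignment"),
            length(counts) == length(alignment))
  acc <- new.env(parent = emptyenv())
  add <- function(off, val) {
    key <- as.character(off)
    cur <- if (is.null(acc[[key]])) 0 else acc[[key]]
    assign(key, cur + val, envir = acc)
  }
  for (h in seq_along(counts)) {
    mono <- counts[[h]]
    if (!is.list(mono)) mono <- list(mono)
    if (all(c("A", "B") %in% names(mono))) mono <- mono[c("A", "B")]
    use <- switch(monomer_mode,
      both  = mono,
      first = mono[1],
      max   = {
        nm <- names(mono[[1]])
        list(setNames(do.call(pmax, lapply(mono, function(m) m[nm])), nm))
      })
    offs <- alignment[[h]]$offsets
    for (m in use) {
      o <- offs[names(m)]
      if (anyNA(o)) stop("counted residue not mappable to an offset (homolog ", h, ")")
      for (k in seq_along(m)) add(o[k], m[k])
    }
  }
  keys <- as.integer(ls(acc))
  out <- vapply(sort(keys), function(k) acc[[as.character(k)]], numeric(1))
  setNames(out, sort(keys))
}

#' Consensus residue per offset across homologs
#'
#' Majority one-letter residue at each offset of a centred alignment (ties:
#' alphabetical first).
#'
#' @param alignment a [center_alignment()].
#' @return Named character vector, names = offsets.
#' @export
consensus_residues <- function(alignment) {
  stopifnot(inherits(alignment, "centered_alignment"))
  offs <- sort(unique(unlist(lapply(alignment, function(h) unname(h$offsets)))))
  vapply(offs, function(o) {
    res <- unlist(lapply(alignment, function(h) h$residues[as.character(o)]))
    res <- res[!is.na(res)]
    if (!length(res)) return(NA_character_)
    names(sort(table(res), decreasing = TRUE))[1]
  }, character(1)) -> cons
  setNames(cons, offs)
}

#' Extract the symmetric hydrophobic motif from a cumulative profile
#'
#' Offsets whose cumulative count reaches `threshold` and whose consensus
#' residue (if supplied) is hydrophobic become conserved positions.  The
#' pattern string writes `H` at each conserved offset, `Hc` at offset 0, and
#' `Xk` for each run of k unspecified positions between them (so offsets
#' {-12, 0, 12} give `"HX11HcX11H"`).  The symmetry report lists conserved
#' offsets with no conserved counterpart within +/- 1 of their mirror.
#'
#' @param cumulative named numeric vector from [cumulate_counts()] (names =
#'   signed offsets; offset 0 must be present).
#' @param threshold minimum cumulative count (default 35, the convention for
#'   atomic contact counts accumulated over a 19-homolog family).
#' @param consensus optional named character vector of consensus residues per
#'   offset (e.g. [consensus_residues()]); if supplied, conserved offsets
#'   must be hydrophobic by consensus.
#' @param hydrophobic_set residues counted as hydrophobic.
#' @return List of class `motif_pattern`: `offsets` (sorted conserved
#'   offsets, always containing 0), `pattern`, `asymmetric` (offsets without
#'   a mirror partner), `threshold`.
#' @export
extract_symmetric_motif <- function(cumulative, threshold = 35,
                                    consensus = NULL,
                                    hydrophobic_set = HYDROPHOBIC_SET) {
  offs <- as.integer(names(cumulative))
  if (!0L %in% offs) stop("offset 0 absent from the cumulative profile")
  conserved <- offs[cumulative >= threshold]
  if (!is.null(consensus)) {
    cons <- consensus[as.character(conserved)]
    conserved <- conserved[!is.na(cons) & cons %in% hydrophobic_set]
  }
  if (!0L %in% conserved) {
    warning("center offset 0 below threshold; pattern still centered at 0")
    conserved <- sort(c(conserved, 0L))
  }
  conserved <- sort(unique(conserved))
  piece <- ifelse(conserved == 0L, "Hc", "H")
  gaps <- diff(conserved) - 1L
  pattern <- piece[1]
  for (k in seq_along(gaps)) {
    if (gaps[k] > 0) pattern <- paste0(pattern, "X", gaps[k])
    pattern <- paste0(pattern, piece[k + 1])
  }
  asym <- conserved[vapply(conserved, function(o) {
    o != 0L && !any(abs(conserved + o) <= 1L)
  }, logical(1))]
  structure(list(offsets = conserved, pattern = pattern,
                 asymmetric = asym, threshold = threshold),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("Symmetric motif:", x$pattern, "\n")
  cat("Conserved offsets:", paste(x$offsets, collapse = " "), "\n")
  if (length(x$asymmetric))
    cat("Offsets without mirror partner:", paste(x$asymmetric, collapse = " "), "\n")
  invisible(x)
}

#' Mirror-symmetry score of a cumulative profile
#'
#' Pearson correlation between the profile and its mirror image about offset
#' 0 (offsets missing on one side count as 0), clipped to `[0, 1]`.
#'
#' @param cumulative named numeric vector (names = signed offsets, 0
#'   present).
#' @return Score in `[0, 1]`; 1 for a perfectly mirrored profile.
#' @export
symmetry_score <- function(cumulative) {
  offs <- as.integer(names(cumulative))
  if (!0L %in% offs) stop("offset 0 absent")
  grid <- seq(-max(abs(offs)), max(abs(offs)))
  v <- setNames(rep(0, length(grid)), grid)
  v[as.character(offs)] <- cumulative
  mir <- v[as.character(-grid)]
  if (stats::sd(v) == 0 || stats::sd(mir) == 0) return(1)  # constant: trivially mirrored
  max(0, min(1, stats::cor(v, mir)))
}
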