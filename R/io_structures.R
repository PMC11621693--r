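# Multi-model PDB I/O and the in-memory structural model.
#
# The in-memory containers are plain lists with classes "structure_model" and
# "ensemble":
#   structure_model: $atoms  data.frame(name, element, chain_id, res_index
#                            (character key: author number + insertion code),
#                            res_num (integer author number), res_name)
#                    $xyz    natom x 3 numeric matrix (Angstrom)
#                    $model_id integer
#   ensemble:        $atoms  shared topology data.frame (as above)
#                    $xyz    natom x 3 x nmodel array
#                    $model_ids integer vector
#                    $topology_key single string digest of
#                            (chain_id, res_index, name)

#' Create a structure model
#'
#' @param atoms data.frame with columns `name`, `element`, `chain_id`,
#'   `res_index` (character author-numbering key, insertion code appended),
#'   `res_num` (integer author residue number), `res_name`.
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param model_id integer model identifier.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, xyz, model_id = 1L) {
  xyz <- as.matrix(xyz)
  stopifnot(is.data.frame(atoms), ncol(xyz) == 3L, nrow(xyz) == nrow(atoms))
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (nrow(atoms) < 1L) stop("empty structure")
  atoms$res_index <- as.character(atoms$res_index)
  if (is.null(atoms$res_num)) {
    atoms$res_num <- suppressWarnings(as.integer(gsub("[^0-9-]", "", atoms$res_index)))
  }
  rownames(atoms) <- NULL
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, xyz = xyz, model_id = as.integer(model_id)),
            class = "structure_model")
}

topology_key <- function(atoms) {
  paste(atoms$chain_id, atoms$res_index, atoms$name, sep = "|", collapse = ";")
}

#' Bundle structure models into an ensemble
#'
#' All models must share an identical topology (same chains, residue keys and
#' atom names in the same order); the first divergent atom is named otherwise.
#'
#' @param models list of [structure_model()] objects.
#' @return An object of class `ensemble` with a 3-D coordinate array.
#' @export
as_ensemble <- function(models) {
  stopifnot(length(models) >= 1L)
  ref <- models[[1L]]
  key_ref <- topology_key(ref$atoms)
  for (m in models[-1L]) {
    if (!identical(topology_key(m$atoms), key_ref)) {
      div <- which(paste(m$atoms$chain_id, m$atoms$res_index, m$atoms$name) !=
                   paste(ref$atoms$chain_id, ref$atoms$res_index, ref$atoms$name))
      at <- if (length(div)) {
        i <- div[1L]
        sprintf("%s %s/%s", m$atoms$name[i], m$atoms$chain_id[i], m$atoms$res_index[i])
      } else sprintf("atom count %d vs %d", nrow(m$atoms), nrow(ref$atoms))
      stop("topology mismatch across models, first divergence at: ", at)
    }
  }
  xyz <- array(NA_real_, dim = c(nrow(ref$atoms), 3L, length(models)),
               dimnames = list(NULL, c("x", "y", "z"), NULL))
  for (k in seq_along(models)) xyz[, , k] <- models[[k]]$xyz
  structure(list(atoms = ref$atoms, xyz = xyz,
                 model_ids = vapply(models, `[[`, integer(1), "model_id"),
                 topology_key = key_ref),
            class = "ensemble")
}

#' Number of models in an ensemble
#' @param ens an `ensemble`.
#' @return integer model count.
#' @export
n_models <- function(ens) dim(ens$xyz)[3L]

#' Extract one model of an ensemble
#' @param ens an `ensemble`.
#' @param k model position (1-based).
#' @return A `structure_model`.
#' @export
get_model <- function(ens, k) {
  stopifnot(k >= 1L, k <= n_models(ens))
  structure_model(ens$atoms, ens$xyz[, , k, drop = TRUE], ens$model_ids[k])
}

#' Read a multi-model PDB file into an ensemble
#'
#' Fixed-column parsing of ATOM/HETATM records.  MODEL/ENDMDL blocks become
#' separate models; a file without MODEL records is a single implicit model.
#' Author residue numbering is preserved verbatim, with insertion codes
#' appended to the residue key.  Alternate locations are resolved to the
#' highest-occupancy variant (ties: first encountered).  Hydrogens are kept;
#' HETATM water (HOH/WAT/DOD) is excluded unless `keep_water = TRUE`.
#'
#' @param path PDB file.
#' @param keep_water keep water HETATM records.
#' @return An [as_ensemble()] object; models must share one topology.
#' @export
read_structure_models <- function(path, keep_water = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  is_model <- rec == "MODEL "
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  # model id per line: cumulative count of MODEL records (0 if none seen)
  mblock <- cumsum(is_model)
  models <- list()
  for (b in sort(unique(mblock[is_atom]))) {
    sel <- is_atom & mblock == b
    ln <- lines[sel]
    het <- substr(ln, 1, 6) == "HETATM"
    atoms <- data.frame(
      name      = trimws(substr(ln, 13, 16)),
      altloc    = substr(ln, 17, 17),
      res_name  = trimws(substr(ln, 18, 20)),
      chain_id  = trimws(substr(ln, 22, 22)),
      res_num   = as.integer(substr(ln, 23, 26)),
      icode     = trimws(substr(ln, 27, 27)),
      occ       = suppressWarnings(as.numeric(substr(ln, 55, 60))),
      element   = trimws(substr(ln, 77, 78)),
      stringsAsFactors = FALSE)
    atoms$occ[is.na(atoms$occ)] <- 1
    xyz <- cbind(as.numeric(substr(ln, 31, 38)),
                 as.numeric(substr(ln, 39, 46)),
                 as.numeric(substr(ln, 47, 54)))
    if (!keep_water) {
      w <- het & atoms$res_name %in% c("HOH", "WAT", "DOD")
      atoms <- atoms[!w, , drop = FALSE]; xyz <- xyz[!w, , drop = FALSE]
    }
    # element fallback from the atom-name column for minimal files
    miss <- atoms$element == ""
    atoms$element[miss] <- substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", atoms$name[miss])), 1, 1)
    atoms$res_index <- paste0(atoms$res_num, atoms$icode)
    # altloc: keep blank/"A"-style highest-occupancy variant per atom site
    if (any(atoms$altloc != " " & atoms$altloc != "")) {
      site <- paste(atoms$chain_id, atoms$res_index, atoms$name)
      keep <- !logical(nrow(atoms))
      for (s in unique(site[duplicated(site)])) {
        idx <- which(site == s)
        best <- idx[which.max(atoms$occ[idx])]
        keep[setdiff(idx, best)] <- FALSE
      }
      atoms <- atoms[keep, , drop = FALSE]; xyz <- xyz[keep, , drop = FALSE]
    }
    atoms$altloc <- NULL; atoms$occ <- NULL; atoms$icode <- NULL
    models[[length(models) + 1L]] <-
      structure_model(atoms[, c("name", "element", "chain_id", "res_index", "res_num", "res_name")],
                      xyz, model_id = if (b == 0) 1L else as.integer(b))
  }
  as_ensemble(models)
}

#' Write an ensemble (or single model) as a multi-model PDB file
#'
#' @param x an `ensemble` or `structure_model`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_structure_models <- function(x, path) {
  if (inherits(x, "structure_model")) x <- as_ensemble(list(x))
  stopifnot(inherits(x, "ensemble"))
  at <- x$atoms
  # PDB atom-name field: element-aligned 4-char names
  nm <- ifelse(nchar(at$name) >= 4, substr(at$name, 1, 4),
               sprintf(" %-3s", at$name))
  con <- file(path, "w"); on.exit(close(con))
  multi <- n_models(x) > 1L
  for (k in seq_len(n_models(x))) {
    if (multi) writeLines(sprintf("MODEL     %4d", x$model_ids[k]), con)
    xyz <- x$xyz[, , k, drop = TRUE]
    lines <- sprintf("ATOM  %5d %s%s%s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     seq_len(nrow(at)), nm, " ", sprintf("%-3s", at$res_name),
                     substr(paste0(at$chain_id, " "), 1, 1), at$res_num,
                     sprintf("%-1s", sub("^-?[0-9]+", "", at$res_index)),
                     xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, at$element)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read FASTA sequences
#'
#' Thin wrapper over [Biostrings::readAAStringSet()]: sequences are
#' upper-cased, gap characters `-` are preserved, duplicate record ids are an
#' error.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate FASTA ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  setNames(toupper(as.character(ss)), ids)
}

#' Write FASTA sequences
#' @param seqs named character vector.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  invisible(path)
}

#' Read an NMR restraint table
#'
#' Two dialects are accepted.  (1) A whitespace-separated 9-column distance
#' format: `chain_i res_i atom_i chain_j res_j atom_j target lower upper`
#' (Angstrom), with optional dihedral lines
#' `DIH res angle target tolerance` (degrees, angle `phi` or `psi`);
#' comment lines start with `#`.  (2) A supported subset of CNS/XPLOR
#' `assign` statements with single unambiguous atom selections:
#' `assign (segid A and resid 5 and name HA) (segid A and resid 6 and name HN) 3.0 1.2 1.2`
#' where the trailing numbers are d, dminus, dplus (bounds d-dminus, d+dplus).
#'
#' @param path restraint file.
#' @return List of class `restraint_table` with data.frames
#'   `distance` (chain_i, res_i, atom_i, chain_j, res_j, atom_j, target,
#'   lower, upper) and `dihedral` (res, angle, target, tolerance).
#' @export
read_restraints <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  raw <- trimws(lines)
  keep <- nzchar(raw) & !startsWith(raw, "#") & !startsWith(raw, "!")
  dist <- list(); dih <- list()
  for (i in which(keep)) {
    ln <- raw[i]
    if (grepl("^assign", ln, ignore.case = TRUE)) {
      m <- regmatches(ln, gregexpr("\\(([^()]*)\\)", ln))[[1]]
      if (length(m) < 2L) stop("unparseable assign statement at line ", i)
      sel <- lapply(m[1:2], parse_cns_selection, line = i)
      nums <- suppressWarnings(as.numeric(strsplit(trimws(sub(".*\\)", "", ln)), "\\s+")[[1]]))
      nums <- nums[!is.na(nums)]
      if (length(nums) < 3L) stop("malformed bounds at line ", i)
      d <- nums[1]; lo <- d - nums[2]; hi <- d + nums[3]
      if (!(lo <= d && d <= hi)) stop("malformed bounds at line ", i)
      dist[[length(dist) + 1L]] <- data.frame(
        chain_i = sel[[1]]$chain, res_i = sel[[1]]$res, atom_i = sel[[1]]$atom,
        chain_j = sel[[2]]$chain, res_j = sel[[2]]$res, atom_j = sel[[2]]$atom,
        target = d, lower = lo, upper = hi, stringsAsFactors = FALSE)
      next
    }
    f <- strsplit(ln, "\\s+")[[1]]
    if (toupper(f[1]) == "DIH") {
      if (length(f) != 5L) stop("malformed dihedral restraint at line ", i)
      ang <- tolower(f[3])
      if (!ang %in% c("phi", "psi")) stop("dihedral angle must be phi or psi at line ", i)
      dih[[length(dih) + 1L]] <- data.frame(
        res = as.integer(f[2]), angle = ang,
        target = as.numeric(f[4]), tolerance = as.numeric(f[5]),
        stringsAsFactors = FALSE)
      next
    }
    if (length(f) != 9L) stop("expected 9 fields at line ", i, ", got ", length(f))
    v <- suppressWarnings(as.numeric(f[7:9]))
    if (any(is.na(v)) || !(v[2] <= v[1] && v[1] <= v[3]))
      stop("malformed bounds at line ", i)
    ri <- as.integer(f[2]); rj <- as.integer(f[5])
    if (is.na(ri) || is.na(rj) || ri <= 0 || rj <= 0)
      stop("residue indices must be positive at line ", i)
    dist[[length(dist) + 1L]] <- data.frame(
      chain_i = f[1], res_i = ri, atom_i = f[3],
      chain_j = f[4], res_j = rj, atom_j = f[6],
      target = v[1], lower = v[2], upper = v[3], stringsAsFactors = FALSE)
  }
  empty_d <- data.frame(chain_i = character(), res_i = integer(), atom_i = character(),
                        chain_j = character(), res_j = integer(), atom_j = character(),
                        target = numeric(), lower = numeric(), upper = numeric(),
                        stringsAsFactors = FALSE)
  empty_a <- data.frame(res = integer(), angle = character(),
                        target = numeric(), tolerance = numeric(), stringsAsFactors = FALSE)
  structure(list(
    distance = if (length(dist)) do.call(rbind, dist) else empty_d,
    dihedral = if (length(dih)) do.call(rbind, dih) else empty_a),
    class = "restraint_table")
}

parse_cns_selection <- function(txt, line) {
  get1 <- function(key) {
    m <- regmatches(txt, regexpr(paste0(key, "\\s+\\S+"), txt, ignore.case = TRUE))
    if (!length(m)) return(NA_character_)
    strsplit(m, "\\s+")[[1]][2]
  }
  res <- get1("resid"); atom <- get1("name"); chain <- get1("segid")
  if (is.na(res) || is.na(atom))
    stop("unsupported CNS selection (need single resid/name) at line ", line)
  list(chain = if (is.na(chain)) "A" else chain,
       res = as.integer(res), atom = toupper(atom))
}

#' Write a labelled numeric matrix as TSV
#'
#' Header row holds column labels; first column holds row labels.  Values are
#' written at 6 significant digits and round-trip through [read_matrix_tsv()].
#'
#' @param mat numeric matrix.
#' @param row_labels,col_labels label vectors matching `mat` dimensions.
#' @param path output file.
#' @param comment optional `#` metadata line written first.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(mat, row_labels = rownames(mat),
                             col_labels = colnames(mat), path, comment = NULL) {
  mat <- as.matrix(mat)
  if (length(row_labels) != nrow(mat) || length(col_labels) != ncol(mat))
    stop("label/shape mismatch: ", nrow(mat), "x", ncol(mat), " matrix vs ",
         length(row_labels), "/", length(col_labels), " labels")
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c("", col_labels), collapse = "\t"), con)
  if (nrow(mat)) {
    body <- vapply(seq_len(nrow(mat)), function(i)
      paste(c(row_labels[i], signif(mat[i, ], 6)), collapse = "\t"), character(1))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a TSV matrix written by [write_matrix_tsv()]
#' @param path TSV file.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "# ")]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  if (length(lines) == 1L) {
    m <- matrix(numeric(0), 0, length(header))
    colnames(m) <- header
    return(m)
  }
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  m <- t(vapply(fields, function(f) as.numeric(f[-1]), numeric(length(header))))
  if (length(header) == 1L) m <- matrix(unlist(lapply(fields, function(f) as.numeric(f[-1]))), ncol = 1)
  dimnames(m) <- list(vapply(fields, `[[`, character(1), 1L), header)
  m
}
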