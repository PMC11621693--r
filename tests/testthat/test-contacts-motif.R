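# Contact counting, minimal-distance maps, centred alignment, motif extraction

two_atom_model <- function(d) {
  atoms <- data.frame(name = c("CB", "CB"), element = "C",
                      chain_id = c("A", "B"), res_index = c("1", "1"),
                      res_num = c(1L, 1L), res_name = "LEU",
                      stringsAsFactors = FALSE)
  structure_model(atoms, rbind(c(0, 0, 0), c(d, 0, 0)))
}

test_that("contact counts use strict inequality at the cutoff", {
  expect_equal(unname(contact_counts(two_atom_model(2.5))$A), 1L)
  expect_equal(unname(contact_counts(two_atom_model(3.0))$A), 0L)  # exactly 3.0
  expect_equal(unname(contact_counts(two_atom_model(2.999))$B), 1L)
  expect_error(contact_counts(two_atom_model(1), chainB = "Z"), "unknown chain")
})

test_that("contact counts equal the brute-force double loop on a zipper dimer", {
  m <- build_coiled_coil_dimer(coil_params(n_res = 20, zipper_offsets = c(-7, 0, 7)))
  for (cutoff in c(3, 4.5)) {
    got <- contact_counts(m, cutoff = cutoff, atom_mode = "all_heavy")
    ref <- brute_contact_counts(m, "A", "B", cutoff)
    expect_identical(got$A, ref$A)
    expect_identical(got$B, ref$B)
    # total symmetry: sum over A = sum over B = number of qualifying pairs
    expect_equal(sum(got$A), sum(got$B))
  }
})

test_that("minimal-distance maps take the minimum over frames and mask the band", {
  atoms <- data.frame(name = c("CA", "CA"), element = "C",
                      chain_id = c("A", "B"), res_index = c("1", "1"),
                      res_num = c(1L, 1L), res_name = "GLY", stringsAsFactors = FALSE)
  m1 <- structure_model(atoms, rbind(c(0, 0, 0), c(5, 0, 0)))
  m2 <- structure_model(atoms, rbind(c(0, 0, 0), c(8, 0, 0)), model_id = 2)
  ens <- as_ensemble(list(m1, m2))
  cm <- min_distance_map(ens, band = c(3, 10))
  expect_equal(cm$raw[1, 1], 5)
  one <- min_distance_map(as_ensemble(list(m1)))
  expect_equal(one$raw[1, 1], 5)
  close_ens <- as_ensemble(list(structure_model(atoms, rbind(c(0, 0, 0), c(2, 0, 0)))))
  cmc <- min_distance_map(close_ens, band = c(3, 10))
  expect_true(is.na(cmc$map[1, 1]))   # below the band: masked
  expect_equal(cmc$raw[1, 1], 2)      # raw minimum retained
})

test_that("minimal-distance maps match the exhaustive loop oracle", {
  base <- build_coiled_coil_dimer(coil_params(n_res = 8, zipper_offsets = 0))
  ens <- perturb_ensemble(base, rep(1, 16), n_models = 2, seed = 17)
  got <- min_distance_map(ens, atom_mode = "ca_vs_all")
  ref <- brute_min_distance(ens, "A", "B")
  expect_equal(got$raw, ref)
  # appending frames can only lower the minima
  ens3 <- perturb_ensemble(base, rep(1, 16), n_models = 3, seed = 17)
  got3 <- min_distance_map(ens3, atom_mode = "ca_vs_all")
  expect_true(all(got3$raw <= got$raw + 1e-12))
})

test_that("pair distance series preserve frame order and match single-frame distances", {
  base <- build_coiled_coil_dimer(coil_params(n_res = 10, zipper_offsets = 0))
  ens <- perturb_ensemble(base, rep(0.5, 20), n_models = 6, seed = 19)
  pr <- list(list(c("A", 5, "CA"), c("B", 5, "CA")),
             list(c("A", 1, "CB"), c("B", 10, "CB")))
  ser <- pair_distance_series(ens, pr)
  expect_equal(dim(ser), c(6L, 2L))
  k <- 4
  mk <- get_model(ens, k)
  key <- paste(mk$atoms$chain_id, mk$atoms$res_num, mk$atoms$name)
  i <- match("A 5 CA", key); j <- match("B 5 CA", key)
  expect_equal(unname(ser[k, 1]), sqrt(sum((mk$xyz[i, ] - mk$xyz[j, ])^2)))
  static <- perturb_ensemble(base, rep(0, 20), n_models = 3, seed = 1)
  ss <- pair_distance_series(static, pr)
  expect_true(all(apply(ss, 2, function(x) diff(range(x))) == 0))
  expect_error(pair_distance_series(ens, list(list(c("A", 99, "CA"), c("B", 5, "CA")))),
               "not found")
})

test_that("centred alignment maps residues to signed offsets around the centre", {
  aln <- center_alignment(c(h1 = "MKVLA"), c(h1 = 3))
  expect_equal(unname(aln[[1]]$offsets), -2:2)
  expect_equal(names(aln[[1]]$offsets), as.character(1:5))
  # two homologs with different centres align at offset 0
  aln2 <- center_alignment(c(a = "AAALAAA", b = "GGGGLGG"), c(a = 4, b = 5))
  expect_equal(aln2[[1]]$residues[["0"]], "L")
  expect_equal(aln2[[2]]$residues[["0"]], "L")
  # round trip offset -> index
  offs <- aln2[[2]]$offsets
  expect_equal(as.integer(names(offs)), unname(offs) + aln2[[2]]$center)
  expect_error(center_alignment(c(x = "MK"), c(x = 5)), "outside")
})

test_that("cumulative counts sum homologs and monomers; both-monomer rule", {
  aln <- center_alignment(c(a = "ALA", b = "VLV"), c(a = 2, b = 2))
  one <- setNames(c(0, 1, 0), 1:3)
  counts <- list(list(one, one), list(one, one))
  cum <- cumulate_counts(counts, aln)
  expect_equal(cum[["0"]], 4)   # 2 homologs x 2 monomers
  expect_equal(cumulate_counts(counts, aln, monomer_mode = "first")[["0"]], 2)
  expect_equal(cumulate_counts(counts[1], center_alignment(c(a = "ALA"), c(a = 2)))[["0"]], 2)
  # randomized toy against hand summation
  set.seed(23)
  c1 <- setNames(sample(0:5, 3, TRUE), 1:3); c2 <- setNames(sample(0:5, 3, TRUE), 1:3)
  c3 <- setNames(sample(0:5, 3, TRUE), 1:3); c4 <- setNames(sample(0:5, 3, TRUE), 1:3)
  cumr <- cumulate_counts(list(list(c1, c2), list(c3, c4)), aln)
  expect_equal(unname(cumr), unname(c1 + c2 + c3 + c4))
})

test_that("motif extraction writes the spacing pattern and symmetry report", {
  cum <- setNames(c(40, rep(0, 11), 50, rep(0, 11), 40), seq(-12, 12))
  mp <- extract_symmetric_motif(cum, threshold = 35)
  expect_equal(mp$pattern, "HX11HcX11H")
  expect_equal(mp$offsets, c(-12L, 0L, 12L))
  expect_length(mp$asymmetric, 0)
  # threshold above all counts: pattern collapses to the centre with warning
  expect_warning(deg <- extract_symmetric_motif(cum, threshold = 1000), "below threshold")
  expect_equal(deg$pattern, "Hc")
  # asymmetric profile flagged
  cum2 <- setNames(c(0, rep(0, 11), 50, rep(0, 11), 40), seq(-12, 12))
  mp2 <- extract_symmetric_motif(cum2, threshold = 35)
  expect_equal(mp2$asymmetric, 12L)
  # consensus filter drops non-hydrophobic positions
  cons <- setNames(rep("K", 25), seq(-12, 12)); cons[c("-12", "0", "12")] <- "L"
  cum3 <- cum; cum3[["-5"]] <- 60
  mp3 <- extract_symmetric_motif(cum3, threshold = 35, consensus = cons)
  expect_equal(mp3$offsets, c(-12L, 0L, 12L))
  expect_error(extract_symmetric_motif(setNames(1, 3)), "offset 0")
})

test_that("noise-free planted family recovers its pattern end to end", {
  spec <- motif_family_spec(n_homologs = 19, planted_offsets = c(-12, 0, 12),
                            substitution_noise = 0, seed = 31)
  fam <- generate_motif_family(spec)
  aln <- center_alignment(fam$sequences, fam$centers)
  cum <- cumulate_counts(hydrophobic_profile_counts(aln), aln)
  mp <- extract_symmetric_motif(cum, threshold = 19,
                                consensus = consensus_residues(aln))
  expect_equal(mp$pattern, "HX11HcX11H")
  expect_length(mp$asymmetric, 0)
})

test_that("symmetry score: mirrored 1, one-sided 0, random matches the formula", {
  expect_equal(symmetry_score(setNames(c(3, 1, 7, 1, 3), -2:2)), 1)
  expect_equal(symmetry_score(setNames(c(0, 0, 0, 5, 9), -2:2)), 0)
  set.seed(5)
  for (r in 1:5) {
    v <- setNames(runif(9), -4:4)
    direct <- stats::cor(unname(v), unname(v[as.character(4:-4)]))
    expect_equal(symmetry_score(v), max(0, min(1, direct)))
  }
})

test_that("planted offsets are recovered under substitution noise", {
  # invariant: >= 95% exact recovery at noise 0.1, 19 homologs, 100 seeds
  offs <- c(-31, -12, 0, 12, 31)
  hits <- 0L
  for (s in 1:100) {
    fam <- generate_motif_family(motif_family_spec(
      n_homologs = 19, planted_offsets = offs, substitution_noise = 0.1,
      seed = s))
    aln <- center_alignment(fam$sequences, fam$centers)
    cum <- cumulate_counts(hydrophobic_profile_counts(aln), aln)
    mp <- extract_symmetric_motif(cum, threshold = 19,
                                  consensus = consensus_residues(aln))
    if (identical(mp$offsets, as.integer(offs))) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})
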