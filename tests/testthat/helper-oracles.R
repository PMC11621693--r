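# Independent oracles and small fixture builders shared across the tests.

# Derivative-free superposition oracle: search over unit quaternions with
# iterative shrinking perturbations; translation handled by centring.
# Independent of the SVD route used by superpose().
quaternion_search_rmsd <- function(mobile, reference, n_start = 200L,
                                   n_rounds = 40L, seed = 42L) {
  set.seed(seed)
  X <- sweep(mobile, 2, colMeans(mobile))
  Y <- sweep(reference, 2, colMeans(reference))
  q_to_R <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  score <- function(q) sqrt(mean(rowSums((X %*% t(q_to_R(q)) - Y)^2)))
  qs <- matrix(rnorm(4 * n_start), ncol = 4)
  vals <- apply(qs, 1, score)
  best <- qs[which.min(vals), ]; best_val <- min(vals)
  scale <- 0.5
  for (r in seq_len(n_rounds)) {
    cand <- sweep(matrix(rnorm(4 * 60, sd = scale), ncol = 4), 2, best, `+`)
    v <- apply(cand, 1, score)
    if (min(v) < best_val) { best_val <- min(v); best <- cand[which.min(v), ] }
    scale <- scale * 0.7
  }
  best_val
}

# O(N^2) double-loop contact-count oracle (strict < cutoff)
brute_contact_counts <- function(model, chainA, chainB, cutoff, heavy_only = TRUE) {
  at <- model$atoms
  ia <- which(at$chain_id == chainA & (!heavy_only | toupper(at$element) != "H"))
  ib <- which(at$chain_id == chainB & (!heavy_only | toupper(at$element) != "H"))
  cntA <- setNames(rep(0L, length(unique(at$res_index[at$chain_id == chainA]))),
                   unique(at$res_index[at$chain_id == chainA]))
  cntB <- setNames(rep(0L, length(unique(at$res_index[at$chain_id == chainB]))),
                   unique(at$res_index[at$chain_id == chainB]))
  for (i in ia) for (j in ib) {
    d <- sqrt(sum((model$xyz[i, ] - model$xyz[j, ])^2))
    if (d < cutoff) {
      cntA[at$res_index[i]] <- cntA[at$res_index[i]] + 1L
      cntB[at$res_index[j]] <- cntB[at$res_index[j]] + 1L
    }
  }
  list(A = cntA, B = cntB)
}

# exhaustive min-distance oracle over frames, CA of A vs all atoms of B
brute_min_distance <- function(ens, chainA, chainB) {
  at <- ens$atoms
  ia <- which(at$chain_id == chainA & at$name == "CA")
  ib <- which(at$chain_id == chainB)
  resA <- unique(at$res_index[at$chain_id == chainA])
  resB <- unique(at$res_index[at$chain_id == chainB])
  raw <- matrix(Inf, length(resA), length(resB), dimnames = list(resA, resB))
  for (k in seq_len(n_models(ens))) for (i in ia) for (j in ib) {
    d <- sqrt(sum((ens$xyz[i, , k] - ens$xyz[j, , k])^2))
    ri <- at$res_index[i]; rj <- at$res_index[j]
    if (d < raw[ri, rj]) raw[ri, rj] <- d
  }
  raw
}

# direct double-loop KDE oracle (printed-formula order of operations)
brute_kde <- function(x, sigma) {
  M <- nrow(x); n <- ncol(x)
  pref <- (2 * pi * sigma^2)^(-n / 2) / M
  sapply(seq_len(M), function(i)
    pref * sum(exp(-rowSums(sweep(x, 2, x[i, ])^2) / (2 * sigma^2))))
}

# small random structure: one chain, n_res residues x 2 atoms
random_model <- function(n_res = 5, seed = 1, chain = "A") {
  set.seed(seed)
  atoms <- data.frame(
    name = rep(c("CA", "CB"), n_res), element = "C", chain_id = chain,
    res_index = as.character(rep(seq_len(n_res), each = 2)),
    res_num = rep(seq_len(n_res), each = 2),
    res_name = "ALA", stringsAsFactors = FALSE)
  structure_model(atoms, matrix(rnorm(n_res * 6, sd = 4), n_res * 2, 3))
}

# rigid motion helpers
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

paper_data_file <- function(name) {
  system.file("extdata", "paper_data", name, package = "remcoil")
}
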