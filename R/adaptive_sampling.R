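# Density-biased adaptive sampling: PCA landscape, Gaussian kernel density,
# inverse-density seed probabilities, seed selection and unbiasing weights.
#
# The scheme: project the M_k configurations sampled so far onto the first
# n principal modes, estimate the density rho_k(x_i) at each projected point
# with a Gaussian kernel of bandwidth sigma,
#
#   rho_k(x_i) = (2 pi sigma^2)^(-n/2) M_k^-1 sum_j exp(-|x_i - x_j|^2 / 2 sigma^2),
#
# pick new seeds with probability inversely proportional to density,
#
#   P(i) = rho_k^-1(x_i) / sum_j rho_k^-1(x_j),
#
# and correct observables computed over seeds with the unbiasing factors
#
#   alpha_i = 1 / (M_k P(i)),   omega_i = alpha_i / sum_j alpha_j.

#' PCA projection of a conformational landscape
#'
#' Principal component analysis of a frames x features matrix (for example
#' flattened coordinates): the frames are mean-centred internally and
#' projected onto the top `n_modes` eigenvectors of the covariance.  Sign
#' convention: each mode's largest-magnitude loading is positive.
#'
#' @param frames numeric matrix, one row per configuration; more rows than
#'   `n_total` required.
#' @param n_modes modes retained for the projection (default 4).
#' @param n_total modes computed (default 10).
#' @return List of class `conformation_space`: `projections` (frames x
#'   n_modes), `modes` (loadings, features x n_modes), `explained_variance`
#'   (length `n_total`, non-increasing), `n_modes`, `n_total`.
#' @export
pca_project <- function(frames, n_modes = 4L, n_total = 10L) {
  frames <- as.matrix(frames)
  if (nrow(frames) <= n_total)
    stop("need more than n_total = ", n_total, " frames, got ", nrow(frames))
  n_total <- min(n_total, ncol(frames))
  if (n_modes > n_total) stop("n_modes must not exceed n_total")
  pc <- stats::prcomp(frames, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  rank_ok <- sum(ev > max(ev) * 1e-12)
  if (rank_ok < n_modes)
    stop("data rank ", rank_ok, " below n_modes = ", n_modes)
  keep <- seq_len(n_modes)
  loads <- pc$rotation[, keep, drop = FALSE]
  flip <- vapply(seq_len(n_modes), function(k) {
    l <- loads[, k]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  loads <- sweep(loads, 2, flip, `*`)
  proj <- sweep(pc$x[, keep, drop = FALSE], 2, flip, `*`)
  structure(list(projections = unname(proj), modes = unname(loads),
                 explained_variance = ev[seq_len(min(n_total, length(ev)))],
                 n_modes = n_modes, n_total = n_total),
            class = "conformation_space")
}

#' Gaussian kernel density over projected configurations
#'
#' Evaluates the kernel density estimate at every sample point (self-term
#' included):
#' `rho(x_i) = (2 pi sigma^2)^(-n/2) / M * sum_j exp(-|x_i - x_j|^2 / (2 sigma^2))`.
#' With `bandwidth = "scott"` the data are whitened by their sample
#' covariance and the scalar Scott factor `M^(-1/(n + 4))` is used as sigma
#' in the whitened space (densities are then relative to that space; seed
#' probabilities are unaffected by the constant Jacobian).  A numeric
#' `bandwidth` is used directly as sigma on the raw coordinates.
#'
#' @param projections M x n matrix of projected configurations (M >= 2).
#' @param bandwidth `"scott"` or a positive scalar sigma.
#' @return Numeric vector of densities (> 0), with attributes `sigma` and
#'   `whitened`.
#' @export
kde_density <- function(projections, bandwidth = "scott") {
  x <- as.matrix(projections)
  M <- nrow(x); n <- ncol(x)
  if (M < 2L) stop("need at least 2 configurations for a density estimate")
  whitened <- FALSE
  if (identical(bandwidth, "scott")) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0))
      stop("zero-variance dimension: supply an explicit numeric bandwidth")
    cv <- stats::cov(x)
    ei <- eigen(cv, symmetric = TRUE)
    if (min(ei$values) <= max(ei$values) * 1e-12)
      stop("singular covariance: supply an explicit numeric bandwidth")
    W <- ei$vectors %*% diag(1 / sqrt(ei$values), n) %*% t(ei$vectors)
    x <- x %*% W
    sigma <- M^(-1 / (n + 4))
    whitened <- TRUE
  } else {
    sigma <- as.numeric(bandwidth)
    if (!is.finite(sigma) || sigma <= 0) stop("bandwidth must be positive")
  }
  rho <- kde_gauss_sum(x, sigma)
  rho <- rho * (2 * pi * sigma^2)^(-n / 2) / M
  attr(rho, "sigma") <- sigma
  attr(rho, "whitened") <- whitened
  rho
}

#' Inverse-density seed probabilities
#'
#' `P(i) = rho^-1(x_i) / sum_j rho^-1(x_j)`: the probability of selecting a
#' configuration as a new seed is inversely proportional to its estimated
#' density, favouring undiscovered regions.
#'
#' @param rho positive densities.
#' @return Probability vector summing to 1.
#' @export
seed_probabilities <- function(rho) {
  rho <- as.numeric(rho)
  if (any(!is.finite(rho)) || any(rho <= 0)) stop("densities must be positive")
  inv <- 1 / rho
  inv / sum(inv)
}

#' Select seeds from the biased distribution
#'
#' Draws `n_seeds` configuration indices with probabilities `P`; without
#' replacement (the default — a physical seed is a distinct structure) the
#' remaining probabilities are renormalised after each draw.
#'
#' @param P probability vector (sums to 1).
#' @param n_seeds number of seeds; at most `length(P)` without replacement.
#' @param seed RNG seed (deterministic output).
#' @param replacement sample with replacement.
#' @return Integer vector of selected indices.
#' @export
select_seeds <- function(P, n_seeds, seed = 1L, replacement = FALSE) {
  if (abs(sum(P) - 1) > 1e-9) stop("P must sum to 1")
  if (!replacement && n_seeds > length(P))
    stop("n_seeds exceeds the number of configurations (without replacement)")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  sample.int(length(P), size = n_seeds, replace = replacement, prob = P)
}

#' Unbiasing factors and normalised weights
#'
#' `alpha_i = 1 / (M_k P(i))` undoes the selection bias of seed i;
#' `omega_i = alpha_i / sum_j alpha_j` are the normalised weights used for
#' reweighted observables.  When `P` came from [seed_probabilities()],
#' `omega` is proportional to the density `rho`.
#'
#' @param P seed probabilities (positive, sum 1), typically subset to the
#'   selected seeds.
#' @param M_k total number of configurations in the conformational space.
#' @return List with `alpha` and `omega` (omega sums to 1).
#' @export
unbias_weights <- function(P, M_k) {
  if (any(P <= 0)) stop("P must be positive")
  alpha <- 1 / (M_k * P)
  list(alpha = alpha, omega = alpha / sum(alpha))
}

#' Reweighted mean of an observable over seeds
#'
#' `sum_i omega_i v_i` — the bias-corrected estimate of the observable's
#' ensemble average.
#'
#' @param values observable value per seed.
#' @param omega normalised weights (sum 1), same length.
#' @return Scalar estimate.
#' @export
reweighted_mean <- function(values, omega) {
  if (length(values) != length(omega))
    stop("values and omega differ in length: ", length(values), " vs ", length(omega))
  if (abs(sum(omega) - 1) > 1e-9) stop("omega must sum to 1")
  sum(values * omega)
}

#' One round of density-biased adaptive sampling
#'
#' Composes [pca_project()] (skipped when the input already has no more than
#' `n_modes` columns and `project = FALSE`), [kde_density()],
#' [seed_probabilities()], [select_seeds()] and [unbias_weights()], recording
#' every quantity of the round.  Iterated rounds pass the cumulative point
#' set (all configurations sampled so far).
#'
#' @param points frames x features matrix (cumulative conformational space).
#' @param n_seeds seeds to select (the reference protocol uses 8 in the
#'   first round and 16 thereafter).
#' @param n_modes,n_total PCA modes retained / computed; see [pca_project()].
#' @param seed RNG seed for the selection.
#' @param bandwidth see [kde_density()].
#' @param project run PCA first; set `FALSE` to treat `points` as already
#'   projected.
#' @param replacement passed to [select_seeds()].
#' @return List of class `sampling_state`: `space` (or `NULL`),
#'   `projections`, `rho`, `sigma`, `M_k`, `P`, `seeds` (indices), `alpha`,
#'   `omega` (for the selected seeds, summing to 1), `seed`.
#' @export
adaptive_round <- function(points, n_seeds = 8L, n_modes = 4L, n_total = 10L,
                           seed = 1L, bandwidth = "scott", project = TRUE,
                           replacement = FALSE) {
  points <- as.matrix(points)
  space <- NULL
  if (project && ncol(points) > n_modes) {
    space <- pca_project(points, n_modes = n_modes, n_total = n_total)
    proj <- space$projections
  } else {
    proj <- points
  }
  rho <- kde_density(proj, bandwidth)
  P <- seed_probabilities(rho)
  idx <- select_seeds(P, n_seeds, seed = seed, replacement = replacement)
  w <- unbias_weights(P[idx], M_k = nrow(proj))
  structure(list(space = space, projections = proj,
                 rho = as.numeric(rho), sigma = attr(rho, "sigma"),
                 M_k = nrow(proj), P = P, seeds = idx,
                 alpha = w$alpha, omega = w$omega, seed = seed),
            class = "sampling_state")
}

#' @export
print.sampling_state <- function(x, ...) {
  cat(sprintf("Adaptive-sampling round: M_k = %d, %d seeds, sigma = %.4g\n",
              x$M_k, length(x$seeds), x$sigma))
  cat("Seed indices:", paste(utils::head(x$seeds, 16), collapse = " "),
      if (length(x$seeds) > 16) "..." else "", "\n")
  invisible(x)
}
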