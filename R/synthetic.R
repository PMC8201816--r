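# Seed-deterministic synthetic generators with known ground truth:
# independent binary feature modules, hierarchical Gaussian clusters, and a
# bifurcating trajectory. Each emulates the statistical structure of a class
# of biological datasets at the scale needed to exercise graph learning.

#' Binary feature-module data
#'
#' Generates data with exactly `n_modules` independent feature modules. The
#' `2^n` binary codes from `0` to `2^n - 1` are laid out as base patterns
#' (feature `j` carries bit `j`), cycled until `n_samples` rows exist, and
#' each row receives fresh Gaussian noise with standard deviation `noise_sd`.
#' Because the bits are independent across features, a co-activation graph
#' learned from a faithful representation of this data should split into
#' `n_modules` connected components.
#'
#' @param n_modules Positive integer, the number of independent binary
#'   features (bits).
#' @param n_samples Number of rows; defaults to `64 * 2^n_modules` so every
#'   code is seen many times. A warning is given below `2^n_modules`.
#' @param noise_sd Gaussian noise standard deviation (default `0.1`).
#' @param seed Integer seed; identical arguments give identical output.
#' @return List with `data` (`n_samples` x `n_modules` matrix), `module_id`
#'   (ground-truth module index per feature, here `1:n_modules`), and
#'   `pattern_id` (which binary code each row was generated from, 0-based).
#' @export
generate_module_data <- function(n_modules, n_samples = 64L * 2L^n_modules,
                                 noise_sd = 0.1, seed = 1L) {
  if (n_modules < 1 || n_modules != floor(n_modules)) {
    stop("`n_modules` must be a positive integer")
  }
  if (n_samples < 1) stop("`n_samples` must be positive")
  if (noise_sd <= 0) stop("`noise_sd` must be > 0")
  n_codes <- 2L^n_modules
  if (n_samples < n_codes) {
    warning(sprintf(
      "n_samples = %d is below the number of distinct codes 2^%d = %d",
      n_samples, n_modules, n_codes))
  }
  codes <- t(vapply(0:(n_codes - 1L), function(v) {
    as.numeric(bitwAnd(bitwShiftR(v, 0:(n_modules - 1L)), 1L))
  }, numeric(n_modules)))
  if (n_modules == 1L) codes <- matrix(codes, ncol = 1L)
  pattern_id <- rep_len(0:(n_codes - 1L), n_samples)
  set.seed(seed)
  x <- codes[pattern_id + 1L, , drop = FALSE] +
    matrix(stats::rnorm(n_samples * n_modules, sd = noise_sd),
           n_samples, n_modules)
  list(data = x, module_id = seq_len(n_modules), pattern_id = pattern_id)
}

#' Hierarchical Gaussian cluster data
#'
#' Generates `n_super` well-separated super-clusters, each split into `n_sub`
#' Gaussian sub-clusters, in `dim` dimensions. Super-centers sit on scaled
#' orthogonal coordinate axes at pairwise distance `super_sep`; each
#' sub-center is displaced from its super-center by `sub_sep` in a random
#' direction; points are isotropic Gaussian around their sub-center. With the
#' default separations the hierarchy is realizable: mean within-sub distances
#' < within-super < between-super.
#'
#' @param n_super Number of super-clusters (default 3).
#' @param n_sub Sub-clusters per super-cluster (default 2).
#' @param dim Ambient dimension (default 15); must be at least `n_super`.
#' @param per_cluster Points per (super, sub) cluster.
#' @param super_sep Pairwise distance between super-centers (default 10).
#' @param sub_sep Distance from sub-center to its super-center (default 3).
#' @param noise_sd Isotropic noise standard deviation (default 1).
#' @param seed Integer seed.
#' @return List with `data` (rows x `dim`), `super` and `sub` integer labels
#'   per row (1-based), and the `centers` used.
#' @export
generate_hierarchy_data <- function(n_super = 3L, n_sub = 2L, dim = 15L,
                                    per_cluster = 100L, super_sep = 10,
                                    sub_sep = 3, noise_sd = 1, seed = 1L) {
  if (n_super < 1 || n_sub < 1 || per_cluster < 1) {
    stop("cluster counts and sizes must be positive")
  }
  if (dim < n_super) stop("`dim` must be at least `n_super`")
  if (!(super_sep > sub_sep && sub_sep > noise_sd)) {
    warning("hierarchy may not be realizable: expected super_sep > sub_sep > noise_sd")
  }
  set.seed(seed)
  # orthogonal axes scaled so all pairwise super-center distances = super_sep
  supers <- diag(super_sep / sqrt(2), dim)[, seq_len(n_super), drop = FALSE]
  n <- n_super * n_sub * per_cluster
  x <- matrix(0, n, dim)
  super_lab <- integer(n)
  sub_lab <- integer(n)
  centers <- vector("list", n_super * n_sub)
  row <- 0L
  for (s in seq_len(n_super)) {
    for (b in seq_len(n_sub)) {
      dir_ <- stats::rnorm(dim)
      dir_ <- dir_ / sqrt(sum(dir_^2))
      ctr <- supers[, s] + sub_sep * dir_
      centers[[(s - 1L) * n_sub + b]] <- ctr
      idx <- row + seq_len(per_cluster)
      x[idx, ] <- matrix(ctr, per_cluster, dim, byrow = TRUE) +
        matrix(stats::rnorm(per_cluster * dim, sd = noise_sd),
               per_cluster, dim)
      super_lab[idx] <- s
      sub_lab[idx] <- b
      row <- row + per_cluster
    }
  }
  list(data = x, super = super_lab, sub = sub_lab, centers = centers)
}

# Unit branch directions of the Y backbone: the trunk runs along axis 1;
# branch b leaves the branch point at 45 degrees into the plane spanned by
# axis 1 and axis b + 1.
trajectory_directions <- function(n_branches, dim) {
  v0 <- c(1, rep(0, dim - 1L))
  branches <- lapply(seq_len(n_branches), function(b) {
    v <- rep(0, dim)
    v[1L] <- cos(pi / 4)
    v[b + 1L] <- sin(pi / 4)
    v
  })
  list(trunk = v0, branches = branches)
}

#' Backbone position at a given pseudotime
#'
#' Noise-free coordinates of the Y-shaped backbone used by
#' [generate_trajectory_data]: the trunk spans pseudotime `[0, 0.5]` along
#' the first axis; each branch spans `(0.5, 1]` leaving the branch point at a
#' 45-degree angle. Exposed so downstream geometry (arc-chord distances,
#' branch angles) can be computed in closed form.
#'
#' @param t_pseudo Pseudotime in `[0, 1]`.
#' @param branch Branch index (ignored while `t_pseudo <= 0.5`).
#' @param n_branches,dim As in [generate_trajectory_data].
#' @return Numeric vector of length `dim`.
#' @export
trajectory_backbone <- function(t_pseudo, branch = 1L, n_branches = 2L,
                                dim = 10L) {
  stopifnot(t_pseudo >= 0, t_pseudo <= 1)
  dirs <- trajectory_directions(n_branches, dim)
  if (t_pseudo <= 0.5) {
    t_pseudo * dirs$trunk
  } else {
    0.5 * dirs$trunk + (t_pseudo - 0.5) * dirs$branches[[branch]]
  }
}

#' Bifurcating trajectory data
#'
#' Cells placed along a Y-shaped piecewise-linear backbone: a common trunk
#' for pseudotime in `[0, 0.5]`, after which each cell continues along one of
#' `n_branches` diverging lineages until pseudotime 1. Pseudotime is sampled
#' uniformly along arc length and isotropic Gaussian noise is added. This
#' stands in for differentiating single-cell data (e.g. T cells splitting
#' into two lineages) where the intrinsic structure is a progression, not a
#' set of clusters.
#'
#' @param n_branches Number of lineages after the branch point (default 2).
#' @param dim Ambient dimension; must exceed `n_branches`.
#' @param n_cells Number of rows.
#' @param noise_sd Isotropic noise standard deviation (default 0.05; the
#'   backbone has total arc length 1).
#' @param seed Integer seed.
#' @return List with `data` (`n_cells` x `dim`), `branch` (character:
#'   `"trunk"` or `"branchB"`), `branch_id` (0 for trunk, `b` for branch `b`),
#'   and `pseudotime` in `[0, 1]`.
#' @export
generate_trajectory_data <- function(n_branches = 2L, dim = 10L,
                                     n_cells = 1000L, noise_sd = 0.05,
                                     seed = 1L) {
  if (n_branches < 2) stop("`n_branches` must be >= 2 (a bifurcation)")
  if (dim < n_branches + 1L) stop("`dim` must be at least n_branches + 1")
  if (n_cells < 1) stop("`n_cells` must be positive")
  set.seed(seed)
  t_pseudo <- stats::runif(n_cells)
  branch_choice <- sample.int(n_branches, n_cells, replace = TRUE)
  dirs <- trajectory_directions(n_branches, dim)
  x <- matrix(0, n_cells, dim)
  on_trunk <- t_pseudo <= 0.5
  x[on_trunk, ] <- outer(t_pseudo[on_trunk], dirs$trunk)
  for (b in seq_len(n_branches)) {
    sel <- !on_trunk & branch_choice == b
    if (any(sel)) {
      x[sel, ] <- matrix(0.5 * dirs$trunk, sum(sel), dim, byrow = TRUE) +
        outer(t_pseudo[sel] - 0.5, dirs$branches[[b]])
    }
  }
  x <- x + matrix(stats::rnorm(n_cells * dim, sd = noise_sd), n_cells, dim)
  branch_id <- ifelse(on_trunk, 0L, branch_choice)
  branch <- ifelse(on_trunk, "trunk", paste0("branch", branch_choice))
  list(data = x, branch = branch, branch_id = branch_id,
       pseudotime = t_pseudo)
}
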