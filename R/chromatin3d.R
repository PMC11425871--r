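# Compartment-degree (chromatin activity) estimation from Hi-C and
# bead-on-string 3D reconstruction under connectivity + radial-activity
# restraints.

#' Construct a contact matrix
#'
#' @param chromosome chromosome name.
#' @param counts symmetric non-negative square matrix of contact counts.
#' @param bin_size_bp bin size in bp (default 500 kb).
#' @return A `contact_matrix` object.
#' @export
contact_matrix <- function(chromosome, counts, bin_size_bp = 500000L) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || nrow(counts) < 2L)
    abort_input("counts must be square with >= 2 bins")
  if (any(counts < 0) || any(!is.finite(counts)))
    abort_input("counts must be finite and non-negative")
  if (max(abs(counts - t(counts))) > 1e-8)
    abort_input("counts must be symmetric")
  structure(list(chromosome = chromosome, bin_size_bp = as.integer(bin_size_bp),
                 counts = unname(counts)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix %s: %d bins @ %d bp, total count %g\n",
              x$chromosome, nrow(x$counts), x$bin_size_bp, sum(x$counts)))
  invisible(x)
}

# Observed/expected normalisation: each cell divided by the mean count of
# its genomic-distance diagonal. Diagonals with fewer than 3 cells are
# pooled with the nearest populated diagonal.
oe_normalize <- function(counts) {
  n <- nrow(counts)
  sep <- abs(row(counts) - col(counts))
  expected <- numeric(n - 1L)
  cells <- tabulate(sep[sep > 0] + 0L, nbins = n - 1L) # count per separation
  sums <- vapply(seq_len(n - 1L), function(s) sum(counts[sep == s]), 1.0)
  pooled_ok <- cells >= 3L
  for (s in seq_len(n - 1L)) {
    if (pooled_ok[s]) {
      expected[s] <- sums[s] / cells[s]
    } else {
      near <- which(pooled_ok)
      if (length(near) == 0L) {
        expected[s] <- sums[s] / cells[s]
      } else {
        j <- near[which.min(abs(near - s))]
        expected[s] <- (sums[s] + sums[j]) / (cells[s] + cells[j])
      }
    }
  }
  oe <- matrix(1, n, n)
  nz <- sep > 0
  exp_cell <- expected[sep[nz]]
  oe[nz] <- ifelse(exp_cell > 0, counts[nz] / exp_cell, 0)
  diag(oe) <- 1
  oe
}

#' Compartment degree (chromatin activity) from a Hi-C matrix
#'
#' Classic A/B-compartment eigenvector analysis: (1) observed/expected
#' normalisation with the mean count per genomic-distance diagonal as the
#' expected value; (2) Pearson correlation matrix of the O/E matrix;
#' (3) activity = leading eigenvector of the correlation matrix;
#' (4) sign orientation. If a per-bin `marker` track (e.g. gene density) is
#' supplied the eigenvector is flipped so it correlates positively with the
#' marker; otherwise so that bins in the top decile of row sums (contact-rich
#' bins) have positive mean activity. Bins with zero-variance O/E rows are
#' excluded from the correlation and get activity 0.
#'
#' @param matrix a `contact_matrix`.
#' @param marker optional numeric length-n orientation track.
#' @return An `activity_profile`: list(chromosome, activity, radial_target
#'   = NULL, excluded_bins).
#' @export
compartment_degree <- function(matrix, marker = NULL) {
  stopifnot(inherits(matrix, "contact_matrix"))
  counts <- matrix$counts
  n <- nrow(counts)
  if (sum(counts) == 0) abort_input("all-zero contact matrix")
  rs <- rowSums(counts)
  if (sum(rs > 0) < 2L) abort_input("need >= 2 bins with nonzero marginals")

  oe <- oe_normalize(counts)
  vars <- apply(oe, 1L, stats::var)
  keep <- which(vars > 0 & rs > 0)
  activity <- numeric(n)
  if (length(keep) >= 2L) {
    cc <- stats::cor(t(oe[keep, keep, drop = FALSE]))
    cc[!is.finite(cc)] <- 0
    ev <- eigen(cc, symmetric = TRUE)
    v <- ev$vectors[, 1L]
    activity[keep] <- v
    # orientation: unique sign via marker track or contact-rich bins
    flip <- if (!is.null(marker)) {
      stopifnot(length(marker) == n)
      ok <- stats::sd(marker[keep]) > 0 && stats::sd(activity[keep]) > 0
      ok && stats::cor(activity[keep], marker[keep]) < 0
    } else {
      top <- keep[rs[keep] >= stats::quantile(rs[keep], 0.9)]
      mean(activity[top]) < 0
    }
    if (isTRUE(flip)) activity <- -activity
  }
  structure(list(chromosome = matrix$chromosome, activity = activity,
                 radial_target = NULL, excluded_bins = setdiff(seq_len(n), keep)),
            class = "activity_profile")
}

#' Assign radial targets from activity
#'
#' Rank-based mapping of activity to a target distance from the nuclear
#' center: the most active bin is placed at `R * m` (innermost), the least
#' active at `R`, linearly in fractional rank. Ties share their mean rank.
#'
#' @param profile an `activity_profile` (or numeric activity vector).
#' @param nucleus_radius nuclear radius R.
#' @param min_radius_frac innermost target as a fraction of R (default 0.1).
#' @return The profile with `radial_target` filled (targets in (0, R]).
#' @export
assign_radial_targets <- function(profile, nucleus_radius,
                                  min_radius_frac = 0.1) {
  act <- if (inherits(profile, "activity_profile")) profile$activity else profile
  if (any(!is.finite(act))) abort_input("activity must be finite")
  n <- length(act)
  q <- if (n == 1L) 0.5 else (rank(act, ties.method = "average") - 1) / (n - 1)
  target <- nucleus_radius * (1 - q * (1 - min_radius_frac))
  if (inherits(profile, "activity_profile")) {
    profile$radial_target <- target
    profile
  } else {
    structure(list(chromosome = NA_character_, activity = act,
                   radial_target = target, excluded_bins = integer()),
              class = "activity_profile")
  }
}

#' Reconstruction configuration
#'
#' Force constants and optimiser settings for [reconstruct()]. Defaults:
#' harmonic bond (k = 100) at unit bond length, harmonic radial bias
#' (k = 10), soft-core repulsion (k = 1, cutoff = bond length), 5,000 steps
#' of annealed gradient descent in a nucleus of radius 10 (whole-genome
#' 500 kb scale). Pairwise contact-distance restraints (targets
#' proportional to `count^(-1/alpha)`) are off by default.
#'
#' @param bond_length,k_bond,k_radial,k_repulsion,repulsion_cutoff energy
#'   parameters (force constants >= 0).
#' @param n_steps,step_size optimiser schedule (annealed: the step size and
#'   thermal noise decay geometrically to ~1% of their initial values).
#' @param noise0 initial Langevin noise amplitude.
#' @param polish_steps noise-free pure-descent steps appended after the
#'   annealing schedule to settle bonds into their minima.
#' @param seed integer seed for initialisation and noise.
#' @param use_pairwise_restraints logical; add Hi-C distance restraints.
#' @param k_pair pairwise restraint force constant.
#' @param alpha distance-contact exponent for pairwise targets.
#' @param energy_tol convergence tolerance on the relative energy change
#'   between the last two checkpoints.
#' @return A `reconstruction_config` list.
#' @export
reconstruction_config <- function(bond_length = 1, k_bond = 100,
                                  k_radial = 10, k_repulsion = 1,
                                  repulsion_cutoff = bond_length,
                                  n_steps = 5000L, step_size = 4e-3,
                                  noise0 = 0.03, polish_steps = 800L, seed = 1L,
                                  use_pairwise_restraints = FALSE,
                                  k_pair = 1, alpha = 1,
                                  energy_tol = 0.01) {
  if (any(c(k_bond, k_radial, k_repulsion, k_pair) < 0))
    abort_input("force constants must be >= 0")
  if (n_steps < 1L) abort_input("n_steps must be >= 1")
  structure(list(bond_length = bond_length, k_bond = k_bond,
                 k_radial = k_radial, k_repulsion = k_repulsion,
                 repulsion_cutoff = repulsion_cutoff, n_steps = as.integer(n_steps),
                 step_size = step_size, noise0 = noise0,
                 polish_steps = as.integer(polish_steps), seed = as.integer(seed),
                 use_pairwise_restraints = use_pairwise_restraints,
                 k_pair = k_pair, alpha = alpha, energy_tol = energy_tol),
            class = "reconstruction_config")
}

# Energy and gradient of the full potential, vectorised over all beads.
# coords: N x 3; chain_id: integer per bead; targets: radial targets;
# pair_target: N x N matrix of pairwise target distances (NA = no restraint).
# Pair terms use the identity grad_i = sum_j C_ij (x_i - x_j)
#   = rowSums(C) * x_i - (C %*% X)_i for a symmetric coefficient matrix C.
.energy_grad <- function(coords, chain_id, targets, cfg, pair_target) {
  N <- nrow(coords)
  grad <- matrix(0, N, 3)
  energy <- 0

  # bonds: consecutive beads of the same chain
  bonded <- which(chain_id[-N] == chain_id[-1L])
  bond_mask <- NULL
  if (length(bonded)) {
    dvec <- coords[bonded + 1L, , drop = FALSE] - coords[bonded, , drop = FALSE]
    dlen <- pmax(sqrt(rowSums(dvec^2)), 1e-12)
    dev <- dlen - cfg$bond_length
    energy <- energy + cfg$k_bond * sum(dev^2)
    gb <- dvec * (2 * cfg$k_bond * dev / dlen)
    grad[bonded, ] <- grad[bonded, ] - gb
    grad[bonded + 1L, ] <- grad[bonded + 1L, ] + gb
  }

  # radial bias
  r <- pmax(sqrt(rowSums(coords^2)), 1e-12)
  rdev <- r - targets
  energy <- energy + cfg$k_radial * sum(rdev^2)
  grad <- grad + coords * (2 * cfg$k_radial * rdev / r)

  need_D <- cfg$k_repulsion > 0 || !is.null(pair_target)
  if (need_D) {
    D <- as.matrix(stats::dist(coords))
    Dsafe <- pmax(D, 1e-9)
    C <- matrix(0, N, N) # symmetric pair-force coefficients

    # soft-core repulsion, U = k (1 - d/cutoff)^2 for d < cutoff,
    # excluding bonded neighbours
    if (cfg$k_repulsion > 0) {
      close <- D < cfg$repulsion_cutoff
      diag(close) <- FALSE
      if (length(bonded)) {
        close[cbind(bonded, bonded + 1L)] <- FALSE
        close[cbind(bonded + 1L, bonded)] <- FALSE
      }
      if (any(close)) {
        pen <- (1 - D / cfg$repulsion_cutoff) * close
        energy <- energy + cfg$k_repulsion * sum(pen[upper.tri(pen)]^2)
        C <- C - 2 * cfg$k_repulsion * pen / (cfg$repulsion_cutoff * Dsafe)
      }
    }

    # optional pairwise Hi-C distance restraints, U = k_pair (d - t)^2
    if (!is.null(pair_target)) {
      has <- !is.na(pair_target)
      devp <- (D - ifelse(has, pair_target, 0)) * has
      energy <- energy + cfg$k_pair * sum(devp[upper.tri(devp)]^2)
      C <- C + 2 * cfg$k_pair * devp / Dsafe * has
    }

    grad <- grad + coords * rowSums(C) - C %*% coords
  }

  list(energy = energy, grad = grad)
}

#' Reconstruct a 3D genome structure from Hi-C
#'
#' Minimises a bead-on-string potential — harmonic bonds between consecutive
#' beads, a harmonic bias pulling each bead's radius to its activity-derived
#' target, soft-core excluded volume, and (optionally) harmonic pairwise
#' restraints with target distances proportional to `count^(-1/alpha)` —
#' by annealed overdamped-Langevin gradient descent from a random confined
#' initialisation. Chains interact only through repulsion and the shared
#' nuclear confinement. The best-energy conformation visited is returned;
#' the best-so-far energy is non-increasing across annealing checkpoints.
#'
#' @param matrices named list of `contact_matrix`, one per chromosome.
#' @param profiles named list of `activity_profile` with radial targets
#'   filled, parallel to `matrices`.
#' @param config a [reconstruction_config()].
#' @param nucleus_radius nuclear radius R used for initialisation and as
#'   the maximal radial target scale.
#' @param cell_line label stored on the returned structure.
#' @return A `genome_structure` with attributes `energy_trace` (checkpoint
#'   energies of the best-so-far conformation), `energy_terms` (final
#'   decomposition) and `converged` (logical).
#' @export
reconstruct <- function(matrices, profiles, config = reconstruction_config(),
                        nucleus_radius = 10, cell_line = "reconstructed") {
  stopifnot(length(matrices) == length(profiles))
  if (is.null(names(matrices)))
    names(matrices) <- vapply(matrices, function(m) m$chromosome, "")
  nbins <- vapply(matrices, function(m) nrow(m$counts), 1L)
  chain_id <- rep(seq_along(matrices), nbins)
  targets <- unlist(lapply(profiles, function(p) {
    if (is.null(p$radial_target)) abort_input("profile lacks radial targets")
    p$radial_target
  }), use.names = FALSE)
  N <- sum(nbins)
  offset <- c(0L, cumsum(nbins))

  pair_target <- NULL
  if (isTRUE(config$use_pairwise_restraints)) {
    pair_target <- matrix(NA_real_, N, N)
    for (i in seq_along(matrices)) {
      cnt <- matrices[[i]]$counts
      pos <- cnt > 0
      diag(pos) <- FALSE
      tgt <- matrix(NA_real_, nrow(cnt), ncol(cnt))
      tgt[pos] <- cnt[pos]^(-1 / config$alpha)
      # calibrate the scale so adjacent-bead targets match the bond length
      adj <- tgt[cbind(seq_len(nrow(cnt) - 1L), seq_len(nrow(cnt) - 1L) + 1L)]
      scale_c <- config$bond_length / stats::median(adj, na.rm = TRUE)
      rng <- (offset[i] + 1L):offset[i + 1L]
      pair_target[rng, rng] <- tgt * scale_c
    }
  }

  n_check <- 20L
  check_at <- unique(round(seq(1, config$n_steps, length.out = n_check)))
  res <- with_seed(config$seed, {
    coords <- matrix(stats::rnorm(N * 3), N, 3)
    coords <- coords / sqrt(rowSums(coords^2)) *
      (stats::runif(N)^(1 / 3) * nucleus_radius)
    best <- coords
    best_e <- Inf
    trace <- numeric(0)
    decay <- 0.01^(1 / config$n_steps)
    eta <- config$step_size
    noise <- config$noise0
    for (t in seq_len(config$n_steps)) {
      eg <- .energy_grad(coords, chain_id, targets, config, pair_target)
      g <- eg$grad
      gn <- sqrt(sum(g^2) / N)
      if (gn > 10) g <- g * (10 / gn) # clip to keep descent stable
      coords <- coords - eta * g +
        matrix(stats::rnorm(N * 3, sd = noise), N, 3)
      eta <- eta * decay
      noise <- noise * decay
      if (t %in% check_at) {
        e_now <- .energy_grad(coords, chain_id, targets, config, pair_target)$energy
        if (e_now < best_e) {
          best_e <- e_now
          best <- coords
        }
        trace <- c(trace, best_e)
      }
    }
    # noise-free polish from the best conformation visited, constant step
    coords <- best
    n_pol <- config$polish_steps %||% 0L
    if (n_pol > 0L) {
      eta_p <- config$step_size / 4
      half <- n_pol %/% 2L
      for (t in seq_len(n_pol)) {
        eg <- .energy_grad(coords, chain_id, targets, config, pair_target)
        g <- eg$grad
        gn <- sqrt(sum(g^2) / N)
        if (gn > 10) g <- g * (10 / gn)
        coords <- coords - eta_p * g
        if (t == half || t == n_pol) {
          e_now <- eg$energy
          if (e_now < best_e) {
            best_e <- e_now
            best <- coords
          }
          trace <- c(trace, best_e)
        }
      }
    }
    list(best = best, trace = trace)
  })

  k <- length(res$trace)
  converged <- k >= 2L &&
    abs(res$trace[k] - res$trace[k - 1L]) <=
      config$energy_tol * max(1, abs(res$trace[k]))
  if (!converged)
    warning("reconstruction did not converge within n_steps", call. = FALSE)

  chains <- lapply(seq_along(matrices), function(i) {
    m <- res$best[(offset[i] + 1L):offset[i + 1L], , drop = FALSE]
    dimnames(m) <- list(NULL, c("x", "y", "z"))
    m
  })
  names(chains) <- names(matrices)
  out <- structure(
    list(cell_line = cell_line, chains = chains,
         nucleus_radius = nucleus_radius,
         bin_size_bp = matrices[[1]]$bin_size_bp),
    class = "genome_structure")
  final <- .energy_grad(res$best, chain_id, targets, config, pair_target)
  attr(out, "energy_trace") <- res$trace
  attr(out, "final_energy") <- final$energy
  attr(out, "converged") <- converged
  out
}

#' Look up one bead's coordinates and radius
#'
#' @param structure a `genome_structure`.
#' @param chromosome chromosome name.
#' @param bin_index 0-based bin index along the chromosome.
#' @return Named numeric (x, y, z, radius) with radius the Euclidean norm.
#' @export
bead_lookup <- function(structure, chromosome, bin_index) {
  stopifnot(inherits(structure, "genome_structure"))
  chain <- structure$chains[[chromosome]]
  if (is.null(chain))
    abort_input("chromosome not in structure: ", chromosome)
  if (bin_index < 0L || bin_index >= nrow(chain))
    abort_input(sprintf("bin %d out of range for %s (0..%d)",
                        bin_index, chromosome, nrow(chain) - 1L))
  p <- chain[bin_index + 1L, ]
  c(x = p[["x"]], y = p[["y"]], z = p[["z"]],
    radius = sqrt(sum(p^2)))
}

#' Pairwise distance matrix of one chain
#' @param structure a `genome_structure`.
#' @param chromosome chromosome name.
#' @return Dense symmetric distance matrix.
#' @export
chain_distances <- function(structure, chromosome) {
  chain <- structure$chains[[chromosome]]
  if (is.null(chain)) abort_input("chromosome not in structure: ", chromosome)
  as.matrix(stats::dist(chain))
}

#' All bead radii of a structure
#' @param structure a `genome_structure`.
#' @return data.frame (chromosome, bin_index, radius).
#' @export
bead_radii <- function(structure) {
  do.call(rbind, lapply(names(structure$chains), function(chr) {
    m <- structure$chains[[chr]]
    data.frame(chromosome = chr, bin_index = seq_len(nrow(m)) - 1L,
               radius = sqrt(rowSums(m^2)), stringsAsFactors = FALSE)
  }))
}
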