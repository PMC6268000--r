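#' Generate a compact toy subunit
#'
#' A deterministic (per seed) compact self-avoiding backbone-site chain:
#' sites laid out on a serpentine cubic-lattice path with 0.38 nm spacing
#' (the C-alpha virtual bond length) plus a small seeded jitter, so the
#' minimum inter-site distance stays above 0.35 nm and the radius of
#' gyration grows like n^(1/3). Polarity labels alternate apolar/polar along
#' the chain in a fixed pattern.
#'
#' @param n_residues number of residues (default 72, the ubiquitin analysis
#'   range).
#' @param seed jitter seed.
#' @param spacing lattice spacing in nm.
#' @return list with `xyz` (n x 3, nm), `polarity`, `resnames`.
#' @export
make_toy_subunit <- function(n_residues = 72, seed = 1, spacing = 0.38) {
  if (n_residues < 1) stop("n_residues must be >= 1")
  side <- ceiling(n_residues^(1 / 3))
  xyz <- matrix(0, n_residues, 3)
  k <- 0L
  for (z in 0:(side - 1)) {
    ys <- 0:(side - 1); if (z %% 2 == 1) ys <- rev(ys)
    for (iy in seq_along(ys)) {
      y <- ys[iy]
      xs <- 0:(side - 1)
      # serpentine: reverse x on every other visited row so consecutive
      # sites stay lattice neighbors
      if ((z * side + (iy - 1)) %% 2 == 1) xs <- rev(xs)
      for (x in xs) {
        k <- k + 1L
        if (k > n_residues) break
        xyz[k, ] <- c(x, y, z) * spacing
      }
      if (k > n_residues) break
    }
    if (k > n_residues) break
  }
  jit <- with_seed(seed,
                   matrix(runif(3 * n_residues, -0.005, 0.005), ncol = 3))
  xyz <- xyz + jit
  xyz <- sweep(xyz, 2, colMeans(xyz))
  list(xyz = xyz,
       polarity = rep(c("apolar", "polar"), length.out = n_residues),
       resnames = rep(c("ALA", "SER"), length.out = n_residues))
}

#' Rotation matrix from Euler angles
#' @param angles length-3 vector (radians), applied as Rz(c) Ry(b) Rx(a).
#' @return 3 x 3 rotation matrix.
#' @export
rotation_matrix <- function(angles) {
  a <- angles[1]; b <- angles[2]; cth <- angles[3]
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(cth), -sin(cth), 0), c(sin(cth), cos(cth), 0),
              c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Define a conformational basin
#'
#' A rigid-body pose of the proximal subunit relative to the distal one,
#' with an occupancy weight and isotropic per-site Gaussian noise.
#'
#' @param translation length-3 translation (nm) applied to the proximal
#'   subunit.
#' @param rotation 3 x 3 rotation matrix or length-3 Euler angles (radians).
#' @param weight occupancy weight (> 0).
#' @param noise_sd per-site positional noise standard deviation (nm, >= 0).
#' @return object of class `basin_spec`.
#' @export
basin_spec <- function(translation, rotation = diag(3), weight = 1,
                       noise_sd = 0.02) {
  if (length(rotation) == 3) rotation <- rotation_matrix(rotation)
  if (weight <= 0) stop("basin weight must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(translation = as.numeric(translation), rotation = rotation,
                 weight = weight, noise_sd = noise_sd),
            class = "basin_spec")
}

#' Specify a synthetic two-domain ensemble
#'
#' @param basins list of [basin_spec()]s.
#' @param n_frames frames to sample (>= 1).
#' @param seed RNG seed.
#' @param n_residues residues per subunit (default 72).
#' @param subunit_seed seed of the toy subunit template.
#' @param linker_cap optional cap (nm) on the distance between the distal
#'   C-terminal site and the proximal N-terminal site; frames violating it
#'   are resampled.
#' @return object of class `synthetic_ensemble_spec`.
#' @export
synthetic_ensemble_spec <- function(basins, n_frames, seed = 1,
                                    n_residues = 72, subunit_seed = 1,
                                    linker_cap = NULL) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (!length(basins)) stop("at least one basin is required")
  if (!all(vapply(basins, inherits, TRUE, "basin_spec")))
    stop("basins must be basin_spec objects")
  structure(list(basins = basins, n_frames = as.integer(n_frames),
                 seed = seed, n_residues = n_residues,
                 subunit_seed = subunit_seed, linker_cap = linker_cap),
            class = "synthetic_ensemble_spec")
}

.pose_proximal <- function(template, basin) {
  t(basin$rotation %*% t(template)) +
    matrix(basin$translation, nrow(template), 3, byrow = TRUE)
}

#' Sample a synthetic conjugate ensemble
#'
#' Draws each frame by choosing a basin with probability proportional to its
#' weight, posing the proximal subunit rigidly and adding isotropic Gaussian
#' noise to every site of both subunits. Ground-truth basin labels are
#' returned alongside the trajectory so downstream recovery tests never need
#' to re-infer them. Noiseless poses are checked for inter-subunit clashes
#' (minimum site distance must exceed 0.1 nm).
#'
#' @param spec a [synthetic_ensemble_spec()].
#' @return list with `trajectory` (a [conjugate_trajectory()]) and `labels`
#'   (integer basin index per frame).
#' @export
sample_conjugate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "synthetic_ensemble_spec"))
  tmpl <- make_toy_subunit(spec$n_residues, seed = spec$subunit_seed)
  nb <- length(spec$basins)
  for (b in seq_len(nb)) {
    prox0 <- .pose_proximal(tmpl$xyz, spec$basins[[b]])
    mind <- min(.cross_dist(tmpl$xyz, prox0))
    if (mind <= 0.1)
      stop(sprintf("basin %d clashes: noiseless minimum distance %.3g nm",
                   b, mind))
  }
  w <- vapply(spec$basins, `[[`, numeric(1), "weight")
  n <- spec$n_residues
  nf <- spec$n_frames
  parts <- data.frame(
    subunit = rep(c("distal", "proximal"), each = n),
    resno = rep(seq_len(n), 2),
    resname = rep(tmpl$resnames, 2),
    name = "BB", backbone = TRUE,
    polarity = rep(tmpl$polarity, 2),
    radius = 0.23, stringsAsFactors = FALSE)
  # all residues of the toy chain are analysis residues
  topo <- conjugate_topology(parts, analysis_range = n)
  xyz <- array(0, dim = c(2 * n, 3, nf))
  labels <- integer(nf)
  poses <- lapply(spec$basins, function(b) .pose_proximal(tmpl$xyz, b))
  with_seed(spec$seed, {
    labels <- sample.int(nb, nf, replace = TRUE, prob = w / sum(w))
    for (f in seq_len(nf)) {
      rejects <- 0L
      repeat {
        b <- spec$basins[[labels[f]]]
        noise_d <- if (b$noise_sd > 0)
          matrix(rnorm(3 * n, sd = b$noise_sd), ncol = 3) else 0
        noise_p <- if (b$noise_sd > 0)
          matrix(rnorm(3 * n, sd = b$noise_sd), ncol = 3) else 0
        dxyz <- tmpl$xyz + noise_d
        pxyz <- poses[[labels[f]]] + noise_p
        if (!is.null(spec$linker_cap) &&
            sqrt(sum((dxyz[n, ] - pxyz[1, ])^2)) > spec$linker_cap) {
          rejects <- rejects + 1L
          if (rejects >= 200L)
            stop("basin acceptance rate under the linker cap is below 1%; ",
                 "loosen the cap or move the basins closer")
          next
        }
        xyz[, , f] <- rbind(dxyz, pxyz)
        break
      }
    }
  })
  list(trajectory = conjugate_trajectory(topo, xyz,
                                         times = as.numeric(seq_len(nf) - 1)),
       labels = labels)
}

#' Write ground-truth basin labels as TSV
#' @param labels integer labels from [sample_conjugate_ensemble()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  write.table(data.frame(frame = seq_along(labels), basin = labels), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
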