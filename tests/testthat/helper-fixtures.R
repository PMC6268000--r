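# shared in-code fixtures

# minimal topology: one backbone bead per residue, nd + np residues
toy_topology <- function(nd, np, radius = 0.23, analysis_range = max(nd, np),
                         polarity = NULL) {
  n <- nd + np
  if (is.null(polarity))
    polarity <- rep(c("apolar", "polar"), length.out = n)
  conjugate_topology(data.frame(
    subunit = rep(c("distal", "proximal"), c(nd, np)),
    resno = c(seq_len(nd), seq_len(np)),
    resname = "ALA", name = "BB", backbone = TRUE,
    polarity = polarity, radius = radius, stringsAsFactors = FALSE),
    analysis_range = analysis_range)
}

toy_frame <- function(xyz) conjugate_frame(as.matrix(xyz))

# random two-subunit frame with controlled seed
random_frame <- function(nd, np, seed, spread = 3) {
  set.seed(seed)
  toy_frame(matrix(runif(3 * (nd + np), -spread, spread), ncol = 3))
}

# brute-force O(n^2) RMD oracle: plain double loop, no shared code with the
# package kernel
rmd_bruteforce <- function(xyz, nd, np) {
  A <- xyz[seq_len(nd), , drop = FALSE]
  B <- xyz[nd + seq_len(np), , drop = FALSE]
  outA <- rep(Inf, nd); outB <- rep(Inf, np)
  for (i in seq_len(nd)) for (j in seq_len(np)) {
    d <- sqrt(sum((A[i, ] - B[j, ])^2))
    if (d < outA[i]) outA[i] <- d
    if (d < outB[j]) outB[j] <- d
  }
  c(outA, outB)
}

# hand-constructed density2d with arbitrary point masses: one bin per point
point_mass_density <- function(xy, mass, half = 0.5) {
  stopifnot(nrow(xy) == 1) # single point mass
  structure(list(x_edges = c(xy[1, 1] - half, xy[1, 1] + half),
                 y_edges = c(xy[1, 2] - half, xy[1, 2] + half),
                 mass = matrix(mass, 1, 1),
                 counts = matrix(1L, 1, 1), n = 1L),
            class = "density2d")
}

# single-basin ensemble with the subunits in contact (buried interface)
contact_ensemble <- function(n_frames = 1, n_residues = 8, seed = 19,
                             noise_sd = 0.01) {
  spec <- synthetic_ensemble_spec(
    basins = list(basin_spec(translation = c(1.0, 0, 0), weight = 1,
                             noise_sd = noise_sd)),
    n_frames = n_frames, seed = seed, n_residues = n_residues)
  sample_conjugate_ensemble(spec)
}

# small synthetic two-basin ensemble used by several tests
two_basin_ensemble <- function(n_frames = 500, seed = 11, n_residues = 12,
                               weights = c(0.7, 0.3), noise_sd = 0.05) {
  spec <- synthetic_ensemble_spec(
    basins = list(
      basin_spec(translation = c(2.5, 0, 0), weight = weights[1],
                 noise_sd = noise_sd),
      basin_spec(translation = c(0, 3.5, 0), rotation = c(0, 0, pi / 2),
                 weight = weights[2], noise_sd = noise_sd)),
    n_frames = n_frames, seed = seed, n_residues = n_residues)
  sample_conjugate_ensemble(spec)
}
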