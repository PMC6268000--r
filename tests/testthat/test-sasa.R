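# closed-form accessible area of two intersecting spheres (radii already
# expanded by the probe): total area minus the spherical caps removed
two_sphere_area <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h1 + 4 * pi * R2^2 - 2 * pi * R2 * h2
}

test_that("an isolated sphere reproduces 4*pi*(rho + probe)^2 within 1%", {
  topo <- toy_topology(1, 1, radius = 0.2)
  fr <- toy_frame(rbind(c(0, 0, 0), c(10, 0, 0)))
  s <- sasa_per_residue(fr, topo, probe_radius = 0.14, n_points = 960)
  expect_equal(s$particle_area[1], 4 * pi * (0.2 + 0.14)^2,
               tolerance = 0.01)
  # far-separated spheres are additive
  expect_equal(sum(s$particle_area), 2 * 4 * pi * 0.34^2, tolerance = 0.01)
  expect_equal(unname(s$residue_area["distal:1"]), s$particle_area[1])
})

test_that("two overlapping spheres match the spherical-cap formula within 1%", {
  probe <- 0.14
  r1 <- 0.2; r2 <- 0.25
  R1 <- r1 + probe; R2 <- r2 + probe
  topo <- conjugate_topology(data.frame(
    subunit = c("distal", "proximal"), resno = c(1, 1), resname = "ALA",
    name = "BB", backbone = TRUE, polarity = c("apolar", "polar"),
    radius = c(r1, r2), stringsAsFactors = FALSE), analysis_range = 1)
  for (d in c(0.3, 0.45, 0.6)) {
    fr <- toy_frame(rbind(c(0, 0, 0), c(d, 0, 0)))
    s <- sasa_per_residue(fr, topo, probe_radius = probe, n_points = 960)
    expect_equal(sum(s$particle_area), two_sphere_area(R1, R2, d),
                 tolerance = 0.01)
  }
})

test_that("SASA scales as length squared under coordinate+radius scaling", {
  ens <- two_basin_ensemble(n_frames = 1, n_residues = 6)
  fr <- get_frame(ens$trajectory, 1)
  topo <- ens$trajectory$topology
  s1 <- sasa_per_residue(fr, topo, probe_radius = 0.2, n_points = 480)
  topo2 <- topo
  topo2$particles$radius <- topo$particles$radius * 2
  s2 <- sasa_per_residue(toy_frame(fr$xyz * 2), topo2, probe_radius = 0.4,
                         n_points = 480)
  expect_equal(s2$particle_area, 4 * s1$particle_area, tolerance = 1e-9)
})

test_that("missing radii are reported with the particle index", {
  topo <- toy_topology(2, 2)
  topo$particles$radius[3] <- NA
  fr <- random_frame(2, 2, seed = 1)
  expect_error(sasa_per_residue(fr, topo), "3")
})

test_that("far-separated subunits have zero interface area", {
  topo <- toy_topology(4, 4)
  set.seed(2)
  xyz <- rbind(matrix(runif(12, 0, 1), ncol = 3),
               matrix(runif(12, 0, 1), ncol = 3) + 50)
  ia <- interface_area(toy_frame(xyz), topo, probe_radius = 0.21,
                       n_points = 240)
  expect_equal(ia$sa_interface, 0)
  expect_equal(ia$a_sa, 0)
  expect_equal(ia$p_sa, 0)
})

test_that("interface area is symmetric under label swap and partitions into a-SA + p-SA", {
  ens <- contact_ensemble(n_frames = 3, n_residues = 8)
  topo <- ens$trajectory$topology
  fr <- get_frame(ens$trajectory, 1)
  ia <- interface_area(fr, topo, probe_radius = 0.21, n_points = 240)
  expect_gt(ia$sa_interface, 0)
  expect_equal(ia$a_sa + ia$p_sa, ia$sa_interface, tolerance = 1e-9)
  # swap subunit labels: Eq-1 value unchanged
  p <- topo$particles[, setdiff(names(topo$particles), "particle_id")]
  p$subunit <- ifelse(p$subunit == "distal", "proximal", "distal")
  topo_sw <- conjugate_topology(p, analysis_range = 8)
  ia_sw <- interface_area(fr, topo_sw, probe_radius = 0.21, n_points = 240)
  expect_equal(ia_sw$sa_interface, ia$sa_interface, tolerance = 1e-9)
})

test_that("Eq-1 subunit-total route equals the per-particle burial attribution", {
  ens <- contact_ensemble(n_frames = 1, n_residues = 8)
  topo <- ens$trajectory$topology
  fr <- get_frame(ens$trajectory, 1)
  probe <- 0.21; np <- 480
  ia <- interface_area(fr, topo, probe_radius = probe, n_points = np)
  # independent route: three whole-body SASA evaluations per Eq 1
  p <- topo$particles
  full <- sasa_per_residue(fr, topo, probe, np)
  di <- which(p$subunit == "distal"); pi_ <- which(p$subunit == "proximal")
  iso_d <- conjmap:::.sasa_cpp(fr$xyz[di, , drop = FALSE], p$radius[di],
                               probe, np, seq_along(di))
  iso_p <- conjmap:::.sasa_cpp(fr$xyz[pi_, , drop = FALSE], p$radius[pi_],
                               probe, np, seq_along(pi_))
  eq1 <- sum(iso_d) + sum(iso_p) - sum(full$particle_area)
  expect_equal(ia$sa_interface, eq1, tolerance = 1e-9)
})

test_that("interface_report summarizes per-frame interface statistics", {
  ens <- contact_ensemble(n_frames = 6, n_residues = 6)
  rep <- interface_report(ens$trajectory, probe_radius = 0.21,
                          n_points = 120, stride = 2)
  expect_equal(nrow(rep$frames), 3)
  expect_equal(unname(rep$mean["sa_interface"]),
               mean(rep$frames$sa_interface))
  expect_true(all(rep$frames$sa_interface >= 0))
})

test_that("patch accessibility is ~1 when subunits are apart and ~0 when buried", {
  n <- 8
  patches <- list(toy = patch_definition("toy", c(1, 2)))
  # far apart: nothing buried
  topo <- toy_topology(n, n)
  sub <- make_toy_subunit(n, seed = 2)
  xyz_far <- rbind(sub$xyz, sweep(sub$xyz, 2, c(60, 0, 0), "+"))
  traj_far <- conjugate_trajectory(topo, array(xyz_far, c(2 * n, 3, 1)))
  acc <- patch_accessibility(traj_far, patches, probe_radius = 0.21,
                             n_points = 240)
  expect_true(all(abs(acc$accessibility - 1) < 1e-9))
  # partner beads caged around the proximal patch residues (1 and 2)
  xyz_cover <- xyz_far
  offsets <- rbind(c(0.4, 0, 0), c(-0.4, 0, 0), c(0, 0.4, 0), c(0, -0.4, 0),
                   c(0, 0, 0.4), c(0, 0, -0.4), c(0.3, 0.3, 0),
                   c(-0.3, -0.3, 0))
  centers <- xyz_far[n + rep(1:2, length.out = n), ]
  xyz_cover[seq_len(n), ] <- centers + offsets[seq_len(n), ]
  traj_cover <- conjugate_trajectory(topo, array(xyz_cover, c(2 * n, 3, 1)))
  acc2 <- patch_accessibility(traj_cover, patches, probe_radius = 0.21,
                              n_points = 240)
  prox <- acc2$accessibility[acc2$subunit == "proximal"]
  expect_lt(prox, 0.6)
  expect_true(all(acc2$accessibility >= 0 & acc2$accessibility <= 1))
})

test_that("a patch buried in half the frames scores ~0.5 accessibility", {
  n <- 6
  sub <- make_toy_subunit(n, seed = 3)
  topo <- toy_topology(n, n)
  # frame A: far apart; frame B: distal chain sits on proximal residues 1-2
  far <- rbind(sub$xyz, sweep(sub$xyz, 2, c(40, 0, 0), "+"))
  near <- far
  target <- far[n + 1, ]
  near[seq_len(n), ] <- sweep(sub$xyz * 0.4, 2,
                              target + c(0.15, 0, 0), "+")
  xyz <- array(c(near, far), c(2 * n, 3, 2))
  traj <- conjugate_trajectory(topo, xyz)
  patches <- list(toy = patch_definition("toy", 1))
  acc <- patch_accessibility(traj, patches, probe_radius = 0.21,
                             n_points = 480)
  prox <- acc$accessibility[acc$subunit == "proximal"]
  burial_frame1 <- patch_accessibility(
    conjugate_trajectory(topo, array(near, c(2 * n, 3, 1))), patches,
    probe_radius = 0.21, n_points = 480)
  b1 <- burial_frame1$accessibility[burial_frame1$subunit == "proximal"]
  expect_equal(prox, (b1 + 1) / 2, tolerance = 1e-9)
  expect_lt(b1, 0.9)
})

test_that("zero reference patch SASA is an error", {
  n <- 4
  topo <- toy_topology(n, n)
  ens <- two_basin_ensemble(n_frames = 1, n_residues = n)
  patches <- list(bad = patch_definition("bad", 99))
  expect_error(patch_accessibility(ens$trajectory, patches,
                                   probe_radius = 0.21, n_points = 60),
               "reference SASA")
})

test_that("delta-SASA is zero for separated subunits and sums to the interface area", {
  topo <- toy_topology(5, 5)
  sub <- make_toy_subunit(5, seed = 4)
  far <- rbind(sub$xyz, sweep(sub$xyz, 2, c(30, 0, 0), "+"))
  traj <- conjugate_trajectory(topo, array(far, c(10, 3, 1)))
  prof <- delta_sasa_profile(traj, probe_radius = 0.21, n_points = 240)
  expect_true(all(prof$distal$mean == 0) && all(prof$proximal$mean == 0))
  # contact geometry: accounting identity against the interface area
  ens <- contact_ensemble(n_frames = 2, n_residues = 6)
  prof2 <- delta_sasa_profile(ens$trajectory, probe_radius = 0.21,
                              n_points = 240)
  ia <- interface_report(ens$trajectory, probe_radius = 0.21, n_points = 240)
  expect_equal(sum(prof2$distal$mean) + sum(prof2$proximal$mean),
               unname(ia$mean["sa_interface"]), tolerance = 1e-9)
  expect_true(all(prof2$distal$mean >= 0) && all(prof2$proximal$mean >= 0))
})

test_that("identical replicate runs give zero error bars; mismatched runs are refused", {
  ens <- contact_ensemble(n_frames = 2, n_residues = 4)
  runs <- rep(list(ens$trajectory), 12)
  prof <- delta_sasa_profile(runs, probe_radius = 0.21, n_points = 120)
  expect_true(all(prof$distal$sd == 0) && all(prof$proximal$sd == 0))
  expect_equal(prof$n_runs, 12)
  other <- two_basin_ensemble(n_frames = 1, n_residues = 5)
  expect_error(delta_sasa_profile(list(ens$trajectory, other$trajectory)),
               "inconsistent")
})
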