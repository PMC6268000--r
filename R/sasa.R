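#' Solvent-accessible surface area per particle and residue
#'
#' Shrake-Rupley sphere-sampling SASA with a deterministic Fibonacci sphere
#' point set, so results are exactly reproducible for fixed `n_points`.
#'
#' @param frame a [conjugate_frame()].
#' @param topology a [conjugate_topology()]; supplies per-particle radii.
#' @param probe_radius probe radius in nm (default 0.14, a water probe;
#'   for coarse-grained beads a larger probe such as 0.21 nm is common).
#' @param n_points sphere sample points per particle (default 960).
#' @return object of class `sasa_result` with `particle_area` (nm^2),
#'   `residue_area` (named `subunit:resno`), and the settings used.
#' @export
sasa_per_residue <- function(frame, topology, probe_radius = 0.14,
                             n_points = 960) {
  p <- topology$particles
  if (any(is.na(p$radius)))
    stop("missing radius for particle(s): ",
         paste(which(is.na(p$radius)), collapse = ", "))
  area <- .sasa_cpp(frame$xyz, p$radius, probe_radius, as.integer(n_points),
                    seq_len(nrow(p)))
  key <- paste(p$subunit, p$resno, sep = ":")
  res <- tapply(area, key, sum)
  structure(list(particle_area = area,
                 residue_area = res[unique(key)],
                 probe_radius = probe_radius, n_points = n_points),
            class = "sasa_result")
}

# per-particle burial: SASA with only own-subunit context minus SASA in the
# full conjugate; >= 0 by construction with a shared deterministic point set
.burial_per_particle <- function(frame, topology, probe_radius, n_points) {
  p <- topology$particles
  full <- .sasa_cpp(frame$xyz, p$radius, probe_radius, as.integer(n_points),
                    seq_len(nrow(p)))
  iso <- numeric(nrow(p))
  for (s in c("distal", "proximal")) {
    sel <- which(p$subunit == s)
    iso[sel] <- .sasa_cpp(frame$xyz[sel, , drop = FALSE], p$radius[sel],
                          probe_radius, as.integer(n_points),
                          seq_along(sel))
  }
  list(burial = iso - full, isolated = iso, full = full)
}

#' Interface area of one frame and its polarity split
#'
#' The buried interface area
#' SA_interface = SASA(distal alone) + SASA(proximal alone) - SASA(conjugate),
#' with each subunit's isolated SASA evaluated at the same coordinates with
#' the partner's particles removed. The burial is attributed per particle
#' (isolated minus in-context accessibility) and summed by polarity class,
#' so the apolar (a-SA) and polar (p-SA) contributions partition
#' SA_interface exactly. Sphere-sampling noise can in principle produce tiny
#' negative totals; values in (-1e-3, 0) nm^2 are clamped to zero and larger
#' negatives raise a warning.
#'
#' @inheritParams sasa_per_residue
#' @return list with `sa_interface`, `a_sa`, `p_sa` (nm^2) and the
#'   per-particle burial vector.
#' @export
interface_area <- function(frame, topology, probe_radius = 0.14,
                           n_points = 960) {
  b <- .burial_per_particle(frame, topology, probe_radius, n_points)
  p <- topology$particles
  sa <- sum(b$burial)
  if (sa < 0) {
    if (sa > -1e-3) sa <- 0
    else warning(sprintf("interface area is negative (%.3g nm^2)", sa))
  }
  a_sa <- sum(b$burial[p$polarity == "apolar"])
  p_sa <- sum(b$burial[p$polarity == "polar"])
  list(sa_interface = sa, a_sa = a_sa, p_sa = p_sa,
       per_particle_burial = b$burial)
}

#' Interface statistics over a trajectory
#'
#' Per-frame interface area and polarity split, with means and variances.
#'
#' @param traj a [conjugate_trajectory()].
#' @param probe_radius,n_points see [sasa_per_residue()].
#' @param stride evaluate every `stride`-th frame.
#' @return object of class `interface_report`: per-frame data frame plus
#'   `mean` and `var` summaries.
#' @export
interface_report <- function(traj, probe_radius = 0.14, n_points = 960,
                             stride = 1) {
  sel <- seq.int(1L, n_frames(traj), by = as.integer(stride))
  rows <- lapply(sel, function(i) {
    r <- interface_area(get_frame(traj, i), traj$topology, probe_radius,
                        n_points)
    c(frame = i, sa_interface = r$sa_interface, a_sa = r$a_sa, p_sa = r$p_sa)
  })
  df <- as.data.frame(do.call(rbind, rows))
  structure(list(frames = df,
                 mean = colMeans(df[, -1, drop = FALSE]),
                 var = apply(df[, -1, drop = FALSE], 2, var),
                 probe_radius = probe_radius, n_points = n_points),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf(
    "interface_report: %d frames; <SA_interface> = %.3f nm^2 (a-SA %.3f, p-SA %.3f)\n",
    nrow(x$frames), x$mean["sa_interface"], x$mean["a_sa"], x$mean["p_sa"]))
  invisible(x)
}

#' Define a surface patch
#' @param name patch name.
#' @param residues residue numbers (within-subunit, 1-based).
#' @return object of class `patch_definition`.
#' @export
patch_definition <- function(name, residues) {
  structure(list(name = name, residues = as.integer(residues)),
            class = "patch_definition")
}

#' Default ubiquitin interaction patches
#'
#' Residue sets for the four classical ubiquitin recognition patches
#' (Ile44 patch, Ile36 patch, Phe4 patch, TEK box). These are configuration
#' defaults drawn from the ubiquitin-patch literature, not a fixed truth:
#' pass your own [patch_definition()] list to override. Residues beyond the
#' analysis range (the 73-76 tail) are excluded.
#'
#' @return named list of [patch_definition()] objects.
#' @export
default_ub_patches <- function() {
  list(Ile44 = patch_definition("Ile44", c(8, 44, 68, 70)),
       Ile36 = patch_definition("Ile36", c(36, 71)),
       Phe4 = patch_definition("Phe4", c(2, 4, 14)),
       TEK = patch_definition("TEK", c(6, 11, 12, 14, 34)))
}

.residue_sasa_by_subunit <- function(area, particles) {
  out <- list()
  for (s in c("distal", "proximal")) {
    sel <- particles$subunit == s
    f <- factor(particles$resno[sel],
                levels = sort(unique(particles$resno[sel])))
    out[[s]] <- tapply(area[sel], f, sum)
  }
  out
}

#' Patch accessibility in the conjugate relative to the monomer
#'
#' For each patch and each subunit: the mean over frames of (patch SASA in
#' the conjugate) / (patch SASA in the monomer reference), clipped to
#' \[0, 1]. By default the monomer reference is the same-frame isolated
#' subunit (the partner's particles removed), i.e. the fraction measures
#' how much of the patch the partner subunit buries. A user-supplied
#' per-residue reference table (list with `distal` and `proximal` vectors
#' indexed by residue number) is also accepted.
#'
#' @param traj a [conjugate_trajectory()].
#' @param patches list of [patch_definition()]s (default
#'   [default_ub_patches()]).
#' @param monomer_reference optional per-residue reference SASA table.
#' @param probe_radius,n_points see [sasa_per_residue()].
#' @param stride evaluate every `stride`-th frame.
#' @return data frame: patch, subunit, accessibility fraction.
#' @export
patch_accessibility <- function(traj, patches = default_ub_patches(),
                                monomer_reference = NULL,
                                probe_radius = 0.14, n_points = 960,
                                stride = 1) {
  p <- traj$topology$particles
  sel <- seq.int(1L, n_frames(traj), by = as.integer(stride))
  acc <- array(0, dim = c(length(patches), 2, length(sel)),
               dimnames = list(names(patches), c("distal", "proximal"), NULL))
  for (k in seq_along(sel)) {
    fr <- get_frame(traj, sel[k])
    b <- .burial_per_particle(fr, traj$topology, probe_radius, n_points)
    dim_sasa <- .residue_sasa_by_subunit(b$full, p)
    ref <- if (is.null(monomer_reference))
      .residue_sasa_by_subunit(b$isolated, p) else monomer_reference
    for (pt in seq_along(patches)) {
      res <- as.character(patches[[pt]]$residues)
      for (s in c("distal", "proximal")) {
        denom <- sum(ref[[s]][res])
        if (!is.finite(denom) || denom <= 0)
          stop(sprintf("reference SASA of patch '%s' (%s) is zero",
                       patches[[pt]]$name, s))
        acc[pt, s, k] <- min(1, max(0, sum(dim_sasa[[s]][res]) / denom))
      }
    }
  }
  mean_acc <- apply(acc, c(1, 2), mean)
  data.frame(patch = rep(rownames(mean_acc), 2),
             subunit = rep(colnames(mean_acc), each = nrow(mean_acc)),
             accessibility = as.vector(mean_acc))
}

#' Residue-wise loss of accessibility caused by the partner subunit
#'
#' For every residue of each subunit, the mean over frames (and runs) of
#' dSASA = SASA(subunit isolated, same coordinates) - SASA(in conjugate),
#' non-negative per frame by construction. With several independent runs the
#' error bar is the standard deviation of the per-run means.
#'
#' @param runs a `conjugate_trajectory` or list of them (independent runs of
#'   the same system; topologies must agree in residue counts).
#' @param probe_radius,n_points see [sasa_per_residue()].
#' @param stride evaluate every `stride`-th frame.
#' @return object of class `delta_sasa_profile`: per-subunit data frames
#'   with residue, mean dSASA (nm^2) and sd over runs.
#' @export
delta_sasa_profile <- function(runs, probe_radius = 0.14, n_points = 960,
                               stride = 1) {
  if (inherits(runs, "conjugate_trajectory")) runs <- list(runs)
  nres <- lapply(runs, function(tr)
    tapply(tr$topology$particles$resno, tr$topology$particles$subunit, max))
  if (length(unique(vapply(nres, paste, character(1), collapse = ","))) != 1)
    stop("runs have inconsistent residue counts")
  per_run <- lapply(runs, function(tr) {
    p <- tr$topology$particles
    sel <- seq.int(1L, n_frames(tr), by = as.integer(stride))
    acc <- list(distal = 0, proximal = 0)
    for (i in sel) {
      b <- .burial_per_particle(get_frame(tr, i), tr$topology, probe_radius,
                                n_points)
      dd <- .residue_sasa_by_subunit(b$burial, p)
      acc$distal <- acc$distal + dd$distal
      acc$proximal <- acc$proximal + dd$proximal
    }
    lapply(acc, function(v) v / length(sel))
  })
  out <- list()
  for (s in c("distal", "proximal")) {
    m <- do.call(rbind, lapply(per_run, `[[`, s))
    out[[s]] <- data.frame(residue = as.integer(colnames(m)),
                           mean = colMeans(m),
                           sd = if (nrow(m) > 1) apply(m, 2, sd) else
                             rep(0, ncol(m)))
  }
  structure(c(out, list(n_runs = length(runs), probe_radius = probe_radius,
                        n_points = n_points)),
            class = "delta_sasa_profile")
}

#' @export
print.delta_sasa_profile <- function(x, ...) {
  cat(sprintf(
    "delta_sasa_profile: %d run(s); peak dSASA %.3f (distal) / %.3f (proximal) nm^2\n",
    x$n_runs, max(x$distal$mean), max(x$proximal$mean)))
  invisible(x)
}
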