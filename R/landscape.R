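#' 2D probability density of a projection
#'
#' Normalized 2D histogram of projected points. The grid defaults to the
#' bounding box of the points padded by 5% per side; an explicit `range` is
#' auto-extended if points fall outside it.
#'
#' @param proj n x 2 matrix of map coordinates.
#' @param bins number of bins per axis (scalar or length 2).
#' @param range list with `x` and `y` limits, or NULL for auto.
#' @param smooth_sd optional Gaussian smoothing bandwidth in bins (0 = off).
#' @param aspect `"free"` bins each axis over its own data range; `"equal"`
#'   uses one common bin size (the larger axis span divided by `bins`), so a
#'   map whose second coordinate is nearly degenerate is not sliced into
#'   meaninglessly thin bins along it.
#' @return object of class `density2d`: bin edges, normalized `mass`, raw
#'   `counts`, sample size `n`.
#' @export
density2d <- function(proj, bins = 100, range = NULL, smooth_sd = 0,
                      aspect = c("free", "equal")) {
  proj <- as.matrix(proj)
  aspect <- match.arg(aspect)
  if (nrow(proj) < 1) stop("at least one point is required")
  bins <- rep(as.integer(bins), length.out = 2)
  if (is.null(range)) {
    pad <- function(r) {
      s <- diff(r); if (s == 0) s <- 1
      r + c(-1, 1) * 0.05 * s
    }
    range <- list(x = pad(range(proj[, 1])), y = pad(range(proj[, 2])))
    if (aspect == "equal") {
      s <- max(diff(range$x), diff(range$y))
      grow <- function(r) mean(r) + c(-0.5, 0.5) * s
      range <- list(x = grow(range$x), y = grow(range$y))
    }
  } else {
    range$x <- c(min(range$x[1], min(proj[, 1])),
                 max(range$x[2], max(proj[, 1])))
    range$y <- c(min(range$y[1], min(proj[, 2])),
                 max(range$y[2], max(proj[, 2])))
  }
  xe <- seq(range$x[1], range$x[2], length.out = bins[1] + 1)
  ye <- seq(range$y[1], range$y[2], length.out = bins[2] + 1)
  ix <- findInterval(proj[, 1], xe, rightmost.closed = TRUE,
                     all.inside = TRUE)
  iy <- findInterval(proj[, 2], ye, rightmost.closed = TRUE,
                     all.inside = TRUE)
  counts <- matrix(tabulate(ix + (iy - 1L) * bins[1],
                            nbins = bins[1] * bins[2]),
                   nrow = bins[1])
  mass <- counts / nrow(proj)
  if (smooth_sd > 0) {
    k <- ceiling(3 * smooth_sd)
    ker <- stats::dnorm(-k:k, sd = smooth_sd)
    ker <- ker / sum(ker)
    smooth1 <- function(m) {
      pad <- matrix(0, nrow = nrow(m) + 2 * k, ncol = ncol(m))
      pad[(k + 1):(k + nrow(m)), ] <- m
      out <- matrix(0, nrow(m), ncol(m))
      for (t in seq_along(ker))
        out <- out + ker[t] * pad[t:(t + nrow(m) - 1), , drop = FALSE]
      out
    }
    mass <- smooth1(mass)
    mass <- t(smooth1(t(mass)))
    mass <- mass / sum(mass)
  }
  structure(list(x_edges = xe, y_edges = ye, mass = mass, counts = counts,
                 n = nrow(proj)), class = "density2d")
}

#' @export
print.density2d <- function(x, ...) {
  cat(sprintf("density2d: %d x %d grid, %d samples, %d populated bins\n",
              nrow(x$mass), ncol(x$mass), x$n, sum(x$counts > 0)))
  invisible(x)
}

.bin_centers <- function(edges) (head(edges, -1) + edges[-1]) / 2

#' Boltzmann-inverted free-energy surface
#'
#' Converts a sampled 2D density into a free-energy estimate
#' F = -kT ln(p) per populated bin, shifted so the global minimum is zero.
#' Unpopulated bins are masked and carry no finite energy. Energies are
#' reported both in kT units and kJ/mol (k_B = 0.0083145 kJ mol^-1 K^-1).
#'
#' @param d a [density2d()].
#' @param temperature_K temperature in kelvin (default 300).
#' @return object of class `fes_surface`.
#' @export
free_energy_surface <- function(d, temperature_K = 300) {
  stopifnot(inherits(d, "density2d"))
  kT <- .kB * temperature_K
  mask <- d$mass > 0
  e_kt <- matrix(NA_real_, nrow(d$mass), ncol(d$mass))
  e_kt[mask] <- -log(d$mass[mask])
  shift <- min(e_kt[mask])
  e_kt <- e_kt - shift
  structure(list(x_edges = d$x_edges, y_edges = d$y_edges,
                 energy_kt = e_kt, energy_kjmol = e_kt * kT,
                 mask = mask, counts = d$counts,
                 temperature = temperature_K, kT_kjmol = kT,
                 reference_shift = shift),
            class = "fes_surface")
}

#' @export
print.fes_surface <- function(x, ...) {
  cat(sprintf(
    "fes_surface: %d x %d grid, T = %g K (kT = %.4g kJ/mol), %d populated bins\n",
    nrow(x$energy_kt), ncol(x$energy_kt), x$temperature, x$kT_kjmol,
    sum(x$mask)))
  invisible(x)
}

#' Locate free-energy minima
#'
#' A local minimum is a populated bin strictly lower than all its populated
#' 8-neighbors; flat plateaus of equal energy that are collectively lower
#' than their surroundings count once, at their centroid bin. Bins with
#' fewer than `min_count` samples are treated as unpopulated to suppress
#' noise minima. The `k` lowest minima are returned, ordered by depth; if
#' fewer exist, all are returned and the `fewer_than_requested` attribute is
#' set.
#'
#' @param fes a [free_energy_surface()].
#' @param k number of minima requested (>= 1).
#' @param min_count occupancy threshold (default 2 samples).
#' @return data frame with map coordinates, bin indices and depths (kT and
#'   kJ/mol) relative to the global minimum, sorted ascending.
#' @export
find_minima <- function(fes, k = 5, min_count = 2) {
  if (k < 1) stop("k must be >= 1")
  E <- fes$energy_kt
  pop <- fes$mask & fes$counts >= min_count
  if (!any(pop)) stop("no populated bins at this occupancy threshold")
  nx <- nrow(E); ny <- ncol(E)
  E2 <- matrix(Inf, nx + 2, ny + 2)
  E2[2:(nx + 1), 2:(ny + 1)][pop] <- E[pop]
  shifts <- expand.grid(dx = -1:1, dy = -1:1)
  shifts <- shifts[!(shifts$dx == 0 & shifts$dy == 0), ]
  nb_min <- matrix(Inf, nx, ny)
  strict <- matrix(TRUE, nx, ny)
  for (s in seq_len(nrow(shifts))) {
    nb <- E2[2:(nx + 1) + shifts$dx[s], 2:(ny + 1) + shifts$dy[s]]
    nb_min <- pmin(nb_min, nb)
  }
  here <- E2[2:(nx + 1), 2:(ny + 1)]
  is_min <- pop & (here < nb_min)              # strict minima
  flat <- pop & (here == nb_min) & is.finite(here)
  # plateau handling: flood-fill equal-value connected components that are
  # lower than all external populated neighbors; represent at centroid
  plateau_reps <- list()
  if (any(flat)) {
    visited <- matrix(FALSE, nx, ny)
    idx <- which(flat, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      i0 <- idx[r, 1]; j0 <- idx[r, 2]
      if (visited[i0, j0]) next
      val <- here[i0, j0]
      comp <- matrix(c(i0, j0), ncol = 2)
      visited[i0, j0] <- TRUE
      queue <- list(c(i0, j0))
      lower_outside <- FALSE
      while (length(queue)) {
        cur <- queue[[1]]; queue <- queue[-1]
        for (s in seq_len(nrow(shifts))) {
          ii <- cur[1] + shifts$dx[s]; jj <- cur[2] + shifts$dy[s]
          if (ii < 1 || ii > nx || jj < 1 || jj > ny) next
          if (!pop[ii, jj]) next
          if (here[ii, jj] == val) {
            if (!visited[ii, jj]) {
              visited[ii, jj] <- TRUE
              comp <- rbind(comp, c(ii, jj))
              queue[[length(queue) + 1]] <- c(ii, jj)
            }
          } else if (here[ii, jj] < val) lower_outside <- TRUE
        }
      }
      if (!lower_outside && nrow(comp) > 1) {
        cen <- colMeans(comp)
        best <- which.min((comp[, 1] - cen[1])^2 + (comp[, 2] - cen[2])^2)
        plateau_reps[[length(plateau_reps) + 1]] <- comp[best, ]
      }
    }
  }
  mins <- which(is_min, arr.ind = TRUE)
  if (length(plateau_reps))
    mins <- rbind(mins, do.call(rbind, plateau_reps))
  if (!nrow(mins)) { # completely flat populated surface: single global rep
    pp <- which(pop, arr.ind = TRUE)
    mins <- pp[which.min(here[pop])[1], , drop = FALSE]
  }
  depth <- here[mins]
  o <- order(depth, mins[, 1], mins[, 2])
  mins <- mins[o, , drop = FALSE]
  depth <- depth[o] - min(depth)
  take <- seq_len(min(k, nrow(mins)))
  cx <- .bin_centers(fes$x_edges)[mins[take, 1]]
  cy <- .bin_centers(fes$y_edges)[mins[take, 2]]
  out <- data.frame(x = cx, y = cy,
                    depth_kt = depth[take],
                    depth_kjmol = depth[take] * fes$kT_kjmol,
                    ix = mins[take, 1], iy = mins[take, 2])
  attr(out, "fewer_than_requested") <- nrow(mins) < k
  out
}

#' Select basin-representative frames
#'
#' For each of the `n_minima` lowest free-energy minima: the frame whose
#' projection is nearest the minimum, plus `n_random` distinct frames drawn
#' uniformly (seeded) from all frames projected within `radius` of the
#' minimum. A minimum with no frames inside the radius contributes only its
#' nearest frame, with a warning. The defaults (4 minima, 10 random frames)
#' reproduce the basin-export scheme used to seed backmapped atomistic runs.
#'
#' @param fes a [free_energy_surface()].
#' @param proj n x 2 projection whose rows map to frame indices (attribute
#'   `"frame_indices"`, else 1..n).
#' @param n_minima number of basins (default 4).
#' @param n_random random frames per basin (default 10).
#' @param radius basin radius in map units.
#' @param seed RNG seed.
#' @param min_count occupancy threshold passed to [find_minima()].
#' @return list of per-basin lists: `minimum` (x, y), `representative`
#'   (frame index), `random` (frame indices).
#' @export
select_basin_frames <- function(fes, proj, n_minima = 4, n_random = 10,
                                radius = NULL, seed = 1, min_count = 2) {
  proj <- as.matrix(proj)
  frames <- attr(proj, "frame_indices")
  if (is.null(frames)) frames <- seq_len(nrow(proj))
  if (is.null(radius))
    radius <- 0.05 * max(diff(range(fes$x_edges)), diff(range(fes$y_edges)))
  mins <- find_minima(fes, k = n_minima, min_count = min_count)
  groups <- vector("list", nrow(mins))
  for (m in seq_len(nrow(mins))) {
    d <- sqrt((proj[, 1] - mins$x[m])^2 + (proj[, 2] - mins$y[m])^2)
    rep_i <- which.min(d)
    inside <- setdiff(which(d <= radius), rep_i)
    rnd <- integer(0)
    if (n_random > 0) {
      if (!length(inside)) {
        warning(sprintf("minimum %d has no frames within radius %.3g", m,
                        radius))
      } else {
        take <- min(n_random, length(inside))
        rnd <- with_seed(seed + m,
                         inside[sample.int(length(inside), take)])
      }
    }
    groups[[m]] <- list(minimum = c(x = mins$x[m], y = mins$y[m]),
                        representative = frames[rep_i],
                        random = frames[rnd])
  }
  groups
}
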