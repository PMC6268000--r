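#' Earth Mover Distance between two 2D densities
#'
#' Exact discrete optimal-transport cost between two normalized 2D
#' histograms, with the Euclidean distance between bin centers as ground
#' metric. Grids may differ; both live in the same map coordinate system.
#' Solved exactly with a transportation-simplex network solver. Densities
#' with many populated bins can be coarsened (mass-conserving bin
#' aggregation) before the solve; `coarsen = Inf` forces the exact
#' resolution.
#'
#' @param dA,dB [density2d()] objects with total mass 1.
#' @param coarsen maximum bins per axis before aggregation (default 64).
#' @return transport cost in map units.
#' @export
emd2d <- function(dA, dB, coarsen = 64) {
  stopifnot(inherits(dA, "density2d"), inherits(dB, "density2d"))
  for (d in list(dA, dB))
    if (abs(sum(d$mass) - 1) > 1e-6)
      stop("densities must be normalized to total mass 1")
  pa <- .density_points(dA, coarsen)
  pb <- .density_points(dB, coarsen)
  # guard against tiny normalization drift so the solver sees a balanced
  # problem
  ma <- pa$mass / sum(pa$mass)
  mb <- pb$mass / sum(pb$mass)
  # explicit coordinate differences: exact zeros for coincident bin centers
  cost <- sqrt(outer(pa$xy[, 1], pb$xy[, 1], "-")^2 +
                 outer(pa$xy[, 2], pb$xy[, 2], "-")^2)
  .emd_cpp(ma, mb, cost)
}

# populated-bin point masses of a density, optionally aggregated
.density_points <- function(d, coarsen = 64) {
  mass <- d$mass
  xe <- d$x_edges; ye <- d$y_edges
  fx <- ceiling(nrow(mass) / coarsen)
  fy <- ceiling(ncol(mass) / coarsen)
  if (fx > 1 || fy > 1) {
    gx <- ceiling(seq_len(nrow(mass)) / fx)
    gy <- ceiling(seq_len(ncol(mass)) / fy)
    agg <- rowsum(t(rowsum(mass, gx)), gy)    # gy x gx
    mass <- t(agg)
    xe <- xe[c(seq(1, nrow(d$mass), by = fx), nrow(d$mass) + 1)]
    ye <- ye[c(seq(1, ncol(d$mass), by = fy), ncol(d$mass) + 1)]
    xe[length(xe)] <- d$x_edges[length(d$x_edges)]
    ye[length(ye)] <- d$y_edges[length(d$y_edges)]
  }
  keep <- which(mass > 0, arr.ind = TRUE)
  cx <- .bin_centers(xe)[keep[, 1]]
  cy <- .bin_centers(ye)[keep[, 2]]
  list(xy = cbind(cx, cy), mass = mass[keep])
}

#' Pairwise EMD matrix of a set of landscapes
#'
#' All pairwise Earth Mover Distances between the projected densities of a
#' set of systems, optionally max-normalized so the most dissimilar pair
#' scores exactly 1.
#'
#' @param densities list of [density2d()] objects.
#' @param normalize divide by the largest off-diagonal entry (stored as
#'   `norm_const`).
#' @param labels system labels.
#' @param coarsen passed to [emd2d()].
#' @return object of class `emd_matrix`.
#' @export
pairwise_emd <- function(densities, normalize = TRUE, labels = NULL,
                         coarsen = 64) {
  .assert_flag(normalize, "normalize")
  k <- length(densities)
  if (k < 2) stop("at least two densities are required")
  if (is.null(labels)) labels <- names(densities)
  if (is.null(labels)) labels <- paste0("system", seq_len(k))
  m <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1))
    for (j in (i + 1):k)
      m[i, j] <- m[j, i] <- emd2d(densities[[i]], densities[[j]],
                                  coarsen = coarsen)
  norm_const <- max(m)
  normalized <- FALSE
  if (normalize) {
    # below the transport solver's numerical floor all landscapes coincide
    if (norm_const <= 1e-9) {
      warning("all pairwise EMDs are zero; normalization skipped")
    } else {
      m <- m / norm_const
      normalized <- TRUE
    }
  }
  structure(list(labels = labels, m = m, normalized = normalized,
                 norm_const = norm_const), class = "emd_matrix")
}

#' @export
print.emd_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("emd_matrix: %d systems%s\n", length(x$labels),
              if (x$normalized)
                sprintf(", max-normalized (norm constant %.4g map units)",
                        x$norm_const) else ""))
  print(round(x$m, digits))
  invisible(x)
}

#' Arrange systems in 2D by landscape similarity
#'
#' Classical metric multidimensional scaling of the pairwise EMD matrix,
#' centered at the origin. Orientation is fixed deterministically: each
#' coordinate axis is flipped, if needed, so the first system has
#' non-negative coordinates.
#'
#' @param m an [pairwise_emd()] matrix (or a plain symmetric matrix).
#' @param seed unused (placement is deterministic); kept for interface
#'   stability.
#' @return k x 2 coordinate matrix with system labels as row names.
#' @export
arrange_by_similarity <- function(m, seed = NULL) {
  mat <- if (inherits(m, "emd_matrix")) m$m else as.matrix(m)
  labels <- rownames(mat)
  k <- nrow(mat)
  xy <- cmdscale(mat, k = min(2, k - 1))
  if (ncol(xy) < 2) xy <- cbind(xy, 0)
  xy <- sweep(xy, 2, colMeans(xy))
  for (cc in 1:2) if (xy[1, cc] < 0) xy[, cc] <- -xy[, cc]
  dimnames(xy) <- list(labels, c("x", "y"))
  xy
}
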