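#' Sketch-map sigmoid parameters
#'
#' The switching parameters of the sketch-map transform. `sigma` is the
#' switching distance on the scale of the high-dimensional (RMD) distances,
#' in nm for raw RMD vectors; `a_hd`/`b_hd` shape the high-dimensional
#' sigmoid and `a_ld`/`b_ld` the low-dimensional one. The defaults are the
#' values used for ubiquitin-dimer RMD data: sigma = 5.9, A = 12, B = 4,
#' a = 2, b = 4.
#'
#' @param sigma switching distance (> 0).
#' @param a_hd,b_hd high-dimensional exponents (> 0).
#' @param a_ld,b_ld low-dimensional exponents (> 0).
#' @return object of class `sigmoid_params`.
#' @export
sigmoid_params <- function(sigma = 5.9, a_hd = 12, b_hd = 4,
                           a_ld = 2, b_ld = 4) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (any(c(a_hd, b_hd, a_ld, b_ld) <= 0)) stop("all exponents must be > 0")
  structure(list(sigma = sigma, a_hd = a_hd, b_hd = b_hd,
                 a_ld = a_ld, b_ld = b_ld), class = "sigmoid_params")
}

#' Sketch-map sigmoid transform
#'
#' \deqn{F(r) = 1 - (1 + (2^{a/b} - 1)(r/\sigma)^a)^{-b/a}}
#' Monotone non-decreasing, F(0) = 0, F(sigma) = 1/2, F -> 1 as r -> Inf.
#' With steep high-dimensional exponents and soft low-dimensional ones the
#' stress focuses on the intermediate range of distances around sigma.
#'
#' @param r distances (>= 0).
#' @param sigma switching distance.
#' @param a,b exponents (> 0).
#' @return transformed values in \[0, 1).
#' @export
sketchmap_sigmoid <- function(r, sigma, a, b) {
  if (any(r < 0)) stop("distances must be >= 0")
  1 - (1 + (2^(a / b) - 1) * (r / sigma)^a)^(-b / a)
}

# derivative dF/dr, needed for the stress gradient
.sigmoid_deriv <- function(r, sigma, a, b) {
  c0 <- 2^(a / b) - 1
  g <- 1 + c0 * (r / sigma)^a
  b * c0 * r^(a - 1) / sigma^a * g^(-b / a - 1)
}

.f_hd <- function(r, p) sketchmap_sigmoid(r, p$sigma, p$a_hd, p$b_hd)
.f_ld <- function(r, p) sketchmap_sigmoid(r, p$sigma, p$a_ld, p$b_ld)

#' Select sketch-map landmarks
#'
#' Mixes seeded uniform-random picks with greedy farthest-point ("minmax")
#' picks: `ceiling(gamma * n)` points are drawn uniformly at random, the
#' remainder added greedily as the point farthest (in high-dimensional
#' Euclidean distance) from the current selection. With `gamma = 0` the
#' greedy stage is seeded with the globally most distant pair of points, so
#' that pair is always part of the selection. Landmark weights count the
#' points of the input cloud nearest to each landmark (the landmark itself
#' included), for use in the weighted stress.
#'
#' @param vectors matrix of high-dimensional (RMD) row vectors.
#' @param n number of landmarks (1..nrow).
#' @param gamma fraction of landmarks chosen uniformly at random, in \[0, 1].
#' @param seed RNG seed for the random stage.
#' @return object of class `landmark_set`: indices, vectors, weights.
#' @export
select_landmarks <- function(vectors, n, gamma = 0.1, seed = 1) {
  vectors <- as.matrix(vectors)
  nr <- nrow(vectors)
  if (n < 1 || n > nr) stop("n must be between 1 and nrow(vectors)")
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]")
  if (n == nr) {
    sel <- seq_len(nr)
  } else {
    n_rand <- min(n, ceiling(gamma * n))
    sel <- if (n_rand > 0)
      with_seed(seed, sample.int(nr, n_rand)) else integer(0)
    if (length(sel) < n) {
      if (!length(sel)) {
        # seed greedy stage with the global farthest pair
        far <- c(1L, 1L); best <- -1
        for (i in seq_len(nr - 1L)) {
          d <- .cross_dist(vectors[i, , drop = FALSE],
                           vectors[(i + 1L):nr, , drop = FALSE])
          j <- which.max(d)
          if (d[j] > best) { best <- d[j]; far <- c(i, i + j) }
        }
        sel <- if (n >= 2) far else far[1]
      }
      mind <- apply(.cross_dist(vectors, vectors[sel, , drop = FALSE]), 1, min)
      while (length(sel) < n) {
        nxt <- which.max(mind) # ties -> lowest index
        sel <- c(sel, nxt)
        mind <- pmin(mind, .cross_dist(vectors,
                                       vectors[nxt, , drop = FALSE])[, 1])
      }
    }
  }
  sel <- as.integer(sel)
  nearest <- apply(.cross_dist(vectors, vectors[sel, , drop = FALSE]), 1,
                   which.min)
  w <- tabulate(nearest, nbins = length(sel))
  # each landmark represents at least itself
  w[w == 0] <- 1L
  structure(list(indices = sel, vectors = vectors[sel, , drop = FALSE],
                 weights = as.numeric(w), gamma = gamma, seed = seed),
            class = "landmark_set")
}

# weighted sketch-map stress and its gradient for a flat coordinate vector
.stress_fun <- function(par, Dhd, W, sp) {
  X <- matrix(par, ncol = 2)
  r <- as.matrix(dist(X))
  f <- .f_ld(r, sp)
  sum(W * (Dhd - f)^2) / 2
}

.stress_grad <- function(par, Dhd, W, sp) {
  X <- matrix(par, ncol = 2)
  r <- as.matrix(dist(X))
  fp <- .sigmoid_deriv(r, sp$sigma, sp$a_ld, sp$b_ld)
  coef <- 2 * W * (.f_ld(r, sp) - Dhd) * fp
  rr <- r; rr[rr < 1e-12] <- 1
  coef <- coef / rr
  diag(coef) <- 0
  gx <- rowSums(coef) * X[, 1] - coef %*% X[, 1]
  gy <- rowSums(coef) * X[, 2] - coef %*% X[, 2]
  c(gx, gy)
}

#' Fit a sketch-map model on landmarks
#'
#' Minimizes the weighted stress
#' \deqn{\chi^2 = \sum_{i<j} w_i w_j (F_{hd}(R_{ij}) - F_{ld}(r_{ij}))^2}
#' over the landmark 2D positions, where R are high-dimensional Euclidean
#' distances, r the 2D map distances, and F the sigmoid transforms.
#' Initialization is classical metric MDS of the F_hd-transformed distances;
#' optimization is L-BFGS with analytic gradients, optionally restarted from
#' seeded perturbations of the initialization. The returned stress is never
#' above the initialization stress.
#'
#' @param landmarks a [select_landmarks()] result (or a plain matrix, in
#'   which case all rows are landmarks with unit weight).
#' @param params a [sigmoid_params()].
#' @param seed RNG seed for the restart perturbations.
#' @param max_iter maximum optimizer iterations per start.
#' @param tol relative stress-change tolerance.
#' @param n_restarts additional perturbed starts.
#' @param use_weights use landmark weights in the stress (TRUE) or treat all
#'   landmarks equally (FALSE).
#' @return object of class `sketchmap_model` with landmark 2D `coords`,
#'   final `stress`, `init_stress`, `converged` flag and iteration counts.
#' @export
fit_sketchmap <- function(landmarks, params = sigmoid_params(), seed = 1,
                          max_iter = 1000, tol = 1e-6, n_restarts = 1,
                          use_weights = TRUE) {
  if (is.matrix(landmarks) || is.data.frame(landmarks))
    landmarks <- list(vectors = as.matrix(landmarks),
                      weights = rep(1, nrow(landmarks)),
                      indices = seq_len(nrow(landmarks)))
  V <- landmarks$vectors
  N <- nrow(V)
  if (N < 3) stop("at least 3 landmarks are required")
  w <- if (use_weights) landmarks$weights else rep(1, N)
  Dhd <- .f_hd(as.matrix(dist(V)), params)
  W <- tcrossprod(w)
  diag(W) <- 0
  init <- cmdscale(Dhd, k = 2)
  if (ncol(init) < 2)
    init <- cbind(init, 0)[, 1:2, drop = FALSE]
  s0 <- .stress_fun(as.vector(init), Dhd, W, params)
  best <- list(par = as.vector(init), value = s0, conv = TRUE, iter = 0L)
  starts <- list(as.vector(init))
  if (n_restarts > 0) {
    scale <- max(apply(init, 2, function(z) diff(range(z))), 1e-3)
    for (k in seq_len(n_restarts))
      starts[[k + 1]] <- as.vector(init) +
        with_seed(seed + k, rnorm(2 * N, sd = 0.05 * scale))
  }
  iters <- 0L
  for (st in starts) {
    fit <- optim(st, .stress_fun, .stress_grad, Dhd = Dhd, W = W, sp = params,
                 method = "L-BFGS-B",
                 control = list(maxit = max_iter,
                                factr = tol / .Machine$double.eps))
    iters <- iters + fit$counts[1]
    if (fit$value < best$value)
      best <- list(par = fit$par, value = fit$value,
                   conv = fit$convergence == 0, iter = iters)
  }
  structure(list(params = params,
                 landmark_vectors = V,
                 landmark_indices = landmarks$indices,
                 weights = w,
                 coords = matrix(best$par, ncol = 2,
                                 dimnames = list(NULL, c("x", "y"))),
                 stress = best$value, init_stress = s0,
                 converged = best$conv, iterations = iters),
            class = "sketchmap_model")
}

#' @export
print.sketchmap_model <- function(x, ...) {
  cat(sprintf(
    "sketchmap_model: %d landmarks (dim %d), stress %.6g (init %.6g)%s\n",
    nrow(x$coords), ncol(x$landmark_vectors), x$stress, x$init_stress,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

# out-of-sample placement objective pieces, vectorized over points x grid
.project_cost <- function(A, B, w) {
  # A: npoints x N (F_hd terms), B: ncand x N (F_ld terms), w: weights
  # cost[p, g] = sum_j w_j (A[p,j] - B[g,j])^2
  outer(as.vector(A^2 %*% w), as.vector(B^2 %*% w), "+") -
    2 * tcrossprod(sweep(A, 2, w, "*"), B)
}

#' Project points through a fitted sketch-map model
#'
#' Each point is placed at the 2D position minimizing the weighted
#' out-of-sample stress against the landmarks: a deterministic grid scan
#' over the (padded) landmark bounding box followed by vectorized local
#' gradient refinement with per-point adaptive step sizes.
#'
#' @param vectors matrix of high-dimensional vectors (same dimension as the
#'   landmark vectors).
#' @param model a [fit_sketchmap()] model.
#' @param grid_res grid-scan resolution as a fraction of the larger bounding
#'   box side (default 0.01).
#' @param refine_iter refinement iterations (default 60).
#' @param pad bounding-box padding fraction per side.
#' @param chunk points per grid-scan block (memory control).
#' @return n x 2 matrix of map coordinates with attribute `"frame_indices"`
#'   passed through from the input if present.
#' @export
sketchmap_project <- function(vectors, model, grid_res = 0.01,
                              refine_iter = 60, pad = 0.1, chunk = 2000) {
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != ncol(model$landmark_vectors))
    stop("input dimension does not match the landmark vectors")
  p <- model$params
  L <- model$coords
  w <- model$weights
  A <- .f_hd(.cross_dist(vectors, model$landmark_vectors), p)
  rx <- range(L[, 1]); ry <- range(L[, 2])
  span <- max(diff(rx), diff(ry), 1e-8)
  step <- grid_res * span
  gx <- seq(rx[1] - pad * span, rx[2] + pad * span, by = step)
  gy <- seq(ry[1] - pad * span, ry[2] + pad * span, by = step)
  G <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  B <- .f_ld(.cross_dist(G, L), p)
  n <- nrow(vectors)
  X <- matrix(0, n, 2)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    cost <- .project_cost(A[s:e, , drop = FALSE], B, w)
    X[s:e, ] <- G[max.col(-cost, ties.method = "first"), , drop = FALSE]
  }
  # vectorized per-point refinement
  obj <- function(X) {
    f <- .f_ld(.cross_dist(X, L), p)
    as.vector((A - f)^2 %*% w)
  }
  grad <- function(X) {
    r <- .cross_dist(X, L)
    f <- .f_ld(r, p)
    fp <- .sigmoid_deriv(r, p$sigma, p$a_ld, p$b_ld)
    cc <- sweep(2 * (f - A) * fp, 2, w, "*")
    rr <- r; rr[rr < 1e-12] <- 1
    cc <- cc / rr
    cbind(rowSums(cc) * X[, 1] - cc %*% L[, 1],
          rowSums(cc) * X[, 2] - cc %*% L[, 2])
  }
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    Xi <- X[s:e, , drop = FALSE]
    Ai <- A[s:e, , drop = FALSE]
    A_save <- A; A <- Ai
    fi <- obj(Xi)
    eta <- rep(step, nrow(Xi))
    for (it in seq_len(refine_iter)) {
      g <- grad(Xi)
      gn <- sqrt(rowSums(g^2)); gn[gn < 1e-15] <- 1
      prop <- Xi - (eta / gn) * g
      fp_ <- obj(prop)
      ok <- fp_ < fi
      Xi[ok, ] <- prop[ok, , drop = FALSE]
      fi[ok] <- fp_[ok]
      eta[ok] <- eta[ok] * 1.2
      eta[!ok] <- eta[!ok] * 0.5
    }
    A <- A_save
    X[s:e, ] <- Xi
  }
  colnames(X) <- c("x", "y")
  attr(X, "frame_indices") <- attr(vectors, "frame_indices")
  X
}

#' Serialize a sketch-map model to JSON
#' @param model a `sketchmap_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sketchmap <- function(model, path) {
  obj <- list(params = unclass(model$params),
              landmark_vectors = model$landmark_vectors,
              landmark_indices = model$landmark_indices,
              weights = model$weights,
              coords = model$coords,
              stress = model$stress, init_stress = model$init_stress,
              converged = model$converged, iterations = model$iterations)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a sketch-map model written by [write_sketchmap()]
#' @param path JSON path.
#' @return a `sketchmap_model`.
#' @export
read_sketchmap <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$params <- do.call(sigmoid_params, as.list(obj$params))
  obj$landmark_vectors <- as.matrix(obj$landmark_vectors)
  obj$coords <- as.matrix(obj$coords)
  structure(obj, class = "sketchmap_model")
}

#' Summary of the high-dimensional distance distribution
#'
#' Helper for choosing the sigmoid switching distance sigma: quantiles and a
#' histogram of pairwise Euclidean distances of (a subsample of) the input
#' vectors. The choice of sigma is left to the user.
#'
#' @param vectors matrix of high-dimensional vectors.
#' @param max_rows subsample cap for the pairwise computation.
#' @param seed subsample seed.
#' @return list with `quantiles` and a `hist` object.
#' @export
hd_distance_summary <- function(vectors, max_rows = 2000, seed = 1) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) > max_rows)
    vectors <- vectors[with_seed(seed, sample.int(nrow(vectors), max_rows)), ]
  d <- dist(vectors)
  list(quantiles = stats::quantile(d, c(0, .05, .25, .5, .75, .95, 1)),
       hist = graphics::hist(d, breaks = 50, plot = FALSE))
}
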