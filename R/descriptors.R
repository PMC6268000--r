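#' Residue-wise minimum distance (RMD) vector of one frame
#'
#' The per-frame collective-variable set: for each backbone site (C-alpha
#' atom or CG backbone bead) of the distal subunit, the minimum Euclidean
#' distance to any backbone site of the proximal subunit, and vice versa.
#' Only residues inside the analysis range enter (for ubiquitin 1..72 per
#' subunit, so the descriptor has 2 x 72 = 144 entries). Ordering is the
#' distal block followed by the proximal block.
#'
#' Distances are plain Euclidean; covalently linked subunits are assumed not
#' to straddle the periodic box. Set `pbc_box` to apply the minimum-image
#' convention in an orthorhombic box.
#'
#' @param frame a [conjugate_frame()].
#' @param topology a [conjugate_topology()].
#' @param pbc_box optional length-3 orthorhombic box (nm) for minimum-image
#'   distances.
#' @return numeric vector of length 2R (R = analysis residues per subunit),
#'   distal block first, with attribute `"blocks"` giving the block sizes.
#' @export
rmd_vector <- function(frame, topology, pbc_box = NULL) {
  id <- backbone_indices(topology, "distal")
  ip <- backbone_indices(topology, "proximal")
  if (!length(id) || !length(ip))
    stop("both subunits need at least one analysis residue with a backbone site")
  A <- frame$xyz[id, , drop = FALSE]
  B <- frame$xyz[ip, , drop = FALSE]
  if (!is.null(pbc_box)) {
    # wrap each coordinate difference into [-L/2, L/2) per axis
    d2 <- matrix(0, nrow(A), nrow(B))
    for (k in 1:3) {
      dk <- outer(A[, k], B[, k], "-")
      dk <- dk - pbc_box[k] * round(dk / pbc_box[k])
      d2 <- d2 + dk^2
    }
    v <- c(sqrt(apply(d2, 1, min)), sqrt(apply(d2, 2, min)))
  } else {
    v <- .rmd_cpp(A, B)
  }
  attr(v, "blocks") <- c(distal = length(id), proximal = length(ip))
  v
}

#' RMD descriptors for a trajectory
#'
#' @param traj a [conjugate_trajectory()].
#' @param stride keep every `stride`-th frame starting from the first;
#'   `ceiling(n_frames / stride)` rows result.
#' @param pbc_box see [rmd_vector()].
#' @return matrix, one RMD row per sampled frame; attribute
#'   `"frame_indices"` holds the source frame numbers and `"times"` their
#'   time stamps.
#' @export
rmd_series <- function(traj, stride = 1, pbc_box = NULL) {
  if (stride < 1) stop("stride must be >= 1")
  sel <- seq.int(1L, n_frames(traj), by = as.integer(stride))
  id <- backbone_indices(traj$topology, "distal")
  ip <- backbone_indices(traj$topology, "proximal")
  if (!length(id) || !length(ip))
    stop("both subunits need at least one analysis residue with a backbone site")
  out <- matrix(0, nrow = length(sel), ncol = length(id) + length(ip))
  if (is.null(pbc_box)) {
    for (k in seq_along(sel)) {
      f <- sel[k]
      A <- traj$xyz[id, , f]; if (!is.matrix(A)) A <- matrix(A, ncol = 3)
      B <- traj$xyz[ip, , f]; if (!is.matrix(B)) B <- matrix(B, ncol = 3)
      out[k, ] <- .rmd_cpp(A, B)
    }
  } else {
    for (k in seq_along(sel))
      out[k, ] <- rmd_vector(get_frame(traj, sel[k]), traj$topology, pbc_box)
  }
  colnames(out) <- c(paste0("d", seq_along(id)), paste0("p", seq_along(ip)))
  attr(out, "frame_indices") <- sel
  attr(out, "times") <- traj$times[sel]
  out
}

#' Write an RMD series as TSV
#' @param rmd matrix from [rmd_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rmd <- function(rmd, path) {
  df <- data.frame(frame = attr(rmd, "frame_indices"),
                   time = attr(rmd, "times"), rmd, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an RMD series written by [write_rmd()]
#' @param path TSV path.
#' @return RMD matrix with frame-index and time attributes.
#' @export
read_rmd <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  attr(m, "frame_indices") <- df$frame
  attr(m, "times") <- df$time
  m
}
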