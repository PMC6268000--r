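#' Default particle radii (nm)
#'
#' Van der Waals radii used for SASA when the input does not provide its own.
#' Atomistic values are keyed by element symbol; coarse-grained beads fall
#' back to `cg_default`.
#'
#' @param cg_default radius (nm) assigned to beads with no element match.
#' @return named numeric vector of radii in nm.
#' @export
default_particle_radii <- function(cg_default = 0.23) {
  c(C = 0.170, N = 0.155, O = 0.152, S = 0.180, H = 0.120, P = 0.180,
    BEAD = cg_default)
}

#' Default polarity classes
#'
#' Polar/apolar classification used to split the interface area into a-SA and
#' p-SA. Atomistic: N and O polar, C and S apolar (hydrogens follow carbon).
#' Coarse-grained bead names starting with P or Q (polar/charged classes) and
#' backbone beads are polar; other beads apolar.
#'
#' @param name particle (atom or bead) name.
#' @param element element symbol, `NA` for beads.
#' @return character vector, `"polar"` or `"apolar"`.
#' @export
particle_polarity <- function(name, element = NA_character_) {
  ifelse(!is.na(element) & element %in% c("N", "O"), "polar",
    ifelse(!is.na(element) & element %in% c("C", "S", "H", "P"), "apolar",
      ifelse(grepl("^(P|Q|BB)", name), "polar", "apolar")))
}

.element_from_name <- function(name) {
  # PDB convention: strip digits, first alphabetic character
  e <- toupper(substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", name)), 1, 1))
  e[e == ""] <- NA_character_
  e
}

.lookup_radius <- function(element, radii) {
  r <- radii[match(element, names(radii))]
  r[is.na(r)] <- radii[["BEAD"]]
  unname(r)
}

#' Construct a conjugate topology
#'
#' A topology assigns every particle to a residue, every residue to the
#' distal or proximal subunit, flags the one backbone site per residue (the
#' C-alpha atom atomistically, the backbone bead in coarse-grained models)
#' and carries the polarity class and radius used by the SASA module.
#' Residues beyond `analysis_range` (for ubiquitin, the flexible C-terminal
#' tail 73-76) are kept for SASA but excluded from RMD descriptors.
#'
#' @param particles data frame with columns `subunit` ("distal"/"proximal"),
#'   `resno` (1-based within subunit), `resname`, `name`, `backbone`
#'   (logical), `polarity` ("polar"/"apolar"), `radius` (nm).
#' @param analysis_range last residue index (per subunit) entering the RMD
#'   descriptor; default 72.
#' @return object of class `conjugate_topology`.
#' @export
conjugate_topology <- function(particles, analysis_range = 72) {
  need <- c("subunit", "resno", "resname", "name", "backbone", "polarity",
            "radius")
  miss <- setdiff(need, names(particles))
  if (length(miss))
    stop("topology is missing columns: ", paste(miss, collapse = ", "))
  if (!all(particles$subunit %in% c("distal", "proximal")))
    stop("subunit labels must be 'distal' or 'proximal'")
  if (!all(particles$polarity %in% c("polar", "apolar")))
    stop("polarity must be 'polar' or 'apolar'")
  if (any(!is.finite(particles$radius)) || any(particles$radius <= 0))
    stop("all particle radii must be finite and positive")
  key <- paste(particles$subunit, particles$resno)
  nb <- tapply(particles$backbone, key, sum)
  bad <- names(nb)[nb != 1L]
  if (length(bad))
    stop("each residue needs exactly one backbone site; offending residue(s): ",
         paste(bad, collapse = ", "))
  particles$particle_id <- seq_len(nrow(particles))
  out <- list(particles = particles, analysis_range = analysis_range)
  class(out) <- "conjugate_topology"
  out
}

#' @export
print.conjugate_topology <- function(x, ...) {
  p <- x$particles
  for (s in c("distal", "proximal")) {
    ps <- p[p$subunit == s, ]
    cat(sprintf("  %s: %d residues, %d particles\n",
                s, length(unique(ps$resno)), nrow(ps)))
  }
  cat(sprintf("  RMD analysis range: residues 1..%d per subunit\n",
              x$analysis_range))
  invisible(x)
}

#' Indices of backbone sites of one subunit within the analysis range
#' @param topology a `conjugate_topology`.
#' @param subunit "distal" or "proximal".
#' @return integer particle indices, ordered by residue number.
#' @export
backbone_indices <- function(topology, subunit) {
  p <- topology$particles
  sel <- p$subunit == subunit & p$backbone & p$resno <= topology$analysis_range
  idx <- p$particle_id[sel]
  idx[order(p$resno[sel])]
}

#' Construct a single conjugate frame
#' @param xyz n x 3 coordinate matrix (nm).
#' @param time time stamp (ps).
#' @param box optional box vectors (nm).
#' @return object of class `conjugate_frame`.
#' @export
conjugate_frame <- function(xyz, time = 0, box = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("xyz must have three columns")
  if (any(!is.finite(xyz))) stop("all coordinates must be finite")
  structure(list(xyz = xyz, time = time, box = box),
            class = "conjugate_frame")
}

#' Construct a conjugate trajectory
#'
#' @param topology a `conjugate_topology`.
#' @param xyz array of dimension n_particles x 3 x n_frames (nm).
#' @param times per-frame time stamps (ps), non-decreasing.
#' @return object of class `conjugate_trajectory`.
#' @export
conjugate_trajectory <- function(topology, xyz, times = NULL) {
  stopifnot(inherits(topology, "conjugate_topology"))
  if (length(dim(xyz)) == 2) xyz <- array(xyz, dim = c(dim(xyz), 1L))
  if (dim(xyz)[1] != nrow(topology$particles))
    stop("coordinate count does not match topology particle count")
  if (any(!is.finite(xyz))) stop("all coordinates must be finite")
  nf <- dim(xyz)[3]
  if (is.null(times)) times <- as.numeric(seq_len(nf) - 1L)
  if (length(times) != nf) stop("one time stamp per frame is required")
  if (is.unsorted(times)) stop("time stamps must be non-decreasing")
  structure(list(topology = topology, xyz = xyz, times = times),
            class = "conjugate_trajectory")
}

#' @export
print.conjugate_trajectory <- function(x, ...) {
  cat(sprintf("conjugate_trajectory: %d frames, %d particles\n",
              n_frames(x), dim(x$xyz)[1]))
  print(x$topology)
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `conjugate_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$xyz)[3]

#' Extract one frame
#' @param traj a `conjugate_trajectory`.
#' @param i frame index (1-based).
#' @return a `conjugate_frame`.
#' @export
get_frame <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stop("frame index out of range: ", i)
  conjugate_frame(traj$xyz[, , i], time = traj$times[i])
}

# ---- readers ---------------------------------------------------------------

.residue_rank <- function(keys) match(keys, unique(keys))

.build_topology <- function(res_index, resname, atom_name, element,
                            linkage_spec, backbone_names, analysis_range,
                            radii, polarity) {
  n_res <- max(res_index)
  spans <- lapply(linkage_spec[c("distal", "proximal")], function(r) {
    if (is.null(r)) stop("linkage_spec needs 'distal' and 'proximal' ranges")
    if (length(r) == 2) seq.int(r[1], r[2]) else as.integer(r)
  })
  both <- intersect(spans$distal, spans$proximal)
  if (length(both))
    stop("residue(s) assigned to both subunits: ", paste(both, collapse = ", "))
  covered <- sort(c(spans$distal, spans$proximal))
  if (!identical(covered, seq_len(n_res)))
    stop("linkage_spec must cover every residue in the file exactly once")
  subunit <- ifelse(res_index %in% spans$distal, "distal", "proximal")
  # residue number restarts at 1 within each subunit
  resno <- integer(length(res_index))
  for (s in c("distal", "proximal")) {
    sel <- subunit == s
    resno[sel] <- .residue_rank(res_index[sel])
  }
  backbone <- atom_name %in% backbone_names
  if (is.null(radii)) radii <- default_particle_radii()
  rad <- .lookup_radius(element, radii)
  pol <- if (is.null(polarity)) particle_polarity(atom_name, element)
         else polarity
  parts <- data.frame(subunit = subunit, resno = resno, resname = resname,
                      name = atom_name, backbone = backbone, polarity = pol,
                      radius = rad, stringsAsFactors = FALSE)
  ok <- tryCatch(conjugate_topology(parts, analysis_range), error = identity)
  if (inherits(ok, "error")) {
    # name the file residue(s) lacking a backbone site for a clearer error
    key <- paste(subunit, resno)
    nb <- tapply(backbone, key, sum)
    bad <- names(nb)[nb != 1L]
    if (length(bad))
      stop("missing or duplicated backbone site (looked for ",
           paste(backbone_names, collapse = "/"), ") in residue(s): ",
           paste(bad, collapse = ", "))
    stop(ok)
  }
  ok
}

.read_gro <- function(path) {
  lines <- readLines(path)
  frames <- list(); atom <- NULL; times <- numeric(0)
  i <- 1L
  while (i <= length(lines)) {
    title <- lines[i]
    nat <- as.integer(trimws(lines[i + 1L]))
    block <- lines[(i + 2L):(i + 1L + nat)]
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    times <- c(times, if (length(tm)) as.numeric(sub("t=\\s*", "", tm))
                      else length(frames))
    xyz <- cbind(as.numeric(substr(block, 21, 28)),
                 as.numeric(substr(block, 29, 36)),
                 as.numeric(substr(block, 37, 44)))
    if (is.null(atom))
      atom <- data.frame(
        resno_file = as.integer(substr(block, 1, 5)),
        resname = trimws(substr(block, 6, 10)),
        name = trimws(substr(block, 11, 15)),
        stringsAsFactors = FALSE)
    frames[[length(frames) + 1L]] <- xyz
    i <- i + nat + 3L # title + natoms + atoms + box line
  }
  list(atom = atom, frames = frames, times = times)
}

#' Read a conjugate trajectory
#'
#' Reads a multi-model PDB (via bio3d) or a (possibly multi-frame) GRO file
#' and assigns each residue to the distal or proximal subunit.
#'
#' @param path input file.
#' @param format `"pdb"` or `"gro"`.
#' @param linkage_spec list with `distal` and `proximal`, each a range
#'   `c(first, last)` (or an index vector) over the residues in file order.
#'   The two ranges must cover all residues and must not overlap.
#' @param backbone_names particle names marking the one backbone site per
#'   residue; default `c("CA", "BB")` (atomistic C-alpha, CG backbone bead).
#' @param analysis_range residues 1..`analysis_range` per subunit enter the
#'   RMD descriptor (default 72).
#' @param radii optional named radius table (see [default_particle_radii()]).
#' @param polarity optional per-particle polarity overriding the default
#'   classification.
#' @return a [conjugate_trajectory()]. Coordinates are stored in nm (PDB
#'   angstroms are converted on read).
#' @export
read_conjugate <- function(path, format = c("pdb", "gro"), linkage_spec,
                           backbone_names = c("CA", "BB"),
                           analysis_range = 72, radii = NULL,
                           polarity = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    at <- pdb$atom
    res_key <- paste(at$chain, at$resno, at$insert)
    res_index <- .residue_rank(res_key)
    element <- at$elesy
    element[is.na(element) | element == ""] <- .element_from_name(
      at$elety[is.na(element) | element == ""])
    topo <- .build_topology(res_index, at$resid, at$elety, element,
                            linkage_spec, backbone_names, analysis_range,
                            radii, polarity)
    nf <- nrow(pdb$xyz)
    n <- nrow(at)
    xyz <- array(0, dim = c(n, 3, nf))
    for (f in seq_len(nf))
      xyz[, , f] <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE) / 10
    conjugate_trajectory(topo, xyz, times = as.numeric(seq_len(nf) - 1L))
  } else {
    g <- .read_gro(path)
    res_index <- .residue_rank(g$atom$resno_file)
    element <- .element_from_name(g$atom$name)
    is_bead <- !g$atom$name %in% c("CA", "C", "N", "O", "H", "S")
    element[is_bead & !g$atom$name %in% c("CA")] <- NA_character_
    topo <- .build_topology(res_index, g$atom$resname, g$atom$name, element,
                            linkage_spec, backbone_names, analysis_range,
                            radii, polarity)
    n <- nrow(g$atom)
    xyz <- array(unlist(g$frames), dim = c(n, 3, length(g$frames)))
    conjugate_trajectory(topo, xyz, times = g$times)
  }
}

# ---- writers ---------------------------------------------------------------

.pdb_fields <- function(traj) {
  p <- traj$topology$particles
  # distal -> chain A, proximal -> chain B; residue numbers restart per chain
  list(chain = ifelse(p$subunit == "distal", "A", "B"),
       resno = p$resno, resid = p$resname, elety = p$name)
}

#' Write a trajectory as a multi-model PDB
#'
#' Coordinates are converted from nm to angstroms. The distal subunit is
#' written as chain A, the proximal as chain B, so a file written here can be
#' re-read with a `linkage_spec` that lists the distal residues first.
#'
#' @param traj a `conjugate_trajectory`.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_conjugate <- function(traj, path) {
  f <- .pdb_fields(traj)
  nf <- n_frames(traj)
  n <- dim(traj$xyz)[1]
  xyz <- matrix(0, nrow = nf, ncol = 3 * n)
  for (i in seq_len(nf))
    xyz[i, ] <- as.vector(t(traj$xyz[, , i])) * 10
  bio3d::write.pdb(file = path, xyz = xyz, resno = f$resno, resid = f$resid,
                   elety = f$elety, chain = f$chain)
  invisible(path)
}

#' Export selected frames as single-model PDB files
#'
#' Used to hand basin-representative structures to downstream tools (e.g.
#' backmapping). Files are named `<prefix>_<frame>.pdb` with zero-padded
#' frame numbers.
#'
#' @param traj a `conjugate_trajectory`.
#' @param indices frame indices (1-based).
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of files written, invisibly.
#' @export
write_frames <- function(traj, indices, dir, prefix = "frame") {
  nf <- n_frames(traj)
  indices <- as.integer(indices)
  bad <- indices[indices < 1 | indices > nf]
  if (length(bad))
    stop("frame index out of range: ", paste(bad, collapse = ", "))
  if (!length(indices)) {
    warning("no frame indices given; nothing written")
    return(invisible(character(0)))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f <- .pdb_fields(traj)
  files <- character(length(indices))
  for (k in seq_along(indices)) {
    i <- indices[k]
    files[k] <- file.path(dir, sprintf("%s_%05d.pdb", prefix, i))
    bio3d::write.pdb(file = files[k],
                     xyz = as.vector(t(traj$xyz[, , i])) * 10,
                     resno = f$resno, resid = f$resid, elety = f$elety,
                     chain = f$chain)
  }
  invisible(files)
}
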