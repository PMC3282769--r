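# Van der Waals radii (Angstrom) for SASA; standard set.
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, SE = 1.90, NI = 1.63, ZN = 1.39, MG = 1.73,
               FE = 1.52, MN = 1.61, CA = 2.31, `NA` = 2.27, K = 2.75,
               CL = 1.75)

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records (via [bio3d::read.pdb()]) into a flat atom
#' table.  Alternate locations are resolved to the highest-occupancy
#' conformer; waters and hetero atoms are retained.  Coordinate fields are
#' validated up front so a malformed line is reported with its line number.
#'
#' @param path Path to a PDB file.
#' @return A `struct_model`: data.frame with columns `chain`, `resnum`,
#'   `resname`, `atom_name`, `element`, `x`, `y`, `z`, `occupancy`,
#'   `hetero`.
#' @export
read_pdb_atoms <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  atom_lines <- grep("^(ATOM  |HETATM)", lines)
  if (length(atom_lines) == 0L)
    stop("no ATOM/HETATM records in ", path, call. = FALSE)
  for (ln in atom_lines) {
    l <- lines[ln]
    for (f in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(l, f[1], f[2])))
      if (is.na(v))
        stop("malformed coordinate field at line ", ln, " of ", path,
             call. = FALSE)
    }
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                          rm.alt = FALSE))
  a <- pdb$atom
  # resolve altlocs: keep the highest-occupancy conformer per atom site
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
  occ <- ifelse(is.na(a$o), 1, a$o)
  keep <- unlist(lapply(split(seq_len(nrow(a)), key), function(ix) {
    ix[which.max(occ[ix])]
  }), use.names = FALSE)
  a <- a[sort(keep), ]
  occ <- occ[sort(keep)]
  elem <- toupper(trimws(a$elesy))
  guess <- toupper(substr(trimws(a$elety), 1, 1))
  elem[is.na(elem) | !nzchar(elem)] <- guess[is.na(elem) | !nzchar(elem)]
  model <- data.frame(
    chain = a$chain, resnum = a$resno, resname = a$resid,
    atom_name = trimws(a$elety), element = elem,
    x = a$x, y = a$y, z = a$z,
    occupancy = occ, hetero = a$type == "HETATM",
    stringsAsFactors = FALSE)
  class(model) <- c("struct_model", "data.frame")
  model
}

#' Build a structure model from raw atom data
#'
#' Constructor used for synthetic geometries in analyses and tests.
#'
#' @param element Character vector of element symbols.
#' @param x,y,z Coordinates (Angstrom).
#' @param chain,resnum,resname,atom_name Optional annotation columns.
#' @return A `struct_model` data.frame.
#' @export
struct_model <- function(element, x, y, z, chain = "A",
                         resnum = seq_along(x), resname = "UNK",
                         atom_name = element) {
  model <- data.frame(chain = chain, resnum = resnum, resname = resname,
                      atom_name = atom_name, element = toupper(element),
                      x = x, y = y, z = z, occupancy = 1, hetero = FALSE,
                      stringsAsFactors = FALSE)
  class(model) <- c("struct_model", "data.frame")
  model
}

coords_matrix <- function(model) {
  as.matrix(model[, c("x", "y", "z")])
}

#' Optimal rigid-body superposition (Kabsch) and RMSD
#'
#' Least-squares superposition of two paired coordinate sets using the
#' Kabsch SVD construction, constrained to a proper rotation (no
#' reflection).  The RMSD of the superposed sets is the residual.
#'
#' @param coords_a,coords_b n x 3 matrices of paired coordinates (n >= 3).
#' @return List: `rotation` (3 x 3), `translation` (length 3; the mapping
#'   is `a %*% t(rotation) + translation` onto b), `rmsd` (Angstrom).
#' @export
kabsch_rmsd <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (!is.numeric(a) || !is.numeric(b) || ncol(a) != 3L || ncol(b) != 3L)
    stop("coordinate sets must be n x 3 numeric matrices", call. = FALSE)
  n <- nrow(a)
  if (n != nrow(b)) stop("coordinate sets must be paired (equal length)",
                         call. = FALSE)
  if (n < 3L) stop("need at least 3 paired atoms", call. = FALSE)
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  for (m in list(a0, b0)) {
    sv <- svd(m)$d
    if (sv[2] < 1e-8 * max(sv[1], 1e-30))
      stop("degenerate (collinear) coordinate set", call. = FALSE)
  }
  h <- crossprod(a0, b0)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  corr <- diag(c(1, 1, d))
  rot <- sv$v %*% corr %*% t(sv$u)
  fitted <- a0 %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - b0)^2)))
  list(rotation = rot, translation = as.numeric(cb - ca %*% t(rot)),
       rmsd = rmsd)
}

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radii <- function(model) {
  elem <- toupper(model$element)
  unknown <- setdiff(unique(elem), names(VDW_RADII))
  if (length(unknown)) {
    i <- which(elem %in% unknown)[1]
    stop("no van der Waals radius for element '", elem[i], "' (atom ",
         model$atom_name[i], " ", model$chain[i], ":", model$resnum[i], ")",
         call. = FALSE)
  }
  unname(VDW_RADII[elem])
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA with a rolling probe: each atom's expanded sphere
#' (vdW radius + probe) is sampled with a deterministic golden-spiral
#' point set and points inside any neighbor's expanded sphere are
#' discarded.  Deterministic for a fixed point count; no randomness.
#'
#' @param model A `struct_model`.
#' @param probe_radius Probe radius in Angstrom (default 1.4, a water
#'   molecule).
#' @param n_points Sphere quadrature points per atom (default 960).
#' @return Numeric vector of per-atom areas (Angstrom^2); `sum()` gives
#'   the total SASA.
#' @export
sasa <- function(model, probe_radius = 1.4, n_points = 960L) {
  xyz <- coords_matrix(model)
  n <- nrow(xyz)
  radii <- atom_radii(model) + probe_radius
  pts <- sphere_points(n_points)
  areas <- numeric(n)
  if (n > 1) dmat <- as.matrix(stats::dist(xyz))
  for (i in seq_len(n)) {
    ri <- radii[i]
    neigh <- if (n > 1) which(dmat[i, ] < ri + radii & seq_len(n) != i)
             else integer()
    p <- sweep(pts * ri, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in neigh) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
            (p[, 3] - xyz[j, 3])^2
      acc <- acc & d2 >= radii[j]^2
      if (!any(acc)) break
    }
    areas[i] <- 4 * pi * ri^2 * sum(acc) / n_points
  }
  areas
}

resolve_selection <- function(model, sel) {
  if (is.logical(sel)) return(which(sel))
  if (is.numeric(sel)) return(as.integer(sel))
  if (is.character(sel) && length(sel) == 1L) {
    m <- regmatches(sel, regexec(
      "^([A-Za-z0-9])(?::([-0-9]+)-([-0-9]+))?$", sel))[[1]]
    if (length(m) == 0L)
      stop("cannot parse selection '", sel,
           "'; expected 'A' or 'A:320-337'", call. = FALSE)
    idx <- which(model$chain == m[2])
    if (nzchar(m[3]))
      idx <- idx[model$resnum[idx] >= as.integer(m[3]) &
                 model$resnum[idx] <= as.integer(m[4])]
    return(idx)
  }
  stop("unsupported selection", call. = FALSE)
}

#' Interface burial between two selections
#'
#' Computes, for each partner, the solvent-accessible area lost on
#' complexation: `SASA(partner alone) - SASA(partner in the two-partner
#' complex)`.  This is the metric behind statements like "~750 and ~610
#' square Angstrom of helix 13 and of the adjacent subunit body are buried
#' at each helix-body interface".
#'
#' @param model A `struct_model`.
#' @param selection_a,selection_b Disjoint atom selections: index vectors,
#'   logical masks, or strings like `"A:320-337"` (chain, residue range).
#' @param probe_radius Probe radius (default 1.4 Angstrom).
#' @param n_points Quadrature points per atom.
#' @return Named numeric vector `c(buried_a = , buried_b = )` in
#'   Angstrom^2.
#' @export
buried_interface_area <- function(model, selection_a, selection_b,
                                  probe_radius = 1.4, n_points = 960L) {
  ia <- resolve_selection(model, selection_a)
  ib <- resolve_selection(model, selection_b)
  if (length(ia) == 0L || length(ib) == 0L)
    stop("empty selection", call. = FALSE)
  if (length(intersect(ia, ib)))
    stop("selections overlap", call. = FALSE)
  ma <- model[ia, ]; mb <- model[ib, ]
  complex <- model[c(ia, ib), ]
  sa_alone <- sum(sasa(ma, probe_radius, n_points))
  sb_alone <- sum(sasa(mb, probe_radius, n_points))
  s_complex <- sasa(complex, probe_radius, n_points)
  na <- length(ia)
  sa_cplx <- sum(s_complex[seq_len(na)])
  sb_cplx <- sum(s_complex[-seq_len(na)])
  c(buried_a = sa_alone - sa_cplx, buried_b = sb_alone - sb_cplx)
}

#' Metal coordination site analysis
#'
#' Finds atoms of the given element and reports their coordination shell:
#' all non-metal atoms within the distance cutoff, with distances, plus a
#' geometry call.  The geometry is `octahedral` when there are exactly six
#' ligands whose inter-ligand angles (at the metal) partition into twelve
#' near-90-degree and three near-180-degree angles within the tolerance;
#' anything else is `other`.  This is the test used for the trimer-axis Ni
#' site octahedrally coordinated by three His N atoms and three waters.
#'
#' @param model A `struct_model`.
#' @param element Metal element symbol (default `"NI"`).
#' @param distance_cutoff Ligand distance cutoff (default 2.6 Angstrom).
#' @param angle_tolerance Allowed deviation from 90/180 degrees (default
#'   20).
#' @return List of per-metal reports: `metal` (row of the metal atom),
#'   `ligands` (data.frame with `distance`), `geometry`,
#'   `angle_deviations` (degrees).  Empty list when the element is absent.
#' @export
metal_site <- function(model, element = "NI", distance_cutoff = 2.6,
                       angle_tolerance = 20) {
  element <- toupper(element)
  metals <- which(model$element == element)
  lapply(metals, function(mi) {
    xyz <- coords_matrix(model)
    d <- sqrt(colSums((t(xyz) - xyz[mi, ])^2))
    lig <- which(d <= distance_cutoff & seq_len(nrow(model)) != mi &
                 model$element != element)
    ligands <- model[lig, ]
    ligands$distance <- d[lig]
    geometry <- "other"
    devs <- numeric()
    if (length(lig) == 6L) {
      v <- sweep(xyz[lig, ], 2, xyz[mi, ])
      v <- v / sqrt(rowSums(v^2))
      ang <- c()
      for (p in 1:5) for (q in (p + 1):6)
        ang <- c(ang, acos(max(-1, min(1, sum(v[p, ] * v[q, ])))) * 180 / pi)
      near90 <- abs(ang - 90) <= angle_tolerance
      near180 <- abs(ang - 180) <= angle_tolerance
      if (sum(near90) == 12L && sum(near180) == 3L && all(near90 | near180)) {
        geometry <- "octahedral"
        devs <- ifelse(near180, abs(ang - 180), abs(ang - 90))
      }
    }
    list(metal = model[mi, ], ligands = ligands, geometry = geometry,
         angle_deviations = devs)
  })
}
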