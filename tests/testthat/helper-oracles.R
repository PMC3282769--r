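# Independent oracles used across the suite.  Each re-derives a quantity by
# a different route than the implementation under test.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

# Gotoh affine-gap global alignment score, three-matrix DP, where a gap run
# of length L costs open + L * extend (the package's stated convention).
oracle_align_score <- function(sa, sb, mat, open = 10, extend = 0.5) {
  a <- strsplit(sa, "")[[1]]; b <- strsplit(sb, "")[[1]]
  n <- length(a); m <- length(b)
  neg <- -1e18
  M <- matrix(neg, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + i * extend)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(open + j * extend)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- mat[a[i], b[j]]
    M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
    Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                            Ix[i, j + 1] - extend,
                            Iy[i, j + 1] - open - extend)
    Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                            Iy[i + 1, j] - extend,
                            Ix[i + 1, j] - open - extend)
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Naive per-offset motif checker over explicit allowed-residue sets.
# `sets` is a list, one element per position: either "X" (wildcard) or a
# character vector of allowed residues.
naive_scan_starts <- function(seqstr, sets, window = NULL) {
  chars <- strsplit(seqstr, "")[[1]]
  plen <- length(sets)
  lo <- if (is.null(window)) 1L else window[1]
  hi <- if (is.null(window)) length(chars) else window[2]
  starts <- integer()
  s <- lo
  while (s + plen - 1L <= hi) {
    ok <- TRUE
    for (k in seq_len(plen)) {
      res <- chars[s + k - 1L]
      if (identical(sets[[k]], "X")) { next }
      if (res == "X" || !(res %in% sets[[k]])) { ok <- FALSE; break }
    }
    if (ok) starts <- c(starts, s)
    s <- s + 1L
  }
  starts
}

# Random degenerate pattern: for property tests.  Returns the notation
# string plus the equivalent allowed-set list for the naive checker.
random_pattern <- function(max_len = 5L) {
  plen <- sample(2:max_len, 1)
  sets <- vector("list", plen)
  parts <- character(plen)
  for (k in seq_len(plen)) {
    kind <- sample(c("exact", "group", "wild"), 1,
                   prob = c(0.4, 0.4, 0.2))
    if (kind == "wild") {
      sets[[k]] <- "X"; parts[k] <- "X"
    } else if (kind == "exact") {
      r <- sample(AA20, 1)
      sets[[k]] <- r; parts[k] <- r
    } else {
      nprim <- sample(1:2, 1); nsec <- sample(0:2, 1)
      res <- sample(AA20, nprim + nsec)
      prim <- res[seq_len(nprim)]
      sec <- if (nsec) res[nprim + seq_len(nsec)] else character()
      sets[[k]] <- res
      parts[k] <- paste0("(", paste(c(prim, tolower(sec)), collapse = "/"),
                         ")")
    }
  }
  list(text = paste(parts, collapse = ""), sets = sets)
}

# Closed-form SASA of two intersecting spheres (expanded radii R1, R2 at
# distance d): each sphere loses a spherical cap of area 2*pi*R*h.
oracle_two_sphere_sasa <- function(r1, r2, probe, d) {
  R1 <- r1 + probe; R2 <- r2 + probe
  full <- 4 * pi * c(R1^2, R2^2)
  if (d >= R1 + R2) return(full)
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  full - 2 * pi * c(R1 * h1, R2 * h2)
}

# Numeric-minimization superposition oracle: search rotation space (Euler
# angles) with Nelder-Mead restarts, translations handled by centering.
oracle_min_rmsd <- function(a, b, n_starts = 12L) {
  a0 <- sweep(a, 2, colMeans(a)); b0 <- sweep(b, 2, colMeans(b))
  rotmat <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
    ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
    rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
    rz %*% ry %*% rx
  }
  obj <- function(ang) sqrt(mean(rowSums((a0 %*% t(rotmat(ang)) - b0)^2)))
  best <- Inf
  set.seed(99)
  for (k in seq_len(n_starts)) {
    st <- runif(3, -pi, pi)
    o <- optim(st, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    o <- optim(o$par, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    if (o$value < best) best <- o$value
  }
  best
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# Minimal handwritten PDB writer for fixtures.
write_mini_pdb <- function(path, atoms) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            ifelse(isTRUE(a$hetero), "HETATM", "ATOM"), i,
            substr(a$atom_name, 1, 4), ifelse(is.null(a$alt), "", a$alt),
            a$resname, a$chain, a$resnum, "",
            a$x, a$y, a$z, ifelse(is.null(a$occ), 1, a$occ), 0,
            a$element)
  }, character(1))
  writeLines(c(lines, "END"), path)
}

rule_statuses <- function(report) {
  vapply(report$outcomes, `[[`, character(1), "status")
}
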