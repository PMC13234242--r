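# Fixtures and independent oracles shared across the suite.  Oracles here
# are deliberately written with different machinery than the package code
# they check.

# -- minimal hand-built structures -----------------------------------------

# one glycine-like residue, three atoms
fixture_three_atoms <- function() {
  atoms <- data.frame(
    serial = 1:3, name = c("N", "CA", "C"), resid = "GLY", chain = "A",
    resno = 1L, insert = "", x = c(0, 1.458, 1.996),
    y = c(0, 0, 1.404), z = c(0, 0, 0),
    occupancy = 1, b = 0, elesy = c("N", "C", "C"), het = FALSE,
    stringsAsFactors = FALSE)
  new_structure(atoms, id = "fix3")
}

# two isolated "atoms" at a controlled separation, plus one extra residue
fixture_pair <- function(d) {
  atoms <- data.frame(
    serial = 1:2, name = c("OD1", "N"), resid = c("ASN", "LEU"),
    chain = "A", resno = c(1L, 3L), insert = "",
    x = c(0, d), y = 0, z = 0, occupancy = 1, b = 0,
    elesy = c("O", "N"), het = FALSE, stringsAsFactors = FALSE)
  new_structure(atoms, id = "pair")
}

# -- independent torsion oracle (praxeolitic formula, distinct from the
#    package's normal-vector construction) --------------------------------
oracle_dihedral <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- p3 - p2
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(.cross_oracle(b1, v) * w)
  atan2(y, x) * 180 / pi
}
.cross_oracle <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

# -- brute-force all-pairs contact scan ------------------------------------
oracle_contacts <- function(structure, target_atoms, cutoff) {
  a <- structure$atoms
  a <- a[a$elesy != "H", , drop = FALSE]
  tkey <- paste(target_atoms$chain, target_atoms$resno, target_atoms$name)
  akey <- paste(a$chain, a$resno, a$name)
  res <- list()
  for (i in seq_len(nrow(target_atoms))) {
    for (j in seq_len(nrow(a))) {
      if (akey[j] %in% tkey) next
      if (a$resno[j] == target_atoms$resno[i] &&
          a$chain[j] == target_atoms$chain[i]) next
      d <- sqrt(sum((c(target_atoms$x[i], target_atoms$y[i],
                       target_atoms$z[i]) -
                       c(a$x[j], a$y[j], a$z[j]))^2))
      if (d <= cutoff)
        res[[length(res) + 1L]] <- data.frame(
          name_a = target_atoms$name[i], resno_b = a$resno[j],
          name_b = a$name[j], distance = d, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(NULL)
  do.call(rbind, res)
}

# -- elemental-composition mass oracle -------------------------------------
# independent of the package residue-mass table: sums element counts per
# residue and multiplies by isotope masses
.elem_mass <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
                O = 15.9949146221, S = 31.97207069)
.residue_formula <- list(  # residue (in-chain) compositions C,H,N,O,S
  G = c(2, 3, 1, 1, 0), A = c(3, 5, 1, 1, 0), S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0), V = c(5, 9, 1, 1, 0), T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1), L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0), D = c(4, 5, 1, 3, 0), Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0), M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0), F = c(9, 9, 1, 1, 0), R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0), W = c(11, 10, 2, 1, 0))
oracle_peptide_mass <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  counts <- Reduce(`+`, .residue_formula[aa])
  counts <- counts + c(0, 2, 0, 1, 0)  # + H2O
  sum(counts * .elem_mass[c("C", "H", "N", "O", "S")])
}

# -- exhaustive minimax-path oracle: threshold connectivity ----------------
# minimal level L such that start and end are connected through nodes with
# value <= L (checked for every candidate level; exhaustive and exact)
oracle_minimax <- function(values, start_idx, end_idx) {
  nx <- nrow(values); ny <- ncol(values)
  levels <- sort(unique(as.vector(values)))
  for (L in levels) {
    ok <- values <= L
    if (!ok[start_idx[1], start_idx[2]] || !ok[end_idx[1], end_idx[2]])
      next
    # BFS flood fill from start over allowed nodes
    seen <- matrix(FALSE, nx, ny)
    queue <- list(start_idx)
    seen[start_idx[1], start_idx[2]] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (dx in -1:1) for (dy in -1:1) {
        if (dx == 0 && dy == 0) next
        i <- cur[1] + dx; j <- cur[2] + dy
        if (i < 1 || i > nx || j < 1 || j > ny) next
        if (!ok[i, j] || seen[i, j]) next
        seen[i, j] <- TRUE
        queue[[length(queue) + 1L]] <- c(i, j)
      }
    }
    if (seen[end_idx[1], end_idx[2]]) return(L)
  }
  stop("never connected")
}

# random rigid motion (rotation + translation), seeded by caller
random_rigid_motion <- function() {
  th <- stats::runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  list(R = Rx %*% Ry %*% Rz, t = stats::runif(3, -20, 20))
}

apply_rigid <- function(structure, motion) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  moved <- xyz %*% t(motion$R) +
    matrix(motion$t, nrow(xyz), 3, byrow = TRUE)
  structure$atoms$x <- moved[, 1]
  structure$atoms$y <- moved[, 2]
  structure$atoms$z <- moved[, 3]
  structure
}

# canonical succinimide-site peptide: Glu-Asn-Asp-Leu with the Asn in the
# near-attack-like geometry reported for the deposited double-mutant
# structure (phi -129.3, psi 148.6, chi1 173.9, chi2 -99.6); the resulting
# CG to N(n+1) distance is close to 3.0 Angstrom
fixture_near_attack_peptide <- function() {
  build_peptide("ENDL",
                phi = c(NA, -129.3, -46.3, -120),
                psi = c(140, 148.6, -34.1, NA),
                chi1 = c(NA, 173.9, NA, NA),
                chi2 = c(NA, -99.6, NA, NA))
}
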