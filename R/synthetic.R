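# Seed-deterministic generators for every input class the pipeline needs:
# ideal-geometry peptides with prescribed torsions, hills streams sampled
# on analytic surfaces with known saddle heights, trajectories with
# scripted events, and mutated sequences.

# Place atom D given positions A, B, C, the bond length |C-D|, the angle
# B-C-D (degrees) and the torsion A-B-C-D (degrees): standard
# internal-to-Cartesian (NeRF) construction.
.place_atom <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- .cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an ideal-geometry peptide with prescribed torsions
#'
#' Grows a peptide chain by internal coordinates with ideal bond lengths
#' and angles, imposing the requested backbone (phi, psi, omega) and
#' side-chain (chi1, chi2) torsions.  Asn and Asp side chains are built to
#' full depth (CB, CG, OD1, ND2/OD2) so succinimide-site geometry can be
#' constructed exactly; other residues are built through CB (plus a
#' generic CG where chi1 is requested).  Measured torsions equal the
#' requested ones to well under 0.1 degrees away from termini; steric
#' clashes (< 0.5 Angstrom between nonbonded atoms) trigger a warning, not
#' an error - the builder's fidelity target is torsion round-trip, not
#' physical realism.
#'
#' @param sequence one-letter amino-acid string; use `"ASN"`-position
#'   residues via standard codes (an `N`).  A residue can be flagged as
#'   succinimide via `snn_at`.
#' @param phi,psi,omega per-residue backbone torsions in degrees (recycled;
#'   `phi[1]` and terminal `psi`/`omega` entries are ignored as undefined).
#'   Defaults: extended chain (phi -139, psi 135, omega 180).
#' @param chi1,chi2 per-residue side-chain torsions in degrees (recycled;
#'   `NA` skips side-chain construction beyond CB).
#' @param snn_at optional residue position whose residue name is written as
#'   `SNN` (atom labels keep the Asn-like CB/CG/OD1 mapping).
#' @param chain chain identifier (default "A").
#' @return `snn_structure`.
#' @export
build_peptide <- function(sequence, phi = -139, psi = 135, omega = 180,
                          chi1 = NA, chi2 = NA, snn_at = NULL,
                          chain = "A") {
  aa <- .check_sequence(sequence)
  n <- length(aa)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  omega <- rep_len(omega, n)
  chi1 <- rep_len(chi1, n); chi2 <- rep_len(chi2, n)
  g <- .ideal_geom
  # backbone: seed residue 1 in a canonical frame
  N <- list(); CA <- list(); C <- list(); O <- list()
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(g$b_N_CA, 0, 0)
  ang <- g$a_N_CA_C * pi / 180
  C[[1]] <- CA[[1]] + g$b_CA_C * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)[-1]) {
    N[[i]] <- .place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]],
                          g$b_C_N, g$a_CA_C_N, psi[i - 1])
    CA[[i]] <- .place_atom(CA[[i - 1]], C[[i - 1]], N[[i]],
                           g$b_N_CA, g$a_C_N_CA, omega[i])
    C[[i]] <- .place_atom(C[[i - 1]], N[[i]], CA[[i]],
                          g$b_CA_C, g$a_N_CA_C, phi[i])
  }
  for (i in seq_len(n)) {
    # carbonyl O antiperiplanar to the next N (psi + 180)
    psi_eff <- if (i < n) psi[i] else if (!is.na(psi[i])) psi[i] else 135
    O[[i]] <- .place_atom(N[[i]], CA[[i]], C[[i]],
                          g$b_C_O, g$a_CA_C_O, .wrap180(psi_eff + 180))
  }
  rows <- list()
  serial <- 0L
  add <- function(resno, resid, name, xyz, elesy) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, name = name, resid = resid, chain = chain,
      resno = resno, insert = "", x = xyz[1], y = xyz[2], z = xyz[3],
      occupancy = 1, b = 0, elesy = elesy, het = resid == "SNN",
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    resid <- aa123(aa[i])
    if (!is.null(snn_at) && i %in% snn_at) resid <- "SNN"
    add(i, resid, "N", N[[i]], "N")
    add(i, resid, "CA", CA[[i]], "C")
    add(i, resid, "C", C[[i]], "C")
    add(i, resid, "O", O[[i]], "O")
    if (aa[i] == "G") next
    CB <- .place_atom(C[[i]], N[[i]], CA[[i]], g$b_CA_CB, g$a_N_CA_CB,
                      g$t_CB)
    add(i, resid, "CB", CB, "C")
    if (is.na(chi1[i])) next
    CG <- .place_atom(N[[i]], CA[[i]], CB, g$b_CB_CG, g$a_CA_CB_CG,
                      chi1[i])
    add(i, resid, if (aa[i] %in% c("I", "V")) "CG1" else "CG", CG, "C")
    if (is.na(chi2[i])) next
    if (aa[i] == "N" || resid == "SNN") {
      OD1 <- .place_atom(CA[[i]], CB, CG, g$b_CG_OD1, g$a_CB_CG_OD1,
                         chi2[i])
      ND2 <- .place_atom(CA[[i]], CB, CG, g$b_CG_ND2, g$a_CB_CG_ND2,
                         .wrap180(chi2[i] + 180))
      add(i, resid, "OD1", OD1, "O")
      add(i, resid, "ND2", ND2, "N")
    } else if (aa[i] == "D") {
      OD1 <- .place_atom(CA[[i]], CB, CG, g$b_CG_OD1, g$a_CB_CG_OD1,
                         chi2[i])
      OD2 <- .place_atom(CA[[i]], CB, CG, g$b_CG_OD2, g$a_CB_CG_OD1,
                         .wrap180(chi2[i] + 180))
      add(i, resid, "OD1", OD1, "O")
      add(i, resid, "OD2", OD2, "O")
    } else {
      X <- .place_atom(CA[[i]], CB, CG, 1.52, 114, chi2[i])
      add(i, resid, .chi2_atom[resid], X, substr(.chi2_atom[resid], 1, 1))
    }
  }
  atoms <- do.call(rbind, rows)
  # steric check over nonbonded pairs (different residues, > 2 apart or
  # non-backbone): warn on collapse
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  dm <- as.matrix(dist(xyz))
  close_pairs <- which(dm < 0.5 & upper.tri(dm), arr.ind = TRUE)
  if (nrow(close_pairs)) {
    nonbonded <- abs(atoms$resno[close_pairs[, 1]] -
                       atoms$resno[close_pairs[, 2]]) > 0
    if (any(nonbonded))
      warning("steric collapse: nonbonded atoms closer than 0.5 Angstrom",
              call. = FALSE)
  }
  new_structure(atoms, id = paste0("pept_", sequence),
                source_format = "built")
}

# ---- analytic surfaces and hills -----------------------------------------

#' Analytic 2D surface as a sum of Gaussian wells/barriers
#'
#' @param centers matrix (k x 2) of feature centers in CV units.
#' @param depths numeric k: negative = well, positive = bump (kcal/mol).
#' @param widths numeric k (isotropic Gaussian sigma, CV units).
#' @param bounds domain bounds `c(lo, hi)` per CV (default -0.8..0.8).
#' @return object of class `surface_spec`; evaluate with
#'   [surface_energy()], locate the exact minimax saddle with
#'   [surface_saddle()].
#' @export
surface_spec <- function(centers, depths, widths,
                         bounds = c(-0.8, 0.8)) {
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 2, nrow(centers) == length(depths),
            length(widths) == length(depths), all(widths > 0),
            all(is.finite(depths)))
  structure(list(centers = centers, depths = depths, widths = widths,
                 bounds = bounds), class = "surface_spec")
}

#' Default two-basin test surface
#'
#' Two Gaussian wells of the given depth at (-0.4, -0.4) and (+0.4, +0.4),
#' mirroring the reactant/product endpoints of a two-CV deprotonation
#' coordinate; the saddle between them sits near the origin, `barrier`
#' kcal/mol above the well floor (computable exactly with
#' [surface_saddle()]).
#'
#' @param barrier well depth in kcal/mol (default 5).
#' @param width well Gaussian sigma in CV units (default 0.18).
#' @export
double_well_surface <- function(barrier = 5, width = 0.18) {
  surface_spec(rbind(c(-0.4, -0.4), c(0.4, 0.4)),
               depths = c(-barrier, -barrier), widths = c(width, width))
}

#' Evaluate an analytic surface
#'
#' @param spec `surface_spec`.
#' @param x,y CV coordinates (vectorized).
#' @return energy in kcal/mol.
#' @export
surface_energy <- function(spec, x, y) {
  stopifnot(inherits(spec, "surface_spec"))
  e <- 0
  for (k in seq_along(spec$depths))
    e <- e + spec$depths[k] *
      exp(-((x - spec$centers[k, 1])^2 + (y - spec$centers[k, 2])^2) /
            (2 * spec$widths[k]^2))
  e
}

#' Exact minimax saddle height of an analytic surface by dense-grid search
#'
#' Threshold-connectivity barrier between two points, evaluated on a dense
#' grid of the analytic form; serves as the construction oracle for FES
#' reconstruction tests.
#'
#' @param spec `surface_spec`.
#' @param from,to CV points.
#' @param n dense grid nodes per axis (default 241).
#' @return barrier height in kcal/mol relative to the energy at `from`.
#' @export
surface_saddle <- function(spec, from = c(-0.4, -0.4), to = c(0.4, 0.4),
                           n = 241) {
  ax <- seq(spec$bounds[1], spec$bounds[2], length.out = n)
  u <- outer(ax, ax, function(x, y) surface_energy(spec, x, y))
  fes <- structure(list(axes = list(ax, ax), values = u - min(u),
                        spacing = rep(diff(ax[1:2]), 2)),
                   class = "fes_grid")
  p <- min_free_energy_path(fes, from, to, mode = "minimax")
  p$barrier
}

#' Generate a hills stream by a metadynamics-like walk on an analytic
#' surface
#'
#' A Metropolis walker moves on `surface + current bias`; a Gaussian hill
#' is deposited at the walker position every `stride` steps.  As in
#' nontempered metadynamics, the accumulated bias flattens the visited
#' basins, so the negated hill sum approximates the surface (up to an
#' additive constant) wherever the walker has been.  The walk is an oracle
#' device for testing free-energy reconstruction, not a physics engine.
#'
#' @param spec `surface_spec`.
#' @param n_hills number of hills to deposit (default 20000).
#' @param sigma per-CV hill widths (default 0.005, 0.006).
#' @param height hill height, kcal/mol (default 0.59).
#' @param seed integer seed; identical seeds give identical hill lists.
#' @param kT Metropolis temperature, kcal/mol (default 0.6).
#' @param step proposal standard deviation, CV units (default 0.02).
#' @param stride proposals per deposited hill (default 100; the walker
#'   must re-equilibrate locally between depositions).
#' @param walkers number of independent walkers sharing the accumulated
#'   bias, with deposits interleaved round-robin (default 1).
#' @param start walker start point (default the first surface center;
#'   walkers beyond the first start on successive surface centers).
#' @param time_per_hill ps between hills for the time column (default 0.1,
#'   i.e. one hill per 100 fs).
#' @return `snn_hills` data.frame.
#' @export
gen_hills_on_surface <- function(spec, n_hills = 20000,
                                 sigma = c(0.005, 0.006), height = 0.59,
                                 seed = 1, kT = 0.6, step = 0.02,
                                 stride = 100L, walkers = 1L,
                                 start = NULL, time_per_hill = 0.1) {
  stopifnot(inherits(spec, "surface_spec"), n_hills > 0)
  set.seed(seed)
  lo <- spec$bounds[1]; hi <- spec$bounds[2]
  # surface and bias kept on a fine lookup grid so each Metropolis step is
  # a pair of array reads; resolution of half a hill sigma
  res <- min(sigma) / 2
  ax <- seq(lo, hi, by = res)
  ng <- length(ax)
  Ug <- outer(ax, ax, function(x, y) surface_energy(spec, x, y))
  Eg <- Ug                                   # U + V, updated per deposit
  # precomputed hill patch on the lookup grid (+/- 5 sigma)
  px <- seq(-5 * sigma[1], 5 * sigma[1], by = res)
  py <- seq(-5 * sigma[2], 5 * sigma[2], by = res)
  patch <- height * outer(exp(-px^2 / (2 * sigma[1]^2)),
                          exp(-py^2 / (2 * sigma[2]^2)))
  hw_x <- (length(px) - 1L) %/% 2L
  hw_y <- (length(py) - 1L) %/% 2L
  walkers <- base::max(1L, as.integer(walkers))
  wpos <- matrix(0, walkers, 2)
  for (w in seq_len(walkers))
    wpos[w, ] <- if (is.null(start))
      spec$centers[((w - 1L) %% nrow(spec$centers)) + 1L, ] else start
  wix <- pmin(pmax(1L, as.integer(round((wpos[, 1] - lo) / res)) + 1L), ng)
  wiy <- pmin(pmax(1L, as.integer(round((wpos[, 2] - lo) / res)) + 1L), ng)
  centers <- matrix(0, n_hills, 2)
  inv_kT <- 1 / kT
  for (h in seq_len(n_hills)) {
    w <- ((h - 1L) %% walkers) + 1L
    pos <- wpos[w, ]; ix <- wix[w]; iy <- wiy[w]
    e_cur <- Eg[ix, iy]
    dxy <- matrix(stats::rnorm(2L * stride, 0, step), stride, 2)
    uu <- stats::runif(stride)
    for (s in seq_len(stride)) {
      p1 <- pos[1] + dxy[s, 1]; p2 <- pos[2] + dxy[s, 2]
      if (p1 < lo) p1 <- lo else if (p1 > hi) p1 <- hi
      if (p2 < lo) p2 <- lo else if (p2 > hi) p2 <- hi
      jx <- as.integer(round((p1 - lo) / res)) + 1L
      jy <- as.integer(round((p2 - lo) / res)) + 1L
      if (jx < 1L) jx <- 1L else if (jx > ng) jx <- ng
      if (jy < 1L) jy <- 1L else if (jy > ng) jy <- ng
      e_new <- Eg[jx, jy]
      if (uu[s] < exp((e_cur - e_new) * inv_kT)) {
        pos <- c(p1, p2); ix <- jx; iy <- jy; e_cur <- e_new
      }
    }
    centers[h, ] <- pos
    sx <- max(1L, ix - hw_x):min(ng, ix + hw_x)
    sy <- max(1L, iy - hw_y):min(ng, iy + hw_y)
    Eg[sx, sy] <- Eg[sx, sy] +
      patch[sx - ix + hw_x + 1L, sy - iy + hw_y + 1L, drop = FALSE]
    wpos[w, ] <- pos; wix[w] <- ix; wiy[w] <- iy
  }
  hills_table(time = seq_len(n_hills) * time_per_hill, centers,
              sigma = sigma, height = height)
}

# ---- scripted trajectories -----------------------------------------------

#' Generate a trajectory with positional noise and scripted events
#'
#' Frames are the reference coordinates plus seeded Gaussian positional
#' noise.  Each event moves one atom to a target position, interpolating
#' linearly over `ramp` frames ending at the event frame and holding the
#' target afterwards (e.g. a proton transferred from a backbone amide
#' donor to an acceptor oxygen).
#'
#' @param reference `snn_structure` used as topology and mean positions.
#' @param n_frames number of frames.
#' @param noise_sd positional noise standard deviation, Angstrom (default
#'   0).
#' @param events list of `list(frame=, atom=, target=)`, where `atom` is
#'   an atom selector (see [distance_series()]) and `target` a 3-vector.
#' @param ramp frames over which an event interpolates (default 5).
#' @param timestep ps per frame (default 1).
#' @param seed integer seed.
#' @return `snn_trajectory`.
#' @export
gen_trajectory <- function(reference, n_frames, noise_sd = 0,
                           events = list(), ramp = 5, timestep = 1,
                           seed = 1) {
  stopifnot(inherits(reference, "snn_structure"), n_frames >= 1)
  set.seed(seed)
  ref <- as.matrix(reference$atoms[, c("x", "y", "z")])
  natoms <- nrow(ref)
  coords <- array(0, dim = c(n_frames, natoms, 3))
  base <- array(rep(ref, each = n_frames),
                dim = c(n_frames, natoms, 3))
  for (ev in events) {
    if (ev$frame < 1 || ev$frame > n_frames)
      stop("event frame ", ev$frame, " outside 1..", n_frames)
    ia <- .atom_index(reference, ev$atom)
    from <- ref[ia, ]
    startf <- max(1L, ev$frame - ramp + 1L)
    for (f in startf:n_frames) {
      w <- if (f >= ev$frame) 1 else (f - startf + 1) / (ev$frame - startf + 1)
      base[f, ia, ] <- (1 - w) * from + w * ev$target
    }
  }
  noise <- array(stats::rnorm(n_frames * natoms * 3, 0, noise_sd),
                 dim = c(n_frames, natoms, 3))
  coords <- base + noise
  new_trajectory(reference, coords, timestep = timestep)
}

# ---- sequence mutation ----------------------------------------------------

#' Apply point mutations to a protein sequence
#'
#' Mutations use the conventional `"D110V"` notation; multi-mutation
#' strings joined by underscores (`"D110V_K151L"`) and character vectors
#' are both accepted.  The stated wild-type residue is checked against the
#' sequence and a mismatch is an error naming the position.  Mutations
#' commute.
#'
#' @param sequence one-letter protein sequence.
#' @param mutations character vector of mutations.
#' @return mutated sequence string.
#' @export
mutate_sequence <- function(sequence, mutations) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  muts <- unlist(strsplit(mutations, "_", fixed = TRUE))
  for (m in muts) {
    ok <- grepl("^[A-Z][0-9]+[A-Z]$", m)
    if (!ok) stop("malformed mutation spec '", m, "' (expected e.g. D110V)")
    from <- substr(m, 1, 1)
    to <- substr(m, nchar(m), nchar(m))
    pos <- as.integer(substr(m, 2, nchar(m) - 1))
    if (pos < 1 || pos > length(aa))
      stop("mutation ", m, ": position ", pos, " outside the sequence")
    if (aa[pos] != from)
      stop("mutation ", m, ": sequence has ", aa[pos], " at position ",
           pos, ", not ", from)
    aa[pos] <- to
  }
  paste(aa, collapse = "")
}
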