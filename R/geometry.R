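# Metric geometry on structures: torsions, distance contacts, hydrogen
# bonds, alpha/beta turns, and rigid-body superposition with iterative
# outlier rejection.

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

.wrap180 <- function(x) {
  out <- ((x + 180) %% 360) - 180
  out[out <= -180 + 1e-12] <- 180
  out
}

#' Torsion angle of four points
#'
#' IUPAC-signed dihedral in degrees, in the half-open interval (-180, 180]:
#' looking from `p2` towards `p3`, a clockwise rotation of `p4` relative to
#' `p1` is positive.  cis = 0, trans = 180.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sqrt(sum(b1^2)) < 1e-8 || sqrt(sum(b2^2)) < 1e-8 ||
      sqrt(sum(b3^2)) < 1e-8)
    stop("undefined torsion: consecutive points coincide")
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16)
    stop("undefined torsion: collinear point triplet")
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  .wrap180(-atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi)
}

# angle p1-p2-p3 in degrees
.angle3 <- function(p1, p2, p3) {
  v1 <- p1 - p2; v2 <- p3 - p2
  acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
}

.dist3 <- function(p, q) sqrt(sum((p - q)^2))

#' Backbone torsions of one residue
#'
#' phi is C(i-1)-N-CA-C, psi is N-CA-C-N(i+1), omega is
#' CA(i-1)-C(i-1)-N-CA.  At chain termini (or with missing backbone atoms)
#' the affected angle is `NA` with a warning rather than an error.
#'
#' @param structure `snn_structure`.
#' @param chain chain id.
#' @param resnum author residue number.
#' @return list with numeric `phi`, `psi`, `omega` (degrees, `NA` when
#'   undefined).
#' @export
backbone_dihedrals <- function(structure, chain, resnum) {
  res <- .chain_residues(structure, chain)
  i <- which(res$resno == resnum)
  if (!length(i))
    stop("no residue ", resnum, " in chain ", chain)
  i <- i[1L]
  g <- function(rn, nm) .atom_xyz(structure, chain, rn, nm)
  N <- g(resnum, "N"); CA <- g(resnum, "CA"); C <- g(resnum, "C")
  Cprev <- CAprev <- Nnext <- NULL
  if (i > 1L) {
    Cprev <- g(res$resno[i - 1L], "C")
    CAprev <- g(res$resno[i - 1L], "CA")
  }
  if (i < nrow(res)) Nnext <- g(res$resno[i + 1L], "N")
  tors <- function(a, b, c, d, what) {
    if (is.null(a) || is.null(b) || is.null(c) || is.null(d)) {
      warning(what, " undefined for ", chain, "/", resnum,
              " (terminus or missing backbone atom)", call. = FALSE)
      return(NA_real_)
    }
    dihedral(a, b, c, d)
  }
  list(phi = tors(Cprev, N, CA, C, "phi"),
       psi = tors(N, CA, C, Nnext, "psi"),
       omega = tors(CAprev, Cprev, N, CA, "omega"))
}

#' Side-chain torsions chi1 and chi2
#'
#' chi1 is N-CA-CB-X and chi2 is CA-CB-CG-Y with X/Y the standard atoms for
#' each residue type (for Asn: X = CG, Y = OD1).  The succinimide residue
#' SNN uses the same CB/CG/OD1 labels, so its chi-equivalents are computed
#' from the ring atoms with identical definitions.
#'
#' @inheritParams backbone_dihedrals
#' @return list with numeric `chi1`, `chi2` (degrees, `NA` with a warning
#'   when a required atom is missing).
#' @export
sidechain_dihedrals <- function(structure, chain, resnum) {
  resid <- select_residue(structure, chain, resnum)$name
  g <- function(nm) .atom_xyz(structure, chain, resnum, nm)
  x1_atom <- .chi1_atom[resid]
  x2_atom <- .chi2_atom[resid]
  chi1 <- chi2 <- NA_real_
  if (is.na(x1_atom)) {
    warning("chi1 not defined for residue type ", resid, call. = FALSE)
  } else {
    N <- g("N"); CA <- g("CA"); CB <- g("CB"); X <- g(x1_atom)
    if (is.null(N) || is.null(CA) || is.null(CB) || is.null(X))
      warning("chi1 undefined for ", chain, "/", resnum,
              ": missing atom", call. = FALSE)
    else chi1 <- dihedral(N, CA, CB, X)
  }
  if (!is.na(x2_atom)) {
    CA <- g("CA"); CB <- g("CB")
    CG <- g(x1_atom)  # third chi2 atom is the chi1 terminal atom (CG/CG1/..)
    Y <- g(x2_atom)
    if (is.null(CA) || is.null(CB) || is.null(CG) || is.null(Y))
      warning("chi2 undefined for ", chain, "/", resnum,
              ": missing atom", call. = FALSE)
    else chi2 <- dihedral(CA, CB, CG, Y)
  }
  list(chi1 = chi1, chi2 = chi2)
}

# ---- contacts -------------------------------------------------------------

# atoms excluded as 1-2/1-3 covalent neighbours across the peptide bond:
# C(i)-N(i+1) [1-2]; CA(i)-N(i+1), O(i)-N(i+1), C(i)-CA(i+1) [1-3]
.is_peptide_neighbour <- function(name_a, resno_a, name_b, resno_b) {
  d <- resno_b - resno_a
  if (d == -1L) { # swap so a precedes b
    tmp <- name_a; name_a <- name_b; name_b <- tmp
    d <- 1L
  }
  if (d != 1L) return(FALSE)
  (name_a == "C" && name_b %in% c("N", "CA")) ||
    (name_a %in% c("CA", "O") && name_b == "N")
}

#' Distance contacts of a target atom set
#'
#' Every heavy-atom pair (target atom, non-target atom) with distance at or
#' below `cutoff`, sorted by distance.  Atoms of the same residue and
#' 1-2/1-3 covalent neighbours across the peptide bond are excluded, as are
#' waters and non-protein heteroatoms unless `exclude_solvent = FALSE`.
#'
#' @param structure `snn_structure`.
#' @param target an `snn_residue`, or a list `list(chain=, number=)`, or a
#'   data.frame of atom rows defining the target set.
#' @param cutoff distance cutoff in Angstrom (default 4.0).
#' @param exclude_solvent drop waters/ions and other non-protein residues
#'   from the environment (default TRUE).
#' @param hbond_d distance at or below which an N/O-N/O pair is flagged as a
#'   hydrogen-bond candidate (default 3.5).
#' @return data.frame of contact records: target atom, partner atom,
#'   `distance`, `is_hbond_candidate`.
#' @export
contacts <- function(structure, target, cutoff = 4.0,
                     exclude_solvent = TRUE, hbond_d = 3.5) {
  stopifnot(cutoff > 0)
  if (inherits(target, "snn_residue")) target <- target$atoms
  if (is.list(target) && !is.data.frame(target) &&
      all(c("chain", "number") %in% names(target)))
    target <- select_residue(structure, target$chain, target$number)$atoms
  if (!is.data.frame(target) || nrow(target) == 0L)
    stop("empty target atom set")
  a <- structure$atoms
  tkey <- paste(target$chain, target$resno, target$insert, target$name)
  akey <- paste(a$chain, a$resno, a$insert, a$name)
  env <- a[!(akey %in% tkey) & !.is_hydrogen(a), , drop = FALSE]
  if (exclude_solvent) env <- env[.is_protein(env), , drop = FALSE]
  target <- target[!.is_hydrogen(target), , drop = FALSE]
  if (nrow(target) == 0L) stop("target has no heavy atoms")
  if (nrow(env) == 0L) return(.empty_contacts())
  tm <- as.matrix(target[, c("x", "y", "z")])
  em <- as.matrix(env[, c("x", "y", "z")])
  out <- vector("list", nrow(target))
  for (k in seq_len(nrow(target))) {
    d <- sqrt(colSums((t(em) - tm[k, ])^2))
    hit <- which(d <= cutoff)
    if (!length(hit)) next
    keep <- logical(length(hit))
    for (j in seq_along(hit)) {
      e <- env[hit[j], ]
      same_res <- e$chain == target$chain[k] &&
        e$resno == target$resno[k] && e$insert == target$insert[k]
      cov <- e$chain == target$chain[k] &&
        .is_peptide_neighbour(target$name[k], target$resno[k],
                              e$name, e$resno)
      keep[j] <- !same_res && !cov
    }
    hit <- hit[keep]
    if (!length(hit)) next
    e <- env[hit, , drop = FALSE]
    no <- function(x) x %in% c("N", "O")
    out[[k]] <- data.frame(
      chain_a = target$chain[k], resno_a = target$resno[k],
      resid_a = target$resid[k], name_a = target$name[k],
      chain_b = e$chain, resno_b = e$resno, resid_b = e$resid,
      name_b = e$name, distance = d[hit],
      is_hbond_candidate = no(substr(target$elesy[k], 1, 1)) &
        no(substr(e$elesy, 1, 1)) & d[hit] <= hbond_d,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) return(.empty_contacts())
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_contacts <- function() {
  data.frame(chain_a = character(), resno_a = integer(),
             resid_a = character(), name_a = character(),
             chain_b = character(), resno_b = integer(),
             resid_b = character(), name_b = character(),
             distance = numeric(), is_hbond_candidate = logical(),
             stringsAsFactors = FALSE)
}

# ---- hydrogen bonds -------------------------------------------------------

# place an amide hydrogen on a backbone N: along the negated bisector of the
# N->C(prev) and N->CA bond directions, 1.01 A from N
.infer_amide_h <- function(structure, chain, resno) {
  res <- .chain_residues(structure, chain)
  i <- which(res$resno == resno)
  if (!length(i) || i[1L] == 1L) return(NULL)
  N <- .atom_xyz(structure, chain, resno, "N")
  CA <- .atom_xyz(structure, chain, resno, "CA")
  Cp <- .atom_xyz(structure, chain, res$resno[i[1L] - 1L], "C")
  if (is.null(N) || is.null(CA) || is.null(Cp)) return(NULL)
  u <- (Cp - N) / .dist3(Cp, N) + (CA - N) / .dist3(CA, N)
  N - 1.01 * u / sqrt(sum(u^2))
}

#' Hydrogen bonds between donor and acceptor atoms
#'
#' Acceptance criteria follow common trajectory practice: donor-acceptor
#' distance below `d_max` and, when a hydrogen position is available,
#' donor-H-acceptor angle above `angle_min`.  With
#' `require_angle = FALSE` (crystal mode, hydrogen-free structures) the
#' distance alone decides and the angle is `NA`.  With `infer_h = TRUE`
#' backbone amide hydrogens are placed geometrically on the H-N bisector so
#' the angle criterion can be applied to crystal input.
#'
#' @param structure `snn_structure`.
#' @param d_max donor-acceptor distance criterion in Angstrom (default 3.5).
#' @param angle_min donor-H-acceptor angle criterion in degrees (default
#'   140).
#' @param require_angle apply the angle criterion (needs hydrogens or
#'   `infer_h`).
#' @param infer_h place missing backbone amide hydrogens geometrically.
#' @param donors,acceptors optional data.frames of atom rows restricting the
#'   candidate sets; by default all protein N/O atoms are considered.
#' @return data.frame of H-bond records with donor, hydrogen (or `NA`),
#'   acceptor, `d_DA` and `angle_DHA`.
#' @export
hydrogen_bonds <- function(structure, d_max = 3.5, angle_min = 140,
                           require_angle = FALSE, infer_h = FALSE,
                           donors = NULL, acceptors = NULL) {
  a <- structure$atoms
  prot <- a[.is_protein(a), , drop = FALSE]
  hydro <- prot[.is_hydrogen(prot), , drop = FALSE]
  heavy <- prot[!.is_hydrogen(prot), , drop = FALSE]
  pol <- heavy[substr(heavy$elesy, 1, 1) %in% c("N", "O"), , drop = FALSE]
  if (is.null(donors)) donors <- pol
  if (is.null(acceptors)) acceptors <- pol
  if (require_angle && nrow(hydro) == 0L && !infer_h)
    stop("require_angle = TRUE but the structure has no hydrogens; ",
         "use infer_h = TRUE or require_angle = FALSE")
  recs <- list()
  for (k in seq_len(nrow(donors))) {
    dxyz <- as.numeric(donors[k, c("x", "y", "z")])
    dd <- sqrt(colSums((t(as.matrix(acceptors[, c("x", "y", "z")])) -
                          dxyz)^2))
    hit <- which(dd <= d_max &
                   !(acceptors$chain == donors$chain[k] &
                       acceptors$resno == donors$resno[k] &
                       acceptors$insert == donors$insert[k]))
    for (j in hit) {
      axyz <- as.numeric(acceptors[j, c("x", "y", "z")])
      hxyz <- NULL; hname <- NA_character_
      if (require_angle) {
        # covalently attached hydrogen: any H of the donor residue < 1.3 A
        hres <- hydro[hydro$chain == donors$chain[k] &
                        hydro$resno == donors$resno[k], , drop = FALSE]
        if (nrow(hres)) {
          hd <- sqrt(colSums((t(as.matrix(hres[, c("x", "y", "z")])) -
                                dxyz)^2))
          if (any(hd < 1.3)) {
            # among attached hydrogens take the one best aligned
            att <- which(hd < 1.3)
            angs <- vapply(att, function(m)
              .angle3(dxyz, as.numeric(hres[m, c("x", "y", "z")]), axyz),
              numeric(1))
            best <- att[which.max(angs)]
            hxyz <- as.numeric(hres[best, c("x", "y", "z")])
            hname <- hres$name[best]
          }
        }
        if (is.null(hxyz) && infer_h && donors$name[k] == "N") {
          hxyz <- .infer_amide_h(structure, donors$chain[k],
                                 donors$resno[k])
          hname <- if (!is.null(hxyz)) "H*" else NA_character_
        }
        if (is.null(hxyz)) next
        ang <- .angle3(dxyz, hxyz, axyz)
        if (ang <= angle_min) next
      } else ang <- NA_real_
      recs[[length(recs) + 1L]] <- data.frame(
        donor_chain = donors$chain[k], donor_resno = donors$resno[k],
        donor_resid = donors$resid[k], donor_name = donors$name[k],
        hydrogen = hname,
        acc_chain = acceptors$chain[j], acc_resno = acceptors$resno[j],
        acc_resid = acceptors$resid[j], acc_name = acceptors$name[j],
        d_DA = dd[j], angle_DHA = ang, stringsAsFactors = FALSE)
    }
  }
  if (!length(recs))
    return(data.frame(donor_chain = character(), donor_resno = integer(),
                      donor_resid = character(), donor_name = character(),
                      hydrogen = character(), acc_chain = character(),
                      acc_resno = integer(), acc_resid = character(),
                      acc_name = character(), d_DA = numeric(),
                      angle_DHA = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, recs)
  out[order(out$d_DA), , drop = FALSE]
}

#' Single-pair hydrogen-bond test
#'
#' @param d donor-acceptor distance (Angstrom).
#' @param angle donor-H-acceptor angle (degrees) or `NA` in distance-only
#'   mode.
#' @param d_max,angle_min criteria (defaults 3.5 Angstrom, 140 degrees).
#' @return logical.
#' @export
is_hbond <- function(d, angle = NA, d_max = 3.5, angle_min = 140) {
  d < d_max & (is.na(angle) | angle > angle_min)
}

# ---- turns ----------------------------------------------------------------

#' Detect alpha- and beta-turns from i -> i+4 / i -> i+3 hydrogen bonds
#'
#' An alpha-turn is recorded when the backbone C=O of residue i hydrogen
#' bonds to the backbone NH of residue i+4, a beta-turn for i+3.  Crystal
#' structures lack hydrogens, so by default the donor-acceptor distance
#' alone decides (`require_angle = FALSE`).
#'
#' @param structure `snn_structure`.
#' @param chain chain id.
#' @param range integer vector of author residue numbers to scan (start
#'   positions i are taken from this range).
#' @param d_max distance criterion (default 3.5 Angstrom).
#' @param require_angle,angle_min apply the angle criterion using inferred
#'   amide hydrogen positions.
#' @return data.frame with `kind` ("alpha"/"beta"), `start_resno`,
#'   `start_resid`, `end_resno`, `d_ON` and `angle_DHA`.
#' @export
detect_turns <- function(structure, chain, range, d_max = 3.5,
                         require_angle = FALSE, angle_min = 140) {
  res <- .chain_residues(structure, chain)
  res <- res[res$resno %in% range, , drop = FALSE]
  recs <- list()
  for (k in seq_len(nrow(res))) {
    i <- res$resno[k]
    O <- .atom_xyz(structure, chain, i, "O")
    if (is.null(O)) next
    for (span in c(alpha = 4L, beta = 3L)) {
      j <- i + span
      if (!j %in% res$resno) next
      N <- .atom_xyz(structure, chain, j, "N")
      if (is.null(N)) next
      d <- .dist3(O, N)
      if (d > d_max) next
      ang <- NA_real_
      if (require_angle) {
        H <- .infer_amide_h(structure, chain, j)
        if (is.null(H)) next
        ang <- .angle3(N, H, O)
        if (ang <= angle_min) next
      }
      recs[[length(recs) + 1L]] <- data.frame(
        kind = if (span == 4L) "alpha" else "beta",
        start_resno = i,
        start_resid = res$resid[k],
        end_resno = j, d_ON = d, angle_DHA = ang,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(recs))
    return(data.frame(kind = character(), start_resno = integer(),
                      start_resid = character(), end_resno = integer(),
                      d_ON = numeric(), angle_DHA = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, recs)
}

# ---- superposition --------------------------------------------------------

# least-squares rigid fit (Kabsch, SVD); returns rotation R and translation
# t such that mobile %*% R + t approximates reference
.kabsch <- function(mobile, reference) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  t_vec <- cr - as.numeric(cm %*% R)
  list(rotation = R, translation = t_vec)
}

#' Rigid superposition with iterative outlier rejection
#'
#' Least-squares (Kabsch) fit of paired coordinates, followed by up to
#' `cycles` rejection rounds: after each fit, pairs deviating by more than
#' `reject_factor` times the current RMSD are dropped and the remaining
#' pairs refit.  Matches the "5 cycles, cutoff 2" outlier-rejection scheme
#' of common structure-alignment tools; RMSD never increases across cycles.
#'
#' @param mobile,reference n x 3 matrices of paired coordinates (pairing is
#'   supplied by the caller, e.g. CA atoms matched by residue number via
#'   [pair_ca()]).
#' @param cycles maximum rejection cycles (default 5).
#' @param reject_factor rejection threshold in multiples of the current
#'   RMSD (default 2).
#' @return list with `rotation` (3 x 3, det +1), `translation`, `rmsd` over
#'   retained pairs, `retained_pairs`, `retained` (logical vector),
#'   `cycles_run` and `transformed` (mobile after the fit).
#' @export
superpose <- function(mobile, reference, cycles = 5, reject_factor = 2.0) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  n <- nrow(mobile)
  if (n < 3L) stop("degenerate fit: need at least 3 pairs, got ", n)
  retained <- rep(TRUE, n)
  fit <- NULL; rmsd <- NA_real_; cycles_run <- 0L
  for (cyc in seq_len(cycles + 1L)) {
    fit <- .kabsch(mobile[retained, , drop = FALSE],
                   reference[retained, , drop = FALSE])
    moved <- mobile %*% fit$rotation +
      matrix(fit$translation, n, 3, byrow = TRUE)
    dev <- sqrt(rowSums((moved - reference)^2))
    rmsd <- sqrt(mean(dev[retained]^2))
    if (cyc > cycles) break
    # floor keeps machine-precision fits from rejecting spuriously
    reject <- retained & dev > pmax(reject_factor * rmsd, 1e-8)
    if (!any(reject)) break
    if (sum(retained & !reject) < 3L)
      stop("degenerate fit: outlier rejection left fewer than 3 pairs")
    retained <- retained & !reject
    cycles_run <- cyc
  }
  moved <- mobile %*% fit$rotation +
    matrix(fit$translation, n, 3, byrow = TRUE)
  list(rotation = fit$rotation, translation = fit$translation,
       rmsd = rmsd, retained_pairs = sum(retained), retained = retained,
       cycles_run = cycles_run, transformed = moved)
}

#' Pair CA atoms of two structures by residue number
#'
#' @param mobile,reference `snn_structure` objects.
#' @param chain chain id used in both structures.
#' @return list of two matrices (`mobile`, `reference`) of matched CA
#'   coordinates and the shared residue numbers (`resno`).
#' @export
pair_ca <- function(mobile, reference, chain = "A") {
  am <- mobile$atoms
  ar <- reference$atoms
  cm <- am[am$chain == chain & am$name == "CA" & .is_protein(am), ]
  cr <- ar[ar$chain == chain & ar$name == "CA" & .is_protein(ar), ]
  shared <- intersect(cm$resno, cr$resno)
  if (length(shared) < 3L)
    stop("fewer than 3 shared CA positions in chain ", chain)
  cm <- cm[match(shared, cm$resno), ]
  cr <- cr[match(shared, cr$resno), ]
  list(mobile = as.matrix(cm[, c("x", "y", "z")]),
       reference = as.matrix(cr[, c("x", "y", "z")]),
       resno = shared)
}
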