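# Succinimide-site scanning: classify Asn residues as cyclization-prone
# (near-attack conformation), assign Ramachandran quadrants, and shortlist
# candidate internal-catalyst residues from the contact network.

#' Near-attack conformation criteria
#'
#' Geometry that positions an Asn side-chain carbonyl carbon (CG) for
#' intramolecular attack by the backbone amide nitrogen of the following
#' (n+1) residue: CG(n)-N(n+1) distance below `d_max`, with indicative
#' angular preferences chi1 near +120 deg, chi2 near +90/-90 deg and psi
#' near -120 deg.  The distance criterion is mandatory; which angular
#' criteria gate the verdict is configurable via `required` because their
#' relative necessity is not settled - by default all angles are evaluated
#' and reported as evidence but only the distance decides.
#'
#' @param d_max CG(n)-N(n+1) distance criterion, Angstrom (default 3.5).
#' @param chi1_center,chi2_centers,psi_center angular centers in degrees
#'   (defaults +120; +90 and -90; -120).
#' @param tolerance angular tolerance in degrees, circular (default 40).
#' @param required character subset of `c("chi1","chi2","psi")` whose
#'   criteria must also pass (default none: distance-only verdict).
#' @return object of class `near_attack_criteria`.
#' @export
near_attack_criteria <- function(d_max = 3.5, chi1_center = 120,
                                 chi2_centers = c(90, -90),
                                 psi_center = -120, tolerance = 40,
                                 required = character()) {
  stopifnot(d_max > 0, tolerance > 0, tolerance < 90)
  if (length(required))
    required <- match.arg(required, c("chi1", "chi2", "psi"),
                          several.ok = TRUE)
  structure(list(d_max = d_max, chi1_center = chi1_center,
                 chi2_centers = chi2_centers, psi_center = psi_center,
                 tolerance = tolerance, required = required),
            class = "near_attack_criteria")
}

# circular difference in (-180, 180]
.circ_diff <- function(a, b) .wrap180(a - b)

#' Ramachandran quadrant of a (phi, psi) pair
#'
#' Sign-based partition of the torsion torus; boundaries (0 deg) are
#' assigned to the positive side, so every pair maps to exactly one
#' quadrant.  "Top" is positive psi, "right" is positive phi.
#'
#' @param phi,psi backbone torsions in degrees.
#' @return one of `"top-left"`, `"top-right"`, `"bottom-left"`,
#'   `"bottom-right"`.
#' @export
classify_quadrant <- function(phi, psi) {
  stopifnot(is.finite(phi), is.finite(psi))
  vert <- ifelse(psi >= 0, "top", "bottom")
  horiz <- ifelse(phi >= 0, "right", "left")
  paste(vert, horiz, sep = "-")
}

#' Assess near-attack geometry of one site
#'
#' The distance criterion is mandatory.  Angular criteria pass when within
#' `criteria$tolerance` of a center (circular difference); an undefined
#' angle is reported as not evaluated.  The overall verdict is distance AND
#' all *required* angular criteria that could be evaluated.
#'
#' @param d_CG_N CG(n) to backbone N(n+1) distance, Angstrom.
#' @param chi1,chi2,psi site torsions in degrees (may be `NA`).
#' @param criteria a [near_attack_criteria()] object.
#' @return list with logical `near_attack` and an `evidence` data.frame
#'   (criterion, value, pass: TRUE/FALSE/NA for not-evaluated).
#' @export
near_attack_assess <- function(d_CG_N, chi1 = NA, chi2 = NA, psi = NA,
                               criteria = near_attack_criteria()) {
  stopifnot(inherits(criteria, "near_attack_criteria"))
  ang_pass <- function(x, centers) {
    if (is.na(x)) return(NA)
    any(abs(.circ_diff(x, centers)) <= criteria$tolerance)
  }
  dist_ok <- if (is.na(d_CG_N)) NA else d_CG_N < criteria$d_max
  ev <- data.frame(
    criterion = c("distance", "chi1", "chi2", "psi"),
    value = c(d_CG_N, chi1, chi2, psi),
    pass = c(dist_ok,
             ang_pass(chi1, criteria$chi1_center),
             ang_pass(chi2, criteria$chi2_centers),
             ang_pass(psi, criteria$psi_center)),
    stringsAsFactors = FALSE)
  verdict <- isTRUE(dist_ok)
  for (crit in criteria$required) {
    p <- ev$pass[ev$criterion == crit]
    if (!is.na(p)) verdict <- verdict && p
  }
  list(near_attack = verdict, evidence = ev)
}

#' Scan all Asn (and SNN) residues of a structure for near-attack geometry
#'
#' For each Asn/SNN residue the CG(n) to backbone N(n+1) distance, backbone
#' and side-chain torsions, the psi of the n+1 residue, the Ramachandran
#' quadrant and the near-attack verdict are reported.  A site at the chain
#' terminus is reported with an undefined distance.
#'
#' @param structure `snn_structure`.
#' @param criteria a [near_attack_criteria()] object.
#' @param residue_types residue names treated as sites (default Asn and
#'   SNN).
#' @return data.frame (one row per site), sorted by distance.
#' @export
scan_asn_sites <- function(structure, criteria = near_attack_criteria(),
                           residue_types = c("ASN", "SNN")) {
  a <- structure$atoms
  sites <- unique(a[a$resid %in% residue_types,
                    c("chain", "resno", "insert", "resid")])
  if (nrow(sites) == 0L)
    return(data.frame(chain = character(), resno = integer(),
                      resid = character(), d_CG_N = numeric(),
                      phi = numeric(), psi = numeric(), chi1 = numeric(),
                      chi2 = numeric(), psi_n1 = numeric(),
                      quadrant = character(), near_attack = logical(),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(sites)), function(k) {
    ch <- sites$chain[k]; rn <- sites$resno[k]
    res <- .chain_residues(structure, ch)
    i <- which(res$resno == rn)[1L]
    CG <- .atom_xyz(structure, ch, rn, "CG")
    d <- NA_real_; psi_n1 <- NA_real_
    if (i < nrow(res)) {
      Nn <- .atom_xyz(structure, ch, res$resno[i + 1L], "N")
      if (!is.null(CG) && !is.null(Nn)) d <- .dist3(CG, Nn)
      psi_n1 <- suppressWarnings(
        backbone_dihedrals(structure, ch, res$resno[i + 1L])$psi)
    }
    bb <- suppressWarnings(backbone_dihedrals(structure, ch, rn))
    sc <- suppressWarnings(sidechain_dihedrals(structure, ch, rn))
    verdict <- near_attack_assess(d, sc$chi1, sc$chi2, bb$psi,
                                  criteria)$near_attack
    quad <- if (is.na(bb$phi) || is.na(bb$psi)) NA_character_
            else classify_quadrant(bb$phi, bb$psi)
    data.frame(chain = ch, resno = rn, resid = sites$resid[k],
               d_CG_N = d, phi = bb$phi, psi = bb$psi,
               chi1 = sc$chi1, chi2 = sc$chi2, psi_n1 = psi_n1,
               quadrant = quad, near_attack = verdict,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$d_CG_N, out$resno, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Shortlist candidate internal-catalyst residues around a site
#'
#' Residues owning at least one atom within `cutoff` of any side-chain/ring
#' atom of the site residue, annotated with a structural role hint:
#' `direct-base` when the residue carries a carboxylate oxygen within
#' hydrogen-bond distance of the backbone N of the n+1 residue; `relay`
#' when a hydroxyl/amine atom of the residue is hydrogen-bond-chained to
#' another candidate; `electrostatic` for other charged side chains within
#' the cutoff; `vdw` otherwise.  The hints are structural heuristics, not
#' mechanistic assignments.
#'
#' @param structure `snn_structure`.
#' @param chain,resnum site residue (an Asn or SNN).
#' @param cutoff contact cutoff in Angstrom (default 4.0).
#' @param hbond_d chained hydrogen-bond distance for direct-base/relay
#'   assignment (default 3.5).
#' @return data.frame: residue, `min_distance`, `n_contacts`, `role_hint`.
#' @export
candidate_catalysts <- function(structure, chain, resnum, cutoff = 4.0,
                                hbond_d = 3.5) {
  site <- select_residue(structure, chain, resnum)
  side <- site$atoms[!site$atoms$name %in% c("N", "CA", "C", "O"), ,
                     drop = FALSE]
  if (nrow(side) == 0L) side <- site$atoms
  con <- contacts(structure, side, cutoff = cutoff, hbond_d = hbond_d)
  if (nrow(con) == 0L)
    return(data.frame(chain = character(), resno = integer(),
                      resid = character(), min_distance = numeric(),
                      n_contacts = integer(), role_hint = character(),
                      stringsAsFactors = FALSE))
  key <- paste(con$chain_b, con$resno_b)
  groups <- split(con, key)
  a <- structure$atoms
  # backbone N of the n+1 residue (attack nucleophile)
  res <- .chain_residues(structure, chain)
  i <- which(res$resno == resnum)[1L]
  Nn1 <- if (i < nrow(res))
    .atom_xyz(structure, chain, res$resno[i + 1L], "N") else NULL
  carboxy_o <- c("OD1", "OD2", "OE1", "OE2")
  relay_atoms <- c("OG", "OG1", "OH", "NZ", "NE2", "ND1", "NE")
  charged <- c("NZ", "NH1", "NH2", "NE", "ND1", "NE2", "OD1", "OD2",
               "OE1", "OE2", "CZ", "CG", "CD")
  cand <- do.call(rbind, lapply(groups, function(g) {
    data.frame(chain = g$chain_b[1], resno = g$resno_b[1],
               resid = g$resid_b[1], min_distance = min(g$distance),
               n_contacts = nrow(g), stringsAsFactors = FALSE)
  }))
  hint <- character(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    ra <- a[a$chain == cand$chain[k] & a$resno == cand$resno[k], ,
            drop = FALSE]
    co <- ra[ra$name %in% carboxy_o, , drop = FALSE]
    is_base <- FALSE
    if (!is.null(Nn1) && nrow(co)) {
      dn <- sqrt(colSums((t(as.matrix(co[, c("x", "y", "z")])) - Nn1)^2))
      is_base <- any(dn <= hbond_d)
    }
    if (is_base) { hint[k] <- "direct-base"; next }
    hint[k] <- "pending"
  }
  # relay: hydroxyl/amine atom chained (<= hbond_d) to an atom of another
  # candidate residue
  for (k in which(hint == "pending")) {
    ra <- a[a$chain == cand$chain[k] & a$resno == cand$resno[k] &
              a$name %in% relay_atoms, , drop = FALSE]
    linked <- FALSE
    if (nrow(ra)) {
      for (m in seq_len(nrow(cand))) {
        if (m == k) next
        rb <- a[a$chain == cand$chain[m] & a$resno == cand$resno[m], ,
                drop = FALSE]
        rb <- rb[!.is_hydrogen(rb), , drop = FALSE]
        if (!nrow(rb)) next
        dmat <- as.matrix(dist(rbind(as.matrix(ra[, c("x", "y", "z")]),
                                     as.matrix(rb[, c("x", "y", "z")]))))
        cross <- dmat[seq_len(nrow(ra)), nrow(ra) + seq_len(nrow(rb)),
                      drop = FALSE]
        if (any(cross <= hbond_d)) { linked <- TRUE; break }
      }
    }
    if (linked) hint[k] <- "relay"
  }
  for (k in which(hint == "pending")) {
    ra <- a[a$chain == cand$chain[k] & a$resno == cand$resno[k], ,
            drop = FALSE]
    has_charged <- any(ra$name %in% charged &
                         ra$resid %in% c("LYS", "ARG", "HIS", "ASP", "GLU"))
    hint[k] <- if (has_charged) "electrostatic" else "vdw"
  }
  cand$role_hint <- hint
  cand <- cand[order(cand$min_distance), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Proton-affinity label from the psi of the n+1 residue
#'
#' The acidity of the backbone amide hydrogen of the n+1 residue is mainly
#' dictated by its psi torsion.  This is a configurable range lookup, not
#' hard-coded science: the default table labels the wrapped interval
#' [-50, -10] deg as `"moderately-low"` proton affinity; psi values outside
#' every configured range return `"unclassified"`.
#'
#' @param psi_n1 psi of the n+1 residue, degrees.
#' @param ranges named list of `c(lo, hi)` degree intervals (wrapped
#'   circularly when `lo > hi`).
#' @return character label.
#' @export
n1_acidity_label <- function(psi_n1,
                             ranges = list("moderately-low" = c(-50, -10))) {
  stopifnot(is.finite(psi_n1))
  psi_n1 <- .wrap180(psi_n1)
  for (lab in names(ranges)) {
    r <- ranges[[lab]]
    inside <- if (r[1] <= r[2]) psi_n1 >= r[1] & psi_n1 <= r[2]
              else psi_n1 >= r[1] | psi_n1 <= r[2]
    if (inside) return(lab)
  }
  "unclassified"
}

#' Batch survey: scan a directory of structure files for Asn/SNN sites
#'
#' Runs [scan_asn_sites()] over every PDB/mmCIF file in a directory and
#' returns one row per site, with the source file recorded.  Suitable for
#' local surveys of succinimide-containing structures.
#'
#' @param dir directory containing `.pdb` / `.cif` files.
#' @param criteria a [near_attack_criteria()] object.
#' @param out optional path; when given, the table is also written as TSV.
#' @return data.frame of site reports with a `file` column.
#' @export
scan_structure_dir <- function(dir, criteria = near_attack_criteria(),
                               out = NULL) {
  files <- list.files(dir, pattern = "\\.(pdb|ent|cif|mmcif)$",
                      full.names = TRUE, ignore.case = TRUE)
  if (!length(files)) stop("no structure files found under ", dir)
  rows <- lapply(files, function(f) {
    s <- read_structure(f)
    rep <- scan_asn_sites(s, criteria)
    if (nrow(rep)) cbind(file = basename(f), rep, stringsAsFactors = FALSE)
    else NULL
  })
  res <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (!is.null(out) && !is.null(res))
    utils::write.table(res, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  res
}
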