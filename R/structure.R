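# Hierarchical coordinate model: a structure is an ordered table of atoms
# carrying (chain, residue number, insertion code, residue name, atom name,
# element, xyz, occupancy, B).  Nonstandard residues such as SNN are kept in
# the chain at their deposited author number, never stripped as heteroatoms.

#' Construct a structure object from an atom table
#'
#' @param atoms data.frame with columns `serial`, `name` (atom label, e.g.
#'   `CA`, `OD1`), `resid` (3-letter residue name), `chain`, `resno`
#'   (author residue number), `insert` (insertion code, `""` if none),
#'   `x`, `y`, `z` (Angstrom), `occupancy`, `b`, `elesy` (element symbol),
#'   `het` (logical, HETATM record).
#' @param id identifier string.
#' @param source_format `"pdb"`, `"mmcif"` or `"built"`.
#' @return An object of class `snn_structure`.
#' @export
new_structure <- function(atoms, id = "struct", source_format = "built") {
  required <- c("serial", "name", "resid", "chain", "resno", "insert",
                "x", "y", "z", "occupancy", "b", "elesy", "het")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L) stop("structure must contain at least one atom")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("atom coordinates must be finite")
  if (any(!nzchar(atoms$name))) stop("atom names must be nonempty")
  # order residues within each chain by (number, insertion code); atom order
  # within a residue is preserved as given
  ord <- order(atoms$chain, atoms$resno, atoms$insert)
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms, source_format = source_format),
            class = "snn_structure")
}

#' @export
print.snn_structure <- function(x, ...) {
  a <- x$atoms
  cat("<snn_structure>", x$id, " (", x$source_format, ")\n", sep = "")
  cat("  atoms: ", nrow(a), ",  chains: ",
      paste(unique(a$chain), collapse = " "), "\n", sep = "")
  nres <- nrow(unique(a[, c("chain", "resno", "insert")]))
  cat("  residues: ", nres, "\n", sep = "")
  invisible(x)
}

# Resolve alternate locations: keep the highest-occupancy conformer for each
# (chain, resno, insert, atom name); ties broken by altloc letter order.
.resolve_altloc <- function(atoms, alt) {
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name, sep = "\r")
  occ <- atoms$occupancy
  occ[is.na(occ)] <- 1
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    best <- idx[order(-occ[idx], alt[idx])][1L]
    keep[setdiff(idx, best)] <- FALSE
  }
  atoms[keep, , drop = FALSE]
}

#' Read a protein structure from PDB or mmCIF
#'
#' All ATOM and HETATM records are retained, so modified residues such as
#' succinimide (`SNN`) stay in the chain at their deposited author number.
#' Alternate locations are resolved to the highest-occupancy conformer
#' (ties by altloc letter).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return `snn_structure`.
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' s <- build_peptide("AA", phi = c(NA, -60), psi = c(-45, NA))
#' write_structure(s, f)
#' read_structure(f)
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     pdb = "pdb", ent = "pdb",
                     cif = "mmcif", mmcif = "mmcif",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format explicitly"))
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    else bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  atoms <- data.frame(
    serial = a$eleno, name = a$elety, resid = a$resid, chain = a$chain,
    resno = a$resno,
    insert = ifelse(is.na(a$insert) | a$insert == "NA", "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o), b = ifelse(is.na(a$b), 0, a$b),
    elesy = ifelse(is.na(a$elesy) | !nzchar(a$elesy),
                   .guess_element(a$elety), a$elesy),
    het = a$type == "HETATM", stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- " "
  atoms <- .resolve_altloc(atoms, a$alt)
  new_structure(atoms, id = sub("\\.[^.]*$", "", basename(path)),
                source_format = format)
}

.guess_element <- function(name) {
  toupper(substr(gsub("[0-9' ]", "", name), 1, 1))
}

#' Write a structure to PDB or mmCIF
#'
#' `read_structure(write_structure(s))` preserves chain/residue/atom identity
#' and coordinates to 3 decimal places (the precision of both formats as
#' written).
#'
#' @param structure `snn_structure`.
#' @param path output file path.
#' @param format `"pdb"` or `"mmcif"`.
#' @export
write_structure <- function(structure, path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  stopifnot(inherits(structure, "snn_structure"))
  a <- structure$atoms
  if (nrow(a) == 0L) stop("refusing to write an empty structure")
  if (format == "pdb") {
    ok <- tryCatch({
      bio3d::write.pdb(
        pdb = NULL, file = path,
        xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
        type = ifelse(a$het, "HETATM", "ATOM"),
        resno = a$resno, resid = a$resid, eleno = a$serial, elety = a$name,
        chain = ifelse(a$chain == " ", "", a$chain), insert = a$insert,
        o = a$occupancy, b = a$b, elesy = a$elesy)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      stop("could not write '", path, "': ", conditionMessage(ok))
  } else {
    .write_mmcif(a, path, structure$id)
  }
  invisible(path)
}

# Minimal mmCIF atom_site writer (loop_ records only).
.write_mmcif <- function(a, path, id) {
  hdr <- c(
    paste0("data_", gsub("[^A-Za-z0-9]", "_", id)),
    "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num")
  rows <- sprintf(
    "%-6s %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
    ifelse(a$het, "HETATM", "ATOM"), a$serial, a$elesy, a$name, a$resid,
    ifelse(a$chain == " ", "A", a$chain), a$resno,
    ifelse(nzchar(a$insert), a$insert, "?"),
    a$x, a$y, a$z, a$occupancy, a$b, a$resno, a$resid,
    ifelse(a$chain == " ", "A", a$chain), a$name)
  ok <- tryCatch({ writeLines(c(hdr, rows, "#"), path); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) stop("could not write '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

#' Select one residue from a structure
#'
#' @param structure `snn_structure`.
#' @param chain chain identifier.
#' @param number author residue number.
#' @param insert insertion code (default `""`); if the residue number is
#'   ambiguous because of insertion codes, the ambiguity is reported.
#' @return An object of class `snn_residue`: list with `chain`, `number`,
#'   `insert`, `name` and the `atoms` table.
#' @export
select_residue <- function(structure, chain, number, insert = "") {
  stopifnot(inherits(structure, "snn_structure"))
  a <- structure$atoms
  in_chain <- a$chain == chain
  if (!any(in_chain))
    stop("no chain '", chain, "'; available: ",
         paste(unique(a$chain), collapse = " "))
  hit <- in_chain & a$resno == number
  if (!any(hit)) {
    rng <- range(a$resno[in_chain])
    stop("no residue ", number, " in chain ", chain,
         " (available range ", rng[1], "-", rng[2], ")")
  }
  ins <- unique(a$insert[hit])
  if (length(ins) > 1L) {
    if (!insert %in% ins)
      stop("residue ", number, " in chain ", chain,
           " is ambiguous with insertion codes: ",
           paste(sQuote(ins), collapse = " "), "; pass insert=")
    hit <- hit & a$insert == insert
  }
  atoms <- a[hit, , drop = FALSE]
  structure(list(chain = chain, number = number,
                 insert = unique(atoms$insert)[1],
                 name = atoms$resid[1], atoms = atoms),
            class = "snn_residue")
}

#' @export
print.snn_residue <- function(x, ...) {
  cat("<snn_residue> ", x$name, x$number, x$insert, " chain ", x$chain,
      " (", nrow(x$atoms), " atoms: ",
      paste(x$atoms$name, collapse = " "), ")\n", sep = "")
  invisible(x)
}

# ---- internal selection helpers ------------------------------------------

# ordered table of residues in one chain: chain, resno, insert, resid
.chain_residues <- function(structure, chain) {
  a <- structure$atoms[structure$atoms$chain == chain, , drop = FALSE]
  if (nrow(a) == 0L) stop("no chain '", chain, "'")
  unique(a[, c("chain", "resno", "insert", "resid")])
}

# coordinates of a named atom in a residue, or NULL if absent
.atom_xyz <- function(structure, chain, resno, name, insert = NULL) {
  a <- structure$atoms
  hit <- a$chain == chain & a$resno == resno & a$name == name
  if (!is.null(insert)) hit <- hit & a$insert == insert
  i <- which(hit)
  if (!length(i)) return(NULL)
  as.numeric(a[i[1L], c("x", "y", "z")])
}

.is_hydrogen <- function(atoms) {
  atoms$elesy == "H" | atoms$elesy == "D"
}

.is_water <- function(atoms) atoms$resid %in% .water_resids

.is_protein <- function(atoms) atoms$resid %in% .protein_resids
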