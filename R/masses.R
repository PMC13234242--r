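# Monoisotopic mass arithmetic behind MS-based quantification of
# succinimide (M-17), intact-Asn (M) and hydrolyzed (M+1) populations:
# peptide/protein neutral masses, modification shifts, tryptic digestion,
# charge-state m/z and b/y fragment ions.

#' Registry of modification mass shifts
#'
#' Monoisotopic deltas (Da) of the modifications used in succinimide
#' work-ups: ammonia loss at Asn (succinimide formation, -17.0265),
#' deamidation at Asn/Gln (+0.9840), oxidation at Met (+15.9949) and
#' N-terminal acetylation (+42.0106).
#'
#' @format data.frame with `name`, `delta_mass` (Da) and `applies_to`.
#' @export
modification_shifts <- data.frame(
  name = c("snn", "deamidation", "oxidation", "acetyl"),
  delta_mass = c(-17.026549, 0.984016, 15.994915, 42.010565),
  applies_to = c("N", "N,Q", "M", "N-term"),
  stringsAsFactors = FALSE
)

.mod_delta <- function(mod) {
  if (is.numeric(mod)) return(mod)
  i <- match(mod, modification_shifts$name)
  if (is.na(i)) stop("unknown modification '", mod, "'; known: ",
                     paste(modification_shifts$name, collapse = ", "))
  modification_shifts$delta_mass[i]
}

.check_sequence <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(aa), names(aa_residue_mass))
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  aa
}

# normalize a modification spec into data.frame(position, delta);
# accepted forms: list(list(pos, name_or_delta), ...), named numeric vector,
# or strings "snn@7"
.parse_mods <- function(modifications, n) {
  if (is.null(modifications) || length(modifications) == 0L)
    return(data.frame(position = integer(), delta = numeric()))
  if (is.character(modifications)) {
    parts <- strsplit(modifications, "@", fixed = TRUE)
    modifications <- lapply(parts, function(p) {
      if (length(p) != 2L) stop("modification spec must look like 'snn@7'")
      list(position = as.integer(p[2]), mod = p[1])
    })
  }
  if (is.list(modifications) && length(modifications) == 2L &&
      !is.list(modifications[[1]]) &&
      all(c("position", "mod") %in% names(modifications)))
    modifications <- list(modifications)
  rows <- lapply(modifications, function(m) {
    pos <- m$position
    if (is.null(pos)) pos <- m[[1]]
    mod <- m$mod
    if (is.null(mod)) mod <- m[[2]]
    data.frame(position = as.integer(pos), delta = .mod_delta(mod))
  })
  out <- do.call(rbind, rows)
  if (any(out$position < 0L | out$position > n))
    stop("modification position outside the sequence (0 = N-terminus)")
  out
}

#' Neutral monoisotopic mass of a peptide
#'
#' Sum of residue monoisotopic masses plus one water, plus any modification
#' deltas.  Modifications are given as `"name@position"` strings (position
#' 0 denotes the N-terminus) or a list of `list(position=, mod=)`, where
#' `mod` is a registry name from [modification_shifts] or a numeric delta.
#'
#' @param sequence one-letter amino-acid string.
#' @param modifications see above.
#' @return neutral monoisotopic mass in Da.
#' @examples
#' peptide_neutral_mass("G")                       # 75.03203
#' peptide_neutral_mass("VYVDKENVLFK", "snn@7")    # ammonia-loss at Asn
#' @export
peptide_neutral_mass <- function(sequence, modifications = NULL) {
  aa <- .check_sequence(sequence)
  mods <- .parse_mods(modifications, length(aa))
  sum(aa_residue_mass[aa]) + mass_water + sum(mods$delta)
}

#' Charge-state m/z
#'
#' `(neutral + z * 1.007276) / z` for protonated positive ions.
#'
#' @param neutral neutral monoisotopic mass, Da.
#' @param z positive integer charge.
#' @return m/z.
#' @export
mz <- function(neutral, z) {
  if (any(z < 1) || any(z != round(z))) stop("charge z must be a positive integer")
  (neutral + z * mass_proton) / z
}

#' b- and y-series fragment ions
#'
#' b_i covers residues 1..i plus a proton; y_j covers the last j residues
#' plus water and a proton.  Modification deltas are counted when their
#' position lies in the fragment (position 0, the N-terminus, belongs to
#' every b ion).  For every index, (b_i + y_(n-i)) equals the neutral mass
#' plus two protons.
#'
#' @inheritParams peptide_neutral_mass
#' @param series `"b"`, `"y"` or both.
#' @param charge fragment charge (default 1).
#' @return data.frame with `label`, `series`, `index`, `mz`.
#' @export
fragment_ions <- function(sequence, modifications = NULL,
                          series = c("b", "y"), charge = 1) {
  series <- match.arg(series, c("b", "y"), several.ok = TRUE)
  aa <- .check_sequence(sequence)
  n <- length(aa)
  mods <- .parse_mods(modifications, n)
  res <- as.numeric(aa_residue_mass[aa])
  rows <- list()
  for (s in series) {
    for (i in seq_len(n - 1L)) {
      if (s == "b") {
        neutral <- sum(res[seq_len(i)]) +
          sum(mods$delta[mods$position <= i])
        m <- (neutral + charge * mass_proton) / charge
      } else {
        first <- n - i + 1L
        neutral <- sum(res[first:n]) + mass_water +
          sum(mods$delta[mods$position >= first & mods$position > 0L])
        m <- (neutral + charge * mass_proton) / charge
      }
      rows[[length(rows) + 1L]] <- data.frame(
        label = paste0(s, i), series = s, index = i, mz = m,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K/R except before proline; enumerates peptides
#' with at most `max_missed` internal cleavage sites.  With
#' `semi_specific = TRUE`, peptides with one non-enzymatic terminus
#' (every proper prefix/suffix of each fully tryptic peptide) are added.
#' Zero-missed-cleavage fully tryptic peptides tile the input exactly once.
#'
#' @param sequence protein sequence (one-letter codes).
#' @param max_missed maximum missed cleavages (default 2).
#' @param semi_specific also emit semi-tryptic peptides (default FALSE).
#' @param min_length minimum peptide length to report (default 1).
#' @return data.frame with `sequence`, `start`, `end`, `missed`,
#'   `nterm_enzymatic`, `cterm_enzymatic`.
#' @export
digest <- function(sequence, max_missed = 2, semi_specific = FALSE,
                   min_length = 1) {
  aa <- .check_sequence(sequence)
  n <- length(aa)
  stopifnot(max_missed >= 0)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | aa[pmin(cut_after + 1L, n)] != "P"]
  bounds <- unique(c(0L, cut_after, n))
  rows <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    for (j in (i + 1L):length(bounds)) {
      missed <- j - i - 1L
      if (missed > max_missed) break
      start <- bounds[i] + 1L
      end <- bounds[j]
      if (end - start + 1L < min_length) next
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = paste(aa[start:end], collapse = ""),
        start = start, end = end, missed = missed,
        nterm_enzymatic = TRUE, cterm_enzymatic = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  full <- do.call(rbind, rows)
  if (semi_specific && !is.null(full)) {
    semi <- list()
    for (k in seq_len(nrow(full))) {
      s <- full$start[k]; e <- full$end[k]
      if (e > s) {
        for (e2 in s:(e - 1L)) {         # ragged C-terminus
          if (e2 - s + 1L < min_length) next
          semi[[length(semi) + 1L]] <- data.frame(
            sequence = paste(aa[s:e2], collapse = ""), start = s, end = e2,
            missed = if (e2 > s)
              sum(aa[s:(e2 - 1L)] %in% c("K", "R") &
                    aa[(s + 1L):e2] != "P") else 0L,
            nterm_enzymatic = TRUE, cterm_enzymatic = FALSE,
            stringsAsFactors = FALSE)
        }
        for (s2 in (s + 1L):e) {         # ragged N-terminus
          if (e - s2 + 1L < min_length) next
          semi[[length(semi) + 1L]] <- data.frame(
            sequence = paste(aa[s2:e], collapse = ""), start = s2, end = e,
            missed = if (e > s2)
              sum(aa[s2:(e - 1L)] %in% c("K", "R") &
                    aa[(s2 + 1L):e] != "P") else 0L,
            nterm_enzymatic = FALSE, cterm_enzymatic = TRUE,
            stringsAsFactors = FALSE)
        }
      }
    }
    full <- rbind(full, do.call(rbind, semi))
    full <- full[!duplicated(full[, c("start", "end")]), , drop = FALSE]
  }
  full <- full[order(full$start, full$end), , drop = FALSE]
  rownames(full) <- NULL
  full
}

#' Neutral monoisotopic mass of a full protein chain
#'
#' Mass of the (optionally point-mutated) translated chain, including the
#' initiator methionine unless `met_excision = TRUE`.  Mutations use the
#' conventional `"D110V"` notation (or underscore-joined multi-mutation
#' strings such as `"D110V_K151L"`); the stated wild-type residue is
#' checked against the sequence.
#'
#' @param sequence full protein sequence (one-letter codes).
#' @param mutations character vector of point mutations (optional).
#' @param modifications as in [peptide_neutral_mass()].
#' @param met_excision drop an N-terminal Met before computing the mass.
#' @return neutral monoisotopic mass in Da.
#' @export
protein_neutral_mass <- function(sequence, mutations = NULL,
                                 modifications = NULL,
                                 met_excision = FALSE) {
  seq2 <- if (length(mutations)) mutate_sequence(sequence, mutations)
          else sequence
  if (met_excision) {
    if (substr(seq2, 1, 1) != "M")
      stop("met_excision = TRUE but the chain does not start with Met")
    seq2 <- substr(seq2, 2, nchar(seq2))
  }
  peptide_neutral_mass(seq2, modifications)
}

#' Classify an observed neutral mass into SNN / intact / hydrolyzed
#'
#' Deconvoluted neutral masses are assigned to the nearest of the expected
#' intact mass M, the succinimide form M - 17.02655 (ammonia loss) and the
#' hydrolyzed form M + 0.98402 (deamidation), within `tolerance`;
#' otherwise `"unassigned"`.
#'
#' @param observed observed neutral mass, Da.
#' @param expected_intact expected mass of the intact-Asn form, Da.
#' @param tolerance assignment window, Da (default 0.05).
#' @return one of `"snn"`, `"intact"`, `"hydrolyzed"`, `"unassigned"`.
#' @export
classify_population <- function(observed, expected_intact,
                                tolerance = 0.05) {
  stopifnot(tolerance > 0)
  centers <- c(snn = expected_intact - 17.026549,
               intact = expected_intact,
               hydrolyzed = expected_intact + 0.984016)
  dev <- abs(observed - centers)
  i <- which.min(dev)
  if (dev[i] <= tolerance) names(centers)[i] else "unassigned"
}

#' Filter a PSM table by the counting rule used for relative quantification
#'
#' Keeps peptide-spectrum-match groups with at least `min_psms` matches and
#' at most `max_missed` missed cleavages; relative abundances of peptide
#' forms are then ratios of retained PSM counts.
#'
#' @param psms data.frame with at least `peptide` and `missed` columns; one
#'   row per PSM.
#' @param min_psms minimum PSMs per peptide form (default 2).
#' @param max_missed maximum missed cleavages (default 2).
#' @return data.frame with `peptide`, `n_psms` and `fraction` (of retained
#'   PSMs).
#' @export
count_psms <- function(psms, min_psms = 2, max_missed = 2) {
  stopifnot(all(c("peptide", "missed") %in% names(psms)))
  psms <- psms[psms$missed <= max_missed, , drop = FALSE]
  tab <- table(psms$peptide)
  tab <- tab[tab >= min_psms]
  if (!length(tab))
    return(data.frame(peptide = character(), n_psms = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  data.frame(peptide = names(tab), n_psms = as.integer(tab),
             fraction = as.numeric(tab) / sum(tab),
             stringsAsFactors = FALSE)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  fa <- bio3d::read.fasta(path)
  seqs <- apply(fa$ali, 1, function(r) paste(r[r != "-"], collapse = ""))
  names(seqs) <- fa$id
  toupper(seqs)
}
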