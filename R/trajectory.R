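# Frame-wise geometric statistics from simulation trajectories: distance
# series and their normalized distributions, hydrogen-bond occupancies and
# state-point frame extraction.

#' Construct a trajectory object
#'
#' @param topology `snn_structure` defining the atoms.
#' @param coords numeric array `[frame, atom, xyz]` (Angstrom).
#' @param times frame times in ps (strictly increasing); default
#'   `0, timestep, 2*timestep, ...`.
#' @param timestep ps between frames when `times` is not given (default 1).
#' @return object of class `snn_trajectory`.
#' @export
new_trajectory <- function(topology, coords, times = NULL, timestep = 1) {
  stopifnot(inherits(topology, "snn_structure"))
  coords <- if (length(dim(coords)) == 3L) coords
            else array(coords, dim = c(1L, dim(coords)))
  natoms <- nrow(topology$atoms)
  if (dim(coords)[2] != natoms || dim(coords)[3] != 3L)
    stop("coords must be [frames x ", natoms, " x 3]")
  if (is.null(times)) times <- (seq_len(dim(coords)[1]) - 1L) * timestep
  if (length(times) != dim(coords)[1] ||
      is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing, one per frame")
  structure(list(topology = topology, coords = coords, times = times),
            class = "snn_trajectory")
}

#' @export
print.snn_trajectory <- function(x, ...) {
  cat("<snn_trajectory> ", dim(x$coords)[1], " frames x ",
      dim(x$coords)[2], " atoms, t = ", x$times[1], "..",
      x$times[length(x$times)], " ps\n", sep = "")
  invisible(x)
}

# resolve an atom selector to a row index of the topology; selector is an
# integer index or list(chain=, resno=, name=)
.atom_index <- function(topology, sel) {
  if (is.numeric(sel)) {
    i <- as.integer(sel)
    if (i < 1L || i > nrow(topology$atoms)) stop("atom index out of range")
    return(i)
  }
  a <- topology$atoms
  hit <- which(a$chain == sel$chain & a$resno == sel$resno &
                 a$name == sel$name)
  if (!length(hit))
    stop("no atom ", sel$chain, "/", sel$resno, "/", sel$name,
         " in topology")
  hit[1L]
}

#' Interatomic distance per frame
#'
#' @param traj `snn_trajectory`.
#' @param atom_a,atom_b atom selectors: integer index into the topology or
#'   `list(chain=, resno=, name=)`.
#' @return numeric vector of distances (Angstrom), one per frame, with the
#'   frame times as the `"times"` attribute.
#' @export
distance_series <- function(traj, atom_a, atom_b) {
  stopifnot(inherits(traj, "snn_trajectory"))
  ia <- .atom_index(traj$topology, atom_a)
  ib <- .atom_index(traj$topology, atom_b)
  d <- sqrt(rowSums((traj$coords[, ia, , drop = FALSE] -
                       traj$coords[, ib, , drop = FALSE])^2, dims = 1))
  d <- as.numeric(d)
  attr(d, "times") <- traj$times
  d
}

#' Normalized distance distribution
#'
#' Histogram with uniform bins, reported three ways: raw counts, unit-area
#' density, and the cumulative fraction of samples below each bin edge
#' (both normalizations are provided because printed "normalized
#' distributions" are ambiguous between the two readings).
#'
#' @param series numeric samples (Angstrom).
#' @param bin_width bin width, Angstrom (default 0.01).
#' @return object of class `snn_histogram`: list with `edges`, `counts`,
#'   `density`, `cumulative` (fraction below each *right* edge), `n`,
#'   `bin_width`.
#' @export
distance_histogram <- function(series, bin_width = 0.01) {
  if (!length(series)) stop("empty sample series")
  if (bin_width <= 0) stop("bin width must be positive")
  lo <- floor(min(series) / bin_width) * bin_width
  if (lo > min(series)) lo <- lo - bin_width   # float guard
  nbins <- ceiling((max(series) - lo) / bin_width + 1e-9)
  if (nbins < 1L) nbins <- 1L
  edges <- lo + (0:nbins) * bin_width
  if (edges[length(edges)] <= max(series))
    edges <- c(edges, edges[length(edges)] + bin_width)
  counts <- unname(table(cut(series, breaks = edges, right = FALSE,
                             include.lowest = TRUE)))
  counts <- as.integer(counts)
  n <- length(series)
  structure(list(edges = edges, counts = counts,
                 density = counts / (n * bin_width),
                 cumulative = cumsum(counts) / n,
                 n = n, bin_width = bin_width),
            class = "snn_histogram")
}

#' Fraction of samples below a query distance
#'
#' @param hist `snn_histogram`.
#' @param x query value (same units as the samples).
#' @return fraction in `[0, 1]`, from the empirical cumulative counts.
#' @export
fraction_below <- function(hist, x) {
  stopifnot(inherits(hist, "snn_histogram"))
  idx <- findInterval(x + 1e-9, hist$edges) - 1L
  if (idx <= 0L) return(0)
  if (idx >= length(hist$counts)) return(1)
  hist$cumulative[idx]
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' Fraction of frames in which the donor-acceptor distance is below
#' `d_max` and the donor-H-acceptor angle exceeds `angle_min`.
#'
#' @param traj `snn_trajectory`.
#' @param donor,hydrogen,acceptor atom selectors (see
#'   [distance_series()]).
#' @param d_max,angle_min criteria (defaults 3.5 Angstrom, 140 degrees).
#' @return list with `frames_present`, `n_frames` and `fraction`
#'   (percent).
#' @export
hbond_occupancy <- function(traj, donor, hydrogen, acceptor,
                            d_max = 3.5, angle_min = 140) {
  stopifnot(inherits(traj, "snn_trajectory"))
  id <- .atom_index(traj$topology, donor)
  ih <- .atom_index(traj$topology, hydrogen)
  ia <- .atom_index(traj$topology, acceptor)
  nf <- dim(traj$coords)[1]
  present <- vapply(seq_len(nf), function(f) {
    D <- traj$coords[f, id, ]; H <- traj$coords[f, ih, ]
    A <- traj$coords[f, ia, ]
    .dist3(D, A) < d_max && .angle3(D, H, A) > angle_min
  }, logical(1))
  list(frames_present = sum(present), n_frames = nf,
       fraction = 100 * mean(present))
}

#' Extract structures at requested state-point times
#'
#' The nearest frame is returned for each requested time; exact midpoints
#' tie to the earlier frame.
#'
#' @param traj `snn_trajectory`.
#' @param times requested times, ps (must lie within the trajectory span).
#' @return list of `snn_structure` snapshots.
#' @export
extract_frames <- function(traj, times) {
  stopifnot(inherits(traj, "snn_trajectory"))
  tt <- traj$times
  lapply(times, function(t0) {
    if (t0 < tt[1] || t0 > tt[length(tt)])
      stop("time ", t0, " ps outside trajectory span [", tt[1], ", ",
           tt[length(tt)], "]")
    dev <- abs(tt - t0)
    k <- which(dev == min(dev))[1L]   # ties to the earlier frame
    s <- traj$topology
    s$atoms$x <- traj$coords[k, , 1]
    s$atoms$y <- traj$coords[k, , 2]
    s$atoms$z <- traj$coords[k, , 3]
    s$id <- paste0(s$id, "_t", format(tt[k]))
    s
  })
}

#' Read / write trajectories as plain text
#'
#' Two formats: `"xyz"`, a frame-per-block text format (atom-count header,
#' a `t= <ps>` comment line, then one `name x y z` row per atom - atom
#' metadata beyond the name comes from a supplied topology), and `"pdb"`,
#' multi-model PDB (MODEL/ENDMDL blocks).
#'
#' @param traj `snn_trajectory`.
#' @param path file path.
#' @param format `"xyz"` or `"pdb"`.
#' @param topology required to read `"xyz"` (supplies chain/residue
#'   metadata); optional for `"pdb"`.
#' @return `read_trajectory`: `snn_trajectory`; `write_trajectory`: the
#'   path, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("xyz", "pdb")) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "snn_trajectory"))
  a <- traj$topology$atoms
  nf <- dim(traj$coords)[1]
  if (format == "xyz") {
    con <- file(path, "w"); on.exit(close(con))
    for (f in seq_len(nf)) {
      writeLines(c(as.character(nrow(a)),
                   paste0("t= ", format(traj$times[f], digits = 12))), con)
      writeLines(sprintf("%-4s %12.5f %12.5f %12.5f", a$name,
                         traj$coords[f, , 1], traj$coords[f, , 2],
                         traj$coords[f, , 3]), con)
    }
  } else {
    if (file.exists(path)) file.remove(path)
    for (f in seq_len(nf)) {
      cat(sprintf("MODEL     %4d\n", f), file = path, append = TRUE)
      bio3d::write.pdb(
        pdb = NULL, file = path, append = TRUE, end = FALSE,
        xyz = as.numeric(t(traj$coords[f, , ])),
        type = ifelse(a$het, "HETATM", "ATOM"),
        resno = a$resno, resid = a$resid, eleno = a$serial,
        elety = a$name, chain = ifelse(a$chain == " ", "", a$chain),
        insert = a$insert, o = a$occupancy, b = a$b, elesy = a$elesy)
      cat("ENDMDL\n", file = path, append = TRUE)
    }
    cat("END\n", file = path, append = TRUE)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @param timestep used for `"pdb"` input, where frame times are not
#'   stored (default 1 ps).
#' @export
read_trajectory <- function(path, format = c("xyz", "pdb"),
                            topology = NULL, timestep = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "xyz") {
    if (is.null(topology))
      stop("reading xyz trajectories requires a topology")
    lines <- readLines(path)
    natoms <- nrow(topology$atoms)
    pos <- 1L; frames <- list(); times <- numeric()
    while (pos <= length(lines)) {
      if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
      nat <- suppressWarnings(as.integer(trimws(lines[pos])))
      if (is.na(nat) || nat != natoms)
        stop("frame at line ", pos, " has ", nat, " atoms; topology has ",
             natoms)
      tline <- lines[pos + 1L]
      t0 <- suppressWarnings(as.numeric(sub(".*t=\\s*", "", tline)))
      if (is.na(t0)) t0 <- length(times) * timestep
      block <- lines[pos + 1L + seq_len(nat)]
      m <- t(vapply(strsplit(trimws(block), "\\s+"), function(tok)
        as.numeric(tok[2:4]), numeric(3)))
      frames[[length(frames) + 1L]] <- m
      times <- c(times, t0)
      pos <- pos + 2L + nat
    }
    coords <- array(0, dim = c(length(frames), natoms, 3))
    for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
    new_trajectory(topology, coords, times = times)
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    if (is.null(topology)) {
      tmp <- tempfile(fileext = ".pdb")
      on.exit(unlink(tmp))
      # first model as topology
      bio3d::write.pdb(pdb, file = tmp, xyz = pdb$xyz[1, ])
      topology <- read_structure(tmp)
    }
    nf <- nrow(pdb$xyz)
    natoms <- nrow(topology$atoms)
    coords <- array(0, dim = c(nf, natoms, 3))
    for (f in seq_len(nf))
      coords[f, , ] <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
    new_trajectory(topology, coords, timestep = timestep)
  }
}
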