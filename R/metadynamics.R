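# Reaction-coordinate and free-energy machinery for nontempered
# metadynamics: rational switching functions, coordination-number collective
# variables, upper-wall bias, hills bookkeeping, free-energy-surface
# reconstruction and minimum-free-energy-path barrier extraction.

#' Rational switching function (coordination number of a single contact)
#'
#' `s(r) = (1 - (r/r0)^nn) / (1 - (r/r0)^mm)`, a smooth 0-1 measure of
#' whether a contact is formed.  The removable singularity at `r = r0`
#' evaluates to `nn/mm` (0.5 for the default exponents 6/12).  Strictly
#' decreasing in r.
#'
#' @param r distance, Angstrom (vectorized).
#' @param r0 reference distance, Angstrom.
#' @param nn,mm integer exponents, `mm > nn > 0` (defaults 6 and 12, the
#'   common engine defaults).
#' @return value in `[0, 1]`.
#' @export
switching <- function(r, r0, nn = 6, mm = 12) {
  stopifnot(r0 > 0, mm > nn, nn > 0)
  x <- r / r0
  out <- numeric(length(x))
  sing <- abs(x - 1) < 1e-10
  out[sing] <- nn / mm
  xs <- x[!sing]
  out[!sing] <- (1 - xs^nn) / (1 - xs^mm)
  out
}

#' Define a collective variable as a signed combination of two coordination
#' numbers
#'
#' `CV = c_formed * s(d_formed) + c_broken * s(d_broken)` where each s is a
#' rational [switching()] of the distance between one atom pair.  With the
#' default coefficients (+0.5, -0.5) and single-pair coordination numbers
#' in `[0, 1]`, a state with the formed contact absent and the broken
#' contact present maps to -0.5 (reactant) and the converse to +0.5
#' (product).
#'
#' @param pair_formed,pair_broken integer atom-index pairs.
#' @param r0_formed,r0_broken switching reference distances, Angstrom.
#' @param coefficients numeric `c(c_formed, c_broken)`.
#' @param nn,mm switching exponents.
#' @param name label.
#' @return object of class `cv_definition`.
#' @export
cv_definition <- function(pair_formed, pair_broken, r0_formed, r0_broken,
                          coefficients = c(0.5, -0.5), nn = 6, mm = 12,
                          name = "CV") {
  stopifnot(length(pair_formed) == 2, length(pair_broken) == 2,
            all(is.finite(coefficients)))
  if (all(sort(pair_formed) == sort(pair_broken)))
    stop("formed and broken atom pairs must be distinct")
  structure(list(name = name, pair_formed = as.integer(pair_formed),
                 pair_broken = as.integer(pair_broken),
                 r0_formed = r0_formed, r0_broken = r0_broken,
                 coefficients = coefficients, nn = nn, mm = mm),
            class = "cv_definition")
}

#' Evaluate a collective variable on one coordinate frame
#'
#' @param coords n x 3 matrix of atom coordinates (Angstrom).
#' @param cvdef a [cv_definition()].
#' @return numeric CV value.
#' @export
evaluate_cv <- function(coords, cvdef) {
  stopifnot(inherits(cvdef, "cv_definition"))
  coords <- as.matrix(coords)
  idx <- c(cvdef$pair_formed, cvdef$pair_broken)
  if (any(idx < 1L | idx > nrow(coords)))
    stop("CV atom index outside the frame (", nrow(coords), " atoms)")
  d_f <- .dist3(coords[cvdef$pair_formed[1], ], coords[cvdef$pair_formed[2], ])
  d_b <- .dist3(coords[cvdef$pair_broken[1], ], coords[cvdef$pair_broken[2], ])
  cvdef$coefficients[1] * switching(d_f, cvdef$r0_formed, cvdef$nn, cvdef$mm) +
    cvdef$coefficients[2] * switching(d_b, cvdef$r0_broken, cvdef$nn, cvdef$mm)
}

#' One-sided upper-wall bias energy
#'
#' Zero at or below the wall location, `k * (d - location)^exponent` beyond
#' it; used to keep reactive partners together.
#'
#' @param distance Angstrom (vectorized).
#' @param location wall position, Angstrom (default 5.5).
#' @param force_constant kcal/mol (default 200).
#' @param exponent integer (default 2, harmonic).
#' @return energy in kcal/mol.
#' @export
wall_energy <- function(distance, location = 5.5, force_constant = 200,
                        exponent = 2) {
  stopifnot(location > 0, force_constant >= 0)
  ifelse(distance <= location, 0,
         force_constant * (distance - location)^exponent)
}

# ---- hills ----------------------------------------------------------------

#' Create a hills table
#'
#' @param time ps.
#' @param centers matrix (n x d) of hill centers in CV space.
#' @param sigma per-CV widths (recycled; defaults 0.005 and 0.006 for the
#'   two-CV case).
#' @param height hill heights in kcal/mol (default 0.59, recycled).
#' @return data.frame of class `snn_hills` with columns `time`,
#'   `cv1..cvd`, `sigma1..sigmad`, `height`.
#' @export
hills_table <- function(time, centers, sigma = c(0.005, 0.006),
                        height = 0.59) {
  centers <- as.matrix(centers)
  d <- ncol(centers)
  stopifnot(all(sigma > 0), all(height >= 0))
  sig <- matrix(rep(rep_len(sigma, d), each = nrow(centers)),
                ncol = d)
  out <- data.frame(time = time)
  for (k in seq_len(d)) out[[paste0("cv", k)]] <- centers[, k]
  for (k in seq_len(d)) out[[paste0("sigma", k)]] <- sig[, k]
  out$height <- rep_len(height, nrow(centers))
  class(out) <- c("snn_hills", "data.frame")
  out
}

.hills_ncv <- function(hills) sum(grepl("^cv[0-9]+$", names(hills)))

#' Read / write PLUMED-style HILLS files
#'
#' Whitespace-column text: time, one column per CV center, per-CV sigma,
#' height; a trailing bias-factor column is tolerated and ignored.  A
#' `#! FIELDS` header, when present, determines the CV count; otherwise it
#' is inferred from the column count.  Comment lines are preserved on
#' write, and `write_hills(read_hills(f))` round-trips the bias function
#' exactly.
#'
#' @param path file path.
#' @param ncv number of CVs; inferred when `NULL`.
#' @return `read_hills`: an `snn_hills` data.frame; `write_hills`: the path,
#'   invisibly.
#' @export
read_hills <- function(path, ncv = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  comments <- lines[grepl("^\\s*#", lines)]
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stop("no hill rows in ", path)
  fields <- comments[grepl("FIELDS", comments)]
  has_biasf <- FALSE
  if (length(fields) && is.null(ncv)) {
    toks <- strsplit(trimws(sub(".*FIELDS", "", fields[1])), "\\s+")[[1]]
    ncv <- sum(grepl("^sigma", toks))
    has_biasf <- any(toks %in% c("biasf", "bias_factor"))
  }
  parsed <- lapply(seq_along(body), function(i) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(body[i]),
                                                 "\\s+")[[1]]))
    if (any(is.na(vals)))
      stop("malformed hills row at data line ", i, " of ", path)
    vals
  })
  ncols <- unique(lengths(parsed))
  if (length(ncols) != 1L)
    stop("inconsistent column counts in ", path)
  if (is.null(ncv)) {
    if ((ncols - 2L) %% 2L == 0L) ncv <- (ncols - 2L) %/% 2L
    else { ncv <- (ncols - 3L) %/% 2L; has_biasf <- TRUE }
    if (ncv < 1L) stop("cannot infer CV count from ", ncols, " columns")
  }
  expected <- 2L + 2L * ncv + has_biasf
  if (ncols != expected && ncols != expected + 1L)
    stop("hills file has ", ncols, " columns; expected ", expected,
         " for ", ncv, " CV(s)")
  m <- do.call(rbind, parsed)
  out <- hills_table(m[, 1], m[, 1 + seq_len(ncv), drop = FALSE],
                     sigma = 1, height = m[, 2 + 2 * ncv])
  for (k in seq_len(ncv)) out[[paste0("sigma", k)]] <- m[, 1 + ncv + k]
  attr(out, "comments") <- comments
  out
}

#' @rdname read_hills
#' @param hills an `snn_hills` data.frame.
#' @export
write_hills <- function(hills, path) {
  d <- .hills_ncv(hills)
  comments <- attr(hills, "comments")
  if (is.null(comments))
    comments <- paste("#! FIELDS time",
                      paste0("cv", seq_len(d), collapse = " "),
                      paste0("sigma", seq_len(d), collapse = " "),
                      "height")
  cols <- c("time", paste0("cv", seq_len(d)),
            paste0("sigma", seq_len(d)), "height")
  rows <- apply(as.matrix(hills[, cols]), 1, function(v)
    paste(formatC(v, format = "g", digits = 12), collapse = " "))
  writeLines(c(comments, rows), path)
  invisible(path)
}

#' Metadynamics bias potential from deposited hills
#'
#' Sum over hills of `height * exp(-sum_d (x_d - center_d)^2 / (2 sigma_d^2))`
#' (nontempered Gaussian deposition).
#'
#' @param point numeric CV vector, or matrix (m x d) of evaluation points.
#' @param hills `snn_hills` data.frame.
#' @return bias energy in kcal/mol (one value per evaluation point).
#' @export
bias_potential <- function(point, hills) {
  d <- .hills_ncv(hills)
  pts <- if (is.matrix(point)) point else matrix(point, nrow = 1)
  if (ncol(pts) != d)
    stop("point dimensionality (", ncol(pts),
         ") does not match hills (", d, " CVs)")
  if (nrow(hills) == 0L) return(numeric(nrow(pts)))
  centers <- as.matrix(hills[, paste0("cv", seq_len(d)), drop = FALSE])
  sigmas <- as.matrix(hills[, paste0("sigma", seq_len(d)), drop = FALSE])
  h <- hills$height
  vapply(seq_len(nrow(pts)), function(i) {
    e <- 0
    for (k in seq_len(d))
      e <- e + (pts[i, k] - centers[, k])^2 / (2 * sigmas[, k]^2)
    sum(h * exp(-e))
  }, numeric(1))
}

# ---- free-energy surface --------------------------------------------------

#' Reconstruct the free-energy surface from hills (nontempered estimator)
#'
#' `F(x) = -V(x) + const`, with the constant chosen so that `min F = 0`.
#' Supports 1D and 2D CV spaces on uniform grids.  For speed each Gaussian
#' is accumulated only over its +/- 8 sigma support (truncation below
#' 1e-14 relative).
#'
#' Two estimators are offered.  `"sum"` is the plain negated hill sum at
#' the end of the run.  `"tail-average"` averages `-V(x, t)` over the final
#' `tail_fraction` of the deposition history, the standard remedy for the
#' deposition sawtooth of nontempered runs; it reduces to weighting hill i
#' in the tail by `(n - i + 1) / K` and leaves earlier hills untouched, so
#' it is still a single weighted Gaussian sum.
#'
#' @param hills `snn_hills`.
#' @param min,max,spacing per-CV grid bounds and spacing (defaults
#'   -0.8..0.8, 0.01; recycled to the CV count).
#' @param warn_uncovered warn when the grid does not cover all hill centers
#'   +/- 4 sigma (evaluation is then clipped to the grid).
#' @param estimator `"sum"` (default) or `"tail-average"`.
#' @param tail_fraction fraction of the deposition history averaged by the
#'   tail estimator (default 0.25).
#' @return object of class `fes_grid`: list with `axes` (list of node
#'   vectors) and `values` (vector for 1D, matrix `[i, j]` over
#'   `axes[[1]] x axes[[2]]` for 2D), min-shifted to 0.
#' @export
reconstruct_fes <- function(hills, min = -0.8, max = 0.8, spacing = 0.01,
                            warn_uncovered = TRUE,
                            estimator = c("sum", "tail-average"),
                            tail_fraction = 0.25) {
  estimator <- match.arg(estimator)
  if (estimator == "tail-average" && nrow(hills) > 1L) {
    n <- nrow(hills)
    K <- base::max(1L, floor(tail_fraction * n))
    idx <- (n - K + 1L):n
    w <- rep(1, n)
    w[idx] <- (n - idx + 1) / K
    hills$height <- hills$height * w
  }
  d <- .hills_ncv(hills)
  if (d > 2L) stop("FES reconstruction supports 1 or 2 CVs")
  min <- rep_len(min, d); max <- rep_len(max, d)
  spacing <- rep_len(spacing, d)
  axes <- lapply(seq_len(d), function(k) seq(min[k], max[k], by = spacing[k]))
  if (nrow(hills)) {
    centers <- as.matrix(hills[, paste0("cv", seq_len(d)), drop = FALSE])
    sigmas <- as.matrix(hills[, paste0("sigma", seq_len(d)), drop = FALSE])
    for (k in seq_len(d)) {
      lo <- centers[, k] - 4 * sigmas[, k]
      hi <- centers[, k] + 4 * sigmas[, k]
      if (warn_uncovered && (any(lo < min[k]) || any(hi > max[k])))
        warning("grid does not cover all hills (+/- 4 sigma) along CV", k,
                "; evaluation clipped", call. = FALSE)
    }
  }
  if (d == 1L) {
    V <- numeric(length(axes[[1]]))
    if (nrow(hills)) for (i in seq_len(nrow(hills))) {
      idx <- which(abs(axes[[1]] - centers[i, 1]) <= 8 * sigmas[i, 1])
      if (length(idx))
        V[idx] <- V[idx] + hills$height[i] *
          exp(-(axes[[1]][idx] - centers[i, 1])^2 / (2 * sigmas[i, 1]^2))
    }
  } else {
    V <- matrix(0, length(axes[[1]]), length(axes[[2]]))
    if (nrow(hills)) for (i in seq_len(nrow(hills))) {
      ix <- which(abs(axes[[1]] - centers[i, 1]) <= 8 * sigmas[i, 1])
      iy <- which(abs(axes[[2]] - centers[i, 2]) <= 8 * sigmas[i, 2])
      if (length(ix) && length(iy)) {
        gx <- exp(-(axes[[1]][ix] - centers[i, 1])^2 /
                    (2 * sigmas[i, 1]^2))
        gy <- exp(-(axes[[2]][iy] - centers[i, 2])^2 /
                    (2 * sigmas[i, 2]^2))
        V[ix, iy] <- V[ix, iy] + hills$height[i] * outer(gx, gy)
      }
    }
  }
  f <- -V
  f <- f - base::min(f)
  structure(list(axes = axes, values = f, spacing = spacing),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  dims <- vapply(x$axes, length, integer(1))
  cat("<fes_grid> ", paste(dims, collapse = " x "), " nodes, range [0, ",
      format(base::max(x$values), digits = 4), "] kcal/mol\n", sep = "")
  invisible(x)
}

#' Export a 2D free-energy surface as TSV
#'
#' @param fes `fes_grid` (2D).
#' @param path output TSV path (columns cv1, cv2, free_energy).
#' @export
write_fes_tsv <- function(fes, path) {
  stopifnot(inherits(fes, "fes_grid"), length(fes$axes) == 2L)
  grid <- expand.grid(cv1 = fes$axes[[1]], cv2 = fes$axes[[2]])
  grid$free_energy <- as.vector(fes$values)
  utils::write.table(grid, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Locate the free-energy minimum of a basin
#'
#' Returns the grid node with the lowest free energy within `radius` of a
#' given CV point.  Useful as the start of a barrier measurement: an
#' activation barrier is conventionally referenced to the basin floor, and
#' on a reconstructed (noisy) surface the floor node is a steadier
#' reference than the nominal basin center.
#'
#' @param fes `fes_grid` (2D).
#' @param near CV point `c(cv1, cv2)` at the nominal basin center.
#' @param radius search radius in CV units (default 0.1).
#' @return list with `point` (CV coordinates) and `value` (kcal/mol).
#' @export
fes_basin_minimum <- function(fes, near, radius = 0.1) {
  stopifnot(inherits(fes, "fes_grid"), length(fes$axes) == 2L)
  ix <- which(abs(fes$axes[[1]] - near[1]) <= radius)
  iy <- which(abs(fes$axes[[2]] - near[2]) <= radius)
  if (!length(ix) || !length(iy))
    stop("no grid nodes within ", radius, " of the basin center")
  sub <- fes$values[ix, iy, drop = FALSE]
  k <- which(sub == base::min(sub), arr.ind = TRUE)[1, ]
  list(point = c(fes$axes[[1]][ix[k[1]]], fes$axes[[2]][iy[k[2]]]),
       value = base::min(sub))
}

# ---- minimum free energy path --------------------------------------------

# nearest grid node (indices) to a CV point
.nearest_node <- function(fes, point) {
  vapply(seq_along(fes$axes), function(k) {
    ax <- fes$axes[[k]]
    if (point[k] < ax[1] - 1e-9 || point[k] > ax[length(ax)] + 1e-9)
      stop("point (", paste(signif(point, 4), collapse = ", "),
           ") outside the grid along CV", k)
    which.min(abs(ax - point[k]))
  }, integer(1))
}

#' Minimum free energy path between two points on a 2D FES grid
#'
#' The default path cost is minimax: among all 8-connected grid paths the
#' one minimizing the maximum free energy en route, since an activation
#' barrier is a path-maximum quantity.  The exact minimax level is found by
#' threshold connectivity (nodes are admitted in increasing F until start
#' and end join); within the admitted subgraph the returned path minimizes
#' the integrated (summed) free energy, ties broken by node order.
#' `mode = "integrated"` instead minimizes summed F over the whole grid.
#'
#' @param fes `fes_grid` (2D).
#' @param start,end CV-space points `c(cv1, cv2)` inside the grid.
#' @param mode `"minimax"` (default) or `"integrated"`.
#' @return object of class `mfep_path`: list with `nodes` (m x 2 matrix of
#'   CV coordinates), `indices` (m x 2 grid indices), `profile` (free
#'   energy per node, kcal/mol) and `barrier`
#'   (`max(profile) - profile[1]`).
#' @export
min_free_energy_path <- function(fes, start, end,
                                 mode = c("minimax", "integrated")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fes, "fes_grid"), length(fes$axes) == 2L)
  f <- fes$values
  nx <- nrow(f); ny <- ncol(f)
  s <- .nearest_node(fes, start); e <- .nearest_node(fes, end)
  sid <- s[1] + (s[2] - 1L) * nx
  eid <- e[1] + (e[2] - 1L) * nx
  fv <- as.vector(f)
  n <- nx * ny
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), , drop = FALSE]
  neighbours <- function(id) {
    i <- ((id - 1L) %% nx) + 1L
    j <- ((id - 1L) %/% nx) + 1L
    ii <- i + offs[, 1]; jj <- j + offs[, 2]
    ok <- ii >= 1L & ii <= nx & jj >= 1L & jj <= ny
    ii[ok] + (jj[ok] - 1L) * nx
  }
  if (mode == "minimax") {
    # threshold connectivity: admit nodes in increasing F until start and
    # end share a component; the last admitted F is the exact minimax level
    ord <- order(fv)
    parent <- seq_len(n)
    uf_find <- function(i) {            # union-find with path halving
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    admitted <- logical(n)
    level <- NA_real_
    for (id in ord) {
      admitted[id] <- TRUE
      for (nb in neighbours(id)) if (admitted[nb]) {
        ra <- uf_find(id); rb <- uf_find(nb)
        if (ra != rb) parent[ra] <- rb
      }
      if (admitted[sid] && admitted[eid] &&
          uf_find(sid) == uf_find(eid)) {
        level <- fv[id]
        break
      }
    }
    allowed <- fv <= level + 1e-12
  } else {
    allowed <- rep(TRUE, n)
  }
  # Dijkstra minimizing summed node F within the allowed set
  dist <- rep(Inf, n); dist[sid] <- fv[sid]
  prev <- integer(n)
  done <- rep(FALSE, n)
  while (TRUE) {
    u <- which.min(ifelse(done | !allowed, Inf, dist))
    if (!is.finite(dist[u])) stop("start and end are not connected")
    if (u == eid) break
    done[u] <- TRUE
    for (nb in neighbours(u)) {
      if (done[nb] || !allowed[nb]) next
      alt <- dist[u] + fv[nb]
      if (alt < dist[nb]) { dist[nb] <- alt; prev[nb] <- u }
    }
  }
  path <- eid
  while (path[1] != sid) path <- c(prev[path[1]], path)
  pi <- ((path - 1L) %% nx) + 1L
  pj <- ((path - 1L) %/% nx) + 1L
  nodes <- cbind(fes$axes[[1]][pi], fes$axes[[2]][pj])
  profile <- fv[path]
  structure(list(nodes = nodes, indices = cbind(pi, pj),
                 profile = profile,
                 barrier = base::max(profile) - profile[1]),
            class = "mfep_path")
}

#' @export
print.mfep_path <- function(x, ...) {
  cat("<mfep_path> ", nrow(x$nodes), " nodes, barrier ",
      format(x$barrier, digits = 4), " kcal/mol\n", sep = "")
  invisible(x)
}

# ---- transition detection -------------------------------------------------

#' First reactant-to-product transition in CV time series
#'
#' Earliest time at which every CV exceeds `threshold` and remains above it
#' for a dwell window (which suppresses recrossing noise).  Returns `NA`
#' when no transition occurs - that is a result, not an error.
#'
#' @param times time points, ps (strictly increasing).
#' @param cvs numeric vector or matrix (one column per CV).
#' @param threshold crossing level (default 0, halfway between the -0.5
#'   reactant and +0.5 product endpoints).
#' @param dwell dwell window in ps (default 0.2).
#' @return crossing time (ps) or `NA_real_`.
#' @export
detect_transition <- function(times, cvs, threshold = 0, dwell = 0.2) {
  cvs <- as.matrix(cvs)
  stopifnot(length(times) == nrow(cvs), nrow(cvs) > 0,
            !is.unsorted(times, strictly = TRUE))
  ok <- rowSums(cvs > threshold) == ncol(cvs)
  for (i in which(ok)) {
    win <- times >= times[i] & times <= times[i] + dwell
    if (all(ok[win])) return(times[i])
  }
  NA_real_
}
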