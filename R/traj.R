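# Post-analysis of binding-stability simulations and metadynamics output:
# superposed RMSD series, geometric hydrogen-bond counting, stability
# ranking of candidates, and free-energy reconstruction from deposited
# Gaussian hills.

#' Create a trajectory object
#'
#' @param coords 3D array `frames x atoms x 3`, Angstrom.
#' @param times Frame times (ps), strictly increasing.
#' @param atoms data.frame of per-atom metadata (at least `element`; may
#'   carry `name`, `resno`).
#' @param selections Named list of atom index vectors; conventional names:
#'   `ligand`, `calpha`, `donors` (data.frame with columns `d`, `h`),
#'   `acceptors`.
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(coords, times, atoms, selections = list()) {
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  n_frames <- dim(coords)[1]; n_atoms <- dim(coords)[2]
  stopifnot(length(times) == n_frames, nrow(atoms) == n_atoms)
  if (n_frames > 1 && any(diff(times) <= 0)) {
    stopf("frame times must be strictly increasing")
  }
  if (!all(is.finite(coords))) stopf("trajectory coordinates must be finite")
  structure(list(coords = coords, times = as.numeric(times), atoms = atoms,
                 selections = selections),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d frames, %d atoms, %.0f-%.0f ps>\n",
              dim(x$coords)[1], dim(x$coords)[2], x$times[1],
              utils::tail(x$times, 1)))
  invisible(x)
}

#' Read a trajectory from a multi-model PDB file
#'
#' @param path PDB with MODEL/ENDMDL blocks.
#' @param dt Frame spacing in ps used to synthesize times (default 1).
#' @return A [trajectory()].
#' @export
read_trajectory_pdb <- function(path, dt = 1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  n_frames <- nrow(xyz)
  n_atoms <- ncol(xyz) / 3L
  coords <- array(0, dim = c(n_frames, n_atoms, 3L))
  for (f in seq_len(n_frames)) {
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  }
  a <- pdb$atom
  element <- trimws(a$elesy)
  guess <- toupper(substr(trimws(a$elety), 1, 1))
  element[!nzchar(element) | is.na(element)] <-
    guess[!nzchar(element) | is.na(element)]
  trajectory(coords, times = (seq_len(n_frames) - 1) * dt,
             atoms = data.frame(element = element, name = trimws(a$elety),
                                resno = a$resno, stringsAsFactors = FALSE))
}

#' Read a trajectory from a multi-frame XYZ file
#'
#' Standard XYZ dialect: atom-count line, comment line (a `time=<ps>` token
#' is honoured), then `element x y z` rows, repeated per frame.
#'
#' @param path XYZ file.
#' @return A [trajectory()].
#' @export
read_trajectory_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); times <- numeric(0); atoms <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stopf("malformed XYZ: expected atom count at line %d", i)
    comment <- lines[i + 1L]
    tm <- regmatches(comment, regexpr("time=\\s*[-0-9.eE+]+", comment))
    t_val <- if (length(tm)) as.numeric(sub("time=\\s*", "", tm)) else
      length(frames)
    rows <- strsplit(trimws(lines[i + 1L + seq_len(n)]), "\\s+")
    el <- vapply(rows, `[[`, character(1), 1)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    if (is.null(atoms)) atoms <- data.frame(element = el,
                                            stringsAsFactors = FALSE)
    frames[[length(frames) + 1L]] <- xyz
    times <- c(times, t_val)
    i <- i + 2L + n
  }
  if (length(frames) == 0L) stopf("no frames in XYZ file '%s'", path)
  coords <- array(0, dim = c(length(frames), nrow(atoms), 3L))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  trajectory(coords, times, atoms)
}

#' RMSD time series after least-squares superposition
#'
#' Each frame is optimally superposed (rotation + translation) onto the
#' reference frame over `superpose_selection`, then the RMSD is measured
#' over `measure_selection`. The conventional stability measure for a bound
#' ligand superposes on protein C-alpha atoms and measures over the ligand,
#' separating ligand motion from global tumbling.
#'
#' @param traj A [trajectory()].
#' @param measure_selection Atom indices whose RMSD is reported (defaults
#'   to the `ligand` selection).
#' @param superpose_selection Atom indices used for the fit (>= 3; defaults
#'   to the `calpha` selection).
#' @param reference Reference frame index (default 1).
#' @return data.frame with `time` (ps) and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, measure_selection = NULL,
                        superpose_selection = NULL, reference = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  measure <- measure_selection %||% traj$selections$ligand
  fit_sel <- superpose_selection %||% traj$selections$calpha
  if (is.null(measure) || length(measure) == 0L) {
    stopf("measure selection is empty")
  }
  if (is.null(fit_sel) || length(fit_sel) < 3L) {
    stopf("superpose selection needs at least 3 atoms")
  }
  n_frames <- dim(traj$coords)[1]
  ref <- traj$coords[reference, , ]
  ref_xyz <- as.vector(t(ref))
  fit_inds <- as.vector(t(cbind(3 * fit_sel - 2, 3 * fit_sel - 1,
                                3 * fit_sel)))
  out <- data.frame(time = traj$times, rmsd = NA_real_)
  for (f in seq_len(n_frames)) {
    mob_xyz <- as.vector(t(traj$coords[f, , ]))
    fitted <- bio3d::fit.xyz(fixed = ref_xyz, mobile = mob_xyz,
                             fixed.inds = fit_inds, mobile.inds = fit_inds)
    fm <- matrix(fitted, ncol = 3L, byrow = TRUE)
    d <- fm[measure, , drop = FALSE] - ref[measure, , drop = FALSE]
    out$rmsd[f] <- sqrt(mean(rowSums(d^2)))
  }
  out
}

#' Hydrogen-bond acceptance criteria
#'
#' @param d_max Maximum donor-acceptor distance, Angstrom (default 3.5).
#' @param angle_min Minimum donor-hydrogen-acceptor angle, degrees
#'   (default 130).
#' @return Object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(d_max = 3.5, angle_min = 130) {
  if (!is_scalar_number(d_max) || d_max <= 0) stopf("d_max must be > 0")
  if (!is_scalar_number(angle_min) || angle_min <= 0 || angle_min > 180) {
    stopf("angle_min must lie in (0, 180]")
  }
  structure(list(d_max = d_max, angle_min = angle_min),
            class = "hbond_criteria")
}

#' Hydrogen-bond count time series
#'
#' Per frame, counts donor-H...acceptor triples with donor-acceptor
#' distance <= `d_max` and D-H...A angle >= `angle_min`. Donors are given
#' as (heavy donor, bonded hydrogen) index pairs; an acceptor identical to
#' the donor atom is skipped.
#'
#' @param traj A [trajectory()].
#' @param criteria A [hbond_criteria()].
#' @param donors data.frame with columns `d` (donor heavy atom index) and
#'   `h` (its hydrogen index); defaults to the `donors` selection.
#' @param acceptors Acceptor atom indices; defaults to the `acceptors`
#'   selection.
#' @return data.frame with `time` and `count`.
#' @export
hbond_series <- function(traj, criteria = hbond_criteria(), donors = NULL,
                         acceptors = NULL) {
  stopifnot(inherits(traj, "trajectory"),
            inherits(criteria, "hbond_criteria"))
  donors <- donors %||% traj$selections$donors
  acceptors <- acceptors %||% traj$selections$acceptors
  if (is.null(donors) || nrow(donors) == 0L) stopf("donor selection is empty")
  if (is.null(acceptors) || length(acceptors) == 0L) {
    stopf("acceptor selection is empty")
  }
  n_frames <- dim(traj$coords)[1]
  counts <- integer(n_frames)
  for (f in seq_len(n_frames)) {
    xyz <- traj$coords[f, , ]
    n <- 0L
    for (k in seq_len(nrow(donors))) {
      D <- xyz[donors$d[k], ]; H <- xyz[donors$h[k], ]
      for (a in acceptors) {
        if (a == donors$d[k] || a == donors$h[k]) next
        A <- xyz[a, ]
        if (sqrt(sum((D - A)^2)) > criteria$d_max) next
        v1 <- D - H; v2 <- A - H
        cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
        ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        if (ang >= criteria$angle_min) n <- n + 1L
      }
    }
    counts[f] <- n
  }
  data.frame(time = traj$times, count = counts)
}

#' Create a metadynamics hills log
#'
#' @param entries data.frame with columns `time`, `center`, `sigma`,
#'   `height` (one deposited Gaussian per row).
#' @return Object of class `hills_log`.
#' @export
hills_log <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("time", "center", "sigma", "height") %in% names(entries)))
  if (nrow(entries) == 0L) stopf("hills log is empty")
  if (any(entries$sigma <= 0)) stopf("hill widths must be positive")
  if (any(entries$height < 0)) stopf("hill heights must be non-negative")
  structure(list(entries = entries), class = "hills_log")
}

#' Read a metadynamics HILLS file
#'
#' Whitespace-delimited columns time, center, sigma, height; `#` comment
#' lines are skipped (the common HILLS layout).
#'
#' @param path File path.
#' @return A [hills_log()].
#' @export
read_hills <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(lines) == 0L) stopf("no hills in '%s'", path)
  vals <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  df <- do.call(rbind, lapply(vals, function(v) {
    data.frame(time = v[1], center = v[2], sigma = v[3], height = v[4])
  }))
  hills_log(df)
}

#' Reconstruct a 1D free-energy surface from deposited hills
#'
#' The free-energy estimate at grid point s is the negated bias:
#' `F(s) = -sum_k h_k * exp(-(s - s_k)^2 / (2 sigma_k^2))`. The default
#' grid spans `[min center - 3 sigma_max, max center + 3 sigma_max]` with
#' 512 points. Optionally shifts so the minimum is zero.
#'
#' @param hills A [hills_log()].
#' @param grid Optional explicit grid of collective-variable values.
#' @param n_points Grid size when `grid` is `NULL`.
#' @param zero_min If `TRUE`, shift so `min(F) = 0`.
#' @return Object of class `fes_grid`: data.frame `grid` with `s` and
#'   `free_energy`.
#' @export
reconstruct_fes <- function(hills, grid = NULL, n_points = 512L,
                            zero_min = FALSE) {
  stopifnot(inherits(hills, "hills_log"))
  e <- hills$entries
  if (is.null(grid)) {
    pad <- 3 * max(e$sigma)
    grid <- seq(min(e$center) - pad, max(e$center) + pad,
                length.out = n_points)
  }
  # outer() over (grid point, hill): vectorized Gaussian sum
  diff2 <- outer(grid, e$center, `-`)^2
  bias <- sweep(exp(-sweep(diff2, 2, 2 * e$sigma^2, `/`)), 2, e$height, `*`)
  f <- -rowSums(bias)
  if (zero_min) f <- f - min(f)
  structure(list(grid = data.frame(s = grid, free_energy = f),
                 zero_min = zero_min),
            class = "fes_grid")
}

#' Write a reconstructed free-energy surface as two-column text
#'
#' @param fes An `fes_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fes <- function(fes, path) {
  stopifnot(inherits(fes, "fes_grid"))
  utils::write.table(fes$grid, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Rank candidates by binding stability
#'
#' Candidates are ranked ascending by mean measured RMSD over their series;
#' the most stable k are returned.
#'
#' @param series Named list of RMSD series (data.frames from
#'   [rmsd_series()], or numeric vectors).
#' @param k Number of candidates to return.
#' @return Character vector of the top-k candidate ids, most stable first.
#' @export
stability_rank <- function(series, k) {
  if (k > length(series)) {
    stopf("k = %d exceeds the %d available candidates", k, length(series))
  }
  if (is.null(names(series)) || any(!nzchar(names(series)))) {
    stopf("series must be a named list")
  }
  means <- vapply(series, function(s) {
    v <- if (is.data.frame(s)) s$rmsd else as.numeric(s)
    mean(v)
  }, numeric(1))
  names(sort(means))[seq_len(k)]
}
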