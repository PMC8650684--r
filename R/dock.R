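# Docking integration: Vina-style configuration, a deterministic mock
# engine (the test default, so the suite never needs a docking binary), and
# result-log parsing. Affinities are kcal/mol, more negative is better.

#' Create a docking configuration
#'
#' Defaults follow common practice for cascade screening: a cubic search
#' box of 2.5 nm (25 Angstrom) per side centred on the pocket mass centre,
#' exhaustiveness 8, 20 output modes, energy range 3 kcal/mol.
#'
#' @param center Box centre (x, y, z), Angstrom.
#' @param size Box edge lengths (x, y, z), Angstrom.
#' @param exhaustiveness Search exhaustiveness (>= 1).
#' @param num_modes Maximum number of output poses.
#' @param energy_range Max energy spread of reported poses, kcal/mol.
#' @return Object of class `docking_config`.
#' @export
docking_config <- function(center, size = c(25, 25, 25),
                           exhaustiveness = 8L, num_modes = 20L,
                           energy_range = 3) {
  center <- as.numeric(center); size <- as.numeric(size)
  stopifnot(length(center) == 3L, length(size) == 3L)
  if (any(size <= 0)) stopf("box sizes must be positive")
  if (exhaustiveness < 1) stopf("exhaustiveness must be >= 1")
  structure(list(center = center, size = size,
                 exhaustiveness = as.integer(exhaustiveness),
                 num_modes = as.integer(num_modes),
                 energy_range = as.numeric(energy_range)),
            class = "docking_config")
}

#' Build a docking configuration from a pocket
#'
#' @param pocket A [pocket_definition()] (supplies the box centre).
#' @param size_nm Box edge length in nm (default 2.5; converted to Angstrom).
#' @param ... Overrides passed to [docking_config()].
#' @return A `docking_config`.
#' @export
make_config <- function(pocket, size_nm = 2.5, ...) {
  stopifnot(inherits(pocket, "pocket_definition"))
  docking_config(center = pocket$mass_center,
                 size = rep(nm_to_angstrom(size_nm), 3), ...)
}

#' Write / read a Vina-style configuration text file
#'
#' @param config A `docking_config`.
#' @param path File path.
#' @param receptor,ligand Optional receptor/ligand PDBQT paths to embed.
#' @return `path` invisibly ([write_vina_config()]) or a list with
#'   `config`, `receptor`, `ligand` ([read_vina_config()]).
#' @export
write_vina_config <- function(config, path, receptor = NULL, ligand = NULL) {
  stopifnot(inherits(config, "docking_config"))
  lines <- c(
    if (!is.null(receptor)) sprintf("receptor = %s", receptor),
    if (!is.null(ligand)) sprintf("ligand = %s", ligand),
    sprintf("center_x = %.4f", config$center[1]),
    sprintf("center_y = %.4f", config$center[2]),
    sprintf("center_z = %.4f", config$center[3]),
    sprintf("size_x = %.4f", config$size[1]),
    sprintf("size_y = %.4f", config$size[2]),
    sprintf("size_z = %.4f", config$size[3]),
    sprintf("exhaustiveness = %d", config$exhaustiveness),
    sprintf("num_modes = %d", config$num_modes),
    sprintf("energy_range = %g", config$energy_range)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_vina_config
#' @export
read_vina_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(sub("#.*$", "", lines), "=", fixed = TRUE)
  kv <- kv[vapply(kv, length, integer(1)) == 2L]
  keys <- vapply(kv, function(p) trimws(p[1]), character(1))
  vals <- vapply(kv, function(p) trimws(p[2]), character(1))
  getn <- function(k) as.numeric(vals[match(k, keys)])
  list(
    config = docking_config(
      center = c(getn("center_x"), getn("center_y"), getn("center_z")),
      size = c(getn("size_x"), getn("size_y"), getn("size_z")),
      exhaustiveness = getn("exhaustiveness"),
      num_modes = getn("num_modes"),
      energy_range = getn("energy_range")
    ),
    receptor = if ("receptor" %in% keys) vals[match("receptor", keys)],
    ligand = if ("ligand" %in% keys) vals[match("ligand", keys)]
  )
}

docking_result <- function(poses, coords = NULL) {
  stopifnot(is.data.frame(poses), nrow(poses) >= 1L,
            all(c("mode", "affinity") %in% names(poses)))
  structure(list(poses = poses, coords = coords,
                 best_affinity = min(poses$affinity)),
            class = "docking_result")
}

#' @export
print.docking_result <- function(x, ...) {
  cat(sprintf("<docking result: %d poses, best %.2f kcal/mol>\n",
              nrow(x$poses), x$best_affinity))
  invisible(x)
}

#' Run (or mock) a docking calculation
#'
#' The mock engine is deterministic: the best affinity is a documented
#' function of ligand heavy-atom count plus a seeded per-pair jitter,
#' and synthetic poses are rigid translations of the input ligand to
#' uniform points inside the search box. The external engine shells out to
#' an AutoDock-Vina-compatible binary through its documented config file
#' and parses the log.
#'
#' @param receptor A [structure_model()] (mock) or receptor PDBQT path
#'   (external).
#' @param ligand A data.frame of ligand coordinates with an `element`
#'   column (mock) or ligand PDBQT path (external).
#' @param config A `docking_config`.
#' @param engine `"mock"` or `"external"`.
#' @param seed Seed for the mock engine.
#' @param receptor_id,ligand_id Identifiers mixed into the mock jitter so
#'   distinct pairs score differently but reproducibly.
#' @param vina_bin Binary name for the external engine.
#' @return A `docking_result`; mock results carry per-pose coordinates.
#' @export
run_docking <- function(receptor, ligand, config,
                        engine = c("mock", "external"), seed = 1L,
                        receptor_id = "receptor", ligand_id = "ligand",
                        vina_bin = "vina") {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "docking_config"))
  if (engine == "external") {
    return(run_docking_external(receptor, ligand, config, vina_bin))
  }
  lig <- as_coord_df(ligand)
  lig <- lig[lig$element != "H", , drop = FALSE]
  if (nrow(lig) == 0L) stopf("mock docking: ligand has no heavy atoms")
  n_heavy <- nrow(lig)
  pair_seed <- (as.integer(seed) +
                  as.integer(fnv1a(paste(receptor_id, ligand_id,
                                         sep = "|")) %% 1e6)) %% .Machine$integer.max
  with_seed(pair_seed, {
    n_modes <- min(config$num_modes, 9L)
    # documented mock score: size-dependent base + reproducible jitter
    base <- -(2 + 0.12 * n_heavy) + stats::rnorm(1, sd = 0.5)
    affinities <- sort(base + c(0, abs(stats::rnorm(n_modes - 1,
                                                    sd = config$energy_range / 3))))
    affinities <- pmin(affinities, affinities[1] + config$energy_range)
    centroid <- colMeans(as.matrix(lig[, c("x", "y", "z")]))
    # per-axis ligand extent about its centroid; shrink the sampling range
    # so every atom of a translated pose stays inside the box
    ext <- c(max(abs(lig$x - centroid[1])), max(abs(lig$y - centroid[2])),
             max(abs(lig$z - centroid[3])))
    half <- pmax(config$size / 2 - ext, 0)
    coords <- vector("list", n_modes)
    for (m in seq_len(n_modes)) {
      target <- config$center + stats::runif(3, -half, half)
      shift <- target - centroid
      pose <- lig
      pose$x <- lig$x + shift[1]; pose$y <- lig$y + shift[2]
      pose$z <- lig$z + shift[3]
      coords[[m]] <- pose
    }
    docking_result(
      poses = data.frame(mode = seq_len(n_modes), affinity = affinities,
                         rmsd_lb = c(0, stats::runif(n_modes - 1, 1, 8)),
                         rmsd_ub = c(0, stats::runif(n_modes - 1, 2, 12))),
      coords = coords
    )
  })
}

run_docking_external <- function(receptor, ligand, config, vina_bin) {
  if (!nzchar(Sys.which(vina_bin))) {
    stopf("external docking engine '%s' not found on PATH", vina_bin)
  }
  if (!file.exists(receptor) || !file.exists(ligand)) {
    stopf("receptor/ligand input file missing")
  }
  cfg <- tempfile(fileext = ".txt")
  on.exit(unlink(cfg), add = TRUE)
  write_vina_config(config, cfg, receptor = receptor, ligand = ligand)
  out <- tryCatch(
    system2(vina_bin, c("--config", cfg), stdout = TRUE, stderr = TRUE),
    error = function(e) stopf("docking engine failed: %s",
                              conditionMessage(e))
  )
  parse_docking_log(paste(out, collapse = "\n"))
}

as_coord_df <- function(x) {
  if (is.data.frame(x)) {
    if (!"element" %in% names(x)) x$element <- "C"
    x[, c("element", "x", "y", "z")]
  } else {
    m <- as.matrix(x)
    data.frame(element = "C", x = m[, 1], y = m[, 2], z = m[, 3])
  }
}

#' Parse an AutoDock-Vina-style result log
#'
#' Extracts the `mode | affinity | rmsd l.b. | rmsd u.b.` result table.
#'
#' @param text Log text (single string or character vector of lines).
#' @return A `docking_result`.
#' @export
parse_docking_log <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n")[[1]] else text
  rows <- regmatches(lines,
    regexpr("^\\s*\\d+\\s+-?\\d+(\\.\\d+)?\\s+-?\\d+(\\.\\d+)?\\s+-?\\d+(\\.\\d+)?\\s*$",
            lines))
  rows <- rows[lengths(rows) > 0 | nzchar(rows)]
  rows <- rows[nzchar(rows)]
  if (length(rows) == 0L) stopf("no docking result table found in log")
  vals <- lapply(strsplit(trimws(rows), "\\s+"), as.numeric)
  poses <- do.call(rbind, lapply(vals, function(v) {
    data.frame(mode = as.integer(v[1]), affinity = v[2], rmsd_lb = v[3],
               rmsd_ub = v[4])
  }))
  poses <- poses[order(poses$mode), , drop = FALSE]
  rownames(poses) <- NULL
  docking_result(poses)
}
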