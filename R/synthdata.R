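# Synthetic inputs for testing the whole cascade without external data:
# token-level pocket-ligand libraries with a planted binding rule, small 3D
# toy complexes for the interface/docking stages, stable vs drifting
# trajectories, Gaussian hills logs, and the packaged score-table fixtures.
# Every generator is a pure function of (spec, seed).

#' Specification for a planted-signal pocket-ligand library
#'
#' Each pocket carries a hidden key token; a ligand binds iff its sentence
#' contains the complementary key token, and the binary label equals that
#' rule with a flip probability of `(1 - signal_strength) / 2`, so
#' `signal_strength = 1` is noiseless and `signal_strength = 0` makes
#' labels independent of content.
#'
#' @param n_pockets Number of pockets (>= 2; default 20).
#' @param ligands_per_pocket Ligands generated per pocket (default 100, so
#'   the default library has 2,000 pairs).
#' @param signal_strength Planted signal in \[0, 1\] (default 0.9).
#' @param binder_rate Fraction of ligands that satisfy the binding rule
#'   (default 0.1): screening libraries contain few true actives, and the
#'   enrichment ratio is only informative in that rare-active regime.
#' @param alphabet_size Number of distinct key-token pairs (default 8).
#' @param n_filler Size of the filler-token alphabet per side (default 60).
#' @param sentence_length Tokens per ligand sentence (default 10).
#' @param seed RNG seed.
#' @return Object of class `planted_library_spec`.
#' @export
planted_library_spec <- function(n_pockets = 20L, ligands_per_pocket = 100L,
                                 signal_strength = 0.9, binder_rate = 0.1,
                                 alphabet_size = 8L,
                                 n_filler = 60L, sentence_length = 10L,
                                 seed = 1L) {
  if (n_pockets < 2L) stopf("need at least 2 pockets")
  if (signal_strength < 0 || signal_strength > 1) {
    stopf("signal_strength must lie in [0, 1]")
  }
  if (alphabet_size < 2L) stopf("alphabet_size must be >= 2")
  if (binder_rate <= 0 || binder_rate >= 1) {
    stopf("binder_rate must lie in (0, 1)")
  }
  structure(list(n_pockets = as.integer(n_pockets),
                 ligands_per_pocket = as.integer(ligands_per_pocket),
                 signal_strength = signal_strength,
                 binder_rate = binder_rate,
                 alphabet_size = as.integer(alphabet_size),
                 n_filler = as.integer(n_filler),
                 sentence_length = as.integer(sentence_length),
                 seed = as.integer(seed)),
            class = "planted_library_spec")
}

#' Generate a planted-signal pocket-ligand library
#'
#' @param spec A [planted_library_spec()].
#' @return List with `pocket_sentences` (one per pocket), `ligand_sentences`
#'   (one per pair), `pairs` (data.frame: `pocket`, `ligand`, `label`,
#'   `bind_rule` — the noiseless rule value), `pocket_keys`, and the spec.
#' @export
generate_planted_library <- function(spec) {
  stopifnot(inherits(spec, "planted_library_spec"))
  K <- spec$alphabet_size
  flip_rate <- (1 - spec$signal_strength) / 2
  with_seed(spec$seed, {
    pocket_keys <- ((seq_len(spec$n_pockets) - 1L) %% K) + 1L
    pfill <- sprintf("PF%03d", seq_len(spec$n_filler))
    lfill <- sprintf("LF%03d", seq_len(spec$n_filler))
    pocket_sentences <- lapply(seq_len(spec$n_pockets), function(i) {
      sample(c(rep(sprintf("PK%02d", pocket_keys[i]), 3L),
               sample(pfill, 7L)))
    })
    n_pairs <- spec$n_pockets * spec$ligands_per_pocket
    ligand_sentences <- vector("list", n_pairs)
    pairs <- data.frame(pocket = rep(seq_len(spec$n_pockets),
                                     each = spec$ligands_per_pocket),
                        ligand = seq_len(n_pairs), label = 0L,
                        bind_rule = 0L)
    for (p in seq_len(n_pairs)) {
      k <- pocket_keys[pairs$pocket[p]]
      binds <- stats::runif(1) < spec$binder_rate
      key_tokens <- if (binds) {
        rep(sprintf("LK%02d", k), 2L)
      } else if (stats::runif(1) < 0.7) {
        # non-binder carrying the key of a different pocket class
        rep(sprintf("LK%02d", sample(setdiff(seq_len(K), k), 1L)), 2L)
      } else {
        character(0)  # non-binder with no key token at all
      }
      filler <- sample(lfill, spec$sentence_length - length(key_tokens))
      ligand_sentences[[p]] <- sample(c(key_tokens, filler))
      pairs$bind_rule[p] <- as.integer(binds)
      pairs$label[p] <- if (stats::runif(1) < flip_rate) {
        1L - pairs$bind_rule[p]
      } else {
        pairs$bind_rule[p]
      }
    }
    list(pocket_sentences = pocket_sentences,
         ligand_sentences = ligand_sentences, pairs = pairs,
         pocket_keys = pocket_keys, spec = spec)
  })
}

#' Generate a set of 3D toy pocket-ligand complexes
#'
#' Each complex is a pseudo-receptor whose heavy atoms form a spherical
#' shell (the pocket wall) around the origin, with the cognate ligand
#' placed as a compact atom cluster inside the shell — so native interfaces
#' have many short contacts, while poses placed elsewhere in the docking
#' box have sparse, long-range contact maps.
#'
#' @param n Number of complexes.
#' @param n_shell Shell atoms per receptor (default 50).
#' @param shell_radius Mean shell radius, Angstrom (default 8).
#' @param n_ligand_range Range of ligand heavy-atom counts (default 8-14).
#' @param seed RNG seed.
#' @return List of complexes; each has `id`, `receptor`
#'   ([structure_model()]), `ligand_coords` (data.frame), `ligand_id`,
#'   `ligand_key`.
#' @export
generate_complex_set <- function(n, n_shell = 50L, shell_radius = 8,
                                 n_ligand_range = c(8L, 14L), seed = 1L) {
  if (n < 1L) stopf("need n >= 1 complexes")
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      u <- matrix(stats::rnorm(n_shell * 3), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      r <- shell_radius + stats::rnorm(n_shell, sd = 0.8)
      shell <- u * r
      elements <- sample(c("C", "N", "O", "S"), n_shell, replace = TRUE,
                         prob = c(0.6, 0.18, 0.18, 0.04))
      receptor <- structure_model(data.frame(
        element = elements, name = elements,
        resname = "PSD", resno = ceiling(seq_len(n_shell) / 3), chain = "A",
        x = shell[, 1], y = shell[, 2], z = shell[, 3],
        stringsAsFactors = FALSE))
      n_lig <- sample(seq(n_ligand_range[1], n_ligand_range[2]), 1L)
      lig_xyz <- matrix(stats::rnorm(n_lig * 3, sd = 1.2), ncol = 3)
      lig_xyz <- lig_xyz + matrix(stats::rnorm(3, sd = 0.5), nrow = n_lig,
                                  ncol = 3, byrow = TRUE)
      ligand_coords <- data.frame(
        element = sample(c("C", "N", "O"), n_lig, replace = TRUE,
                         prob = c(0.7, 0.15, 0.15)),
        x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3],
        stringsAsFactors = FALSE)
      list(id = sprintf("cpx%03d", i), receptor = receptor,
           ligand_coords = ligand_coords,
           ligand_id = sprintf("lig%03d", i),
           ligand_key = sprintf("lig%03d", i))
    })
  })
}

#' Generate a synthetic binding trajectory
#'
#' A small near-rigid pseudo-protein (20 C-alpha atoms on a helix plus one
#' donor N-H pair) with a 5-atom ligand whose acceptor oxygen sits 2.8
#' Angstrom from the donor in the reference pose (a formed hydrogen bond).
#' In a `"stable"` trajectory the ligand fluctuates isotropically about its
#' reference position; in a `"drifting"` one it additionally moves `drift`
#' Angstrom per frame in a fixed direction, so the final displacement is
#' `drift * (n_frames - 1)`. Protein atoms fluctuate at one sixth of the
#' ligand noise, so `noise = 0` reproduces the reference exactly in every
#' frame.
#'
#' @param kind `"stable"` or `"drifting"`.
#' @param n_frames Number of frames (>= 2).
#' @param noise Isotropic ligand positional noise, Angstrom (default 0.3).
#' @param drift Drift per frame, Angstrom (default 0.1; drifting only).
#' @param dt Frame spacing, ps (default 1000).
#' @param seed RNG seed.
#' @return A [trajectory()] with `ligand`, `calpha`, `donors`, `acceptors`
#'   selections.
#' @export
generate_trajectory <- function(kind = c("stable", "drifting"),
                                n_frames = 100L, noise = 0.3, drift = 0.1,
                                dt = 1000, seed = 1L) {
  kind <- match.arg(kind)
  if (n_frames < 2L) stopf("need at least 2 frames")
  t20 <- seq_len(20)
  calpha_ref <- cbind(1.5 * t20, 3 * cos(t20 * 100 * pi / 180),
                      3 * sin(t20 * 100 * pi / 180))
  n_ref <- calpha_ref[1, ] + c(0, 1.4, 0)    # donor heavy atom
  h_ref <- n_ref + c(0, 1.0, 0)              # its hydrogen
  o_ref <- n_ref + c(0, 2.8, 0)              # acceptor: linear N-H...O bond
  lig_ref <- rbind(o_ref,
                   o_ref + c(1.3, 0.5, 0.2),
                   o_ref + c(-1.2, 0.8, -0.5),
                   o_ref + c(0.4, 1.9, 0.9),
                   o_ref + c(-0.3, 1.6, -1.2))
  ref <- rbind(calpha_ref, n_ref, h_ref, lig_ref)
  n_atoms <- nrow(ref)
  lig_idx <- 23:27
  with_seed(seed, {
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    coords <- array(0, dim = c(n_frames, n_atoms, 3))
    for (f in seq_len(n_frames)) {
      frame <- ref + matrix(stats::rnorm(n_atoms * 3, sd = noise / 6),
                            ncol = 3)
      frame[lig_idx, ] <- ref[lig_idx, ] +
        matrix(stats::rnorm(length(lig_idx) * 3, sd = noise), ncol = 3)
      if (kind == "drifting") {
        frame[lig_idx, ] <- frame[lig_idx, ] +
          matrix((f - 1) * drift * dir, nrow = length(lig_idx), ncol = 3,
                 byrow = TRUE)
      }
      coords[f, , ] <- frame
    }
    trajectory(
      coords, times = (seq_len(n_frames) - 1) * dt,
      atoms = data.frame(
        element = c(rep("C", 20), "N", "H", "O", rep("C", 4)),
        name = c(rep("CA", 20), "N", "H", "O1", paste0("C", 1:4)),
        resno = c(t20, 1L, 1L, rep(21L, 5)), stringsAsFactors = FALSE),
      selections = list(ligand = lig_idx, calpha = 1:20,
                        donors = data.frame(d = 21L, h = 22L),
                        acceptors = 23L))
  })
}

#' Generate a random metadynamics hills log
#'
#' Uniform draws of center, width and height within the given ranges, one
#' hill per deposition time.
#'
#' @param n Number of hills (>= 1).
#' @param center_range,sigma_range,height_range Ranges for the uniform
#'   draws.
#' @param dt Deposition interval (time units of the log).
#' @param seed RNG seed.
#' @return A [hills_log()].
#' @export
generate_hills <- function(n, center_range = c(-2, 2),
                           sigma_range = c(0.05, 0.3),
                           height_range = c(0.1, 2), dt = 1, seed = 1L) {
  if (n < 1L) stopf("need at least 1 hill")
  with_seed(seed, {
    hills_log(data.frame(
      time = seq_len(n) * dt,
      center = stats::runif(n, center_range[1], center_range[2]),
      sigma = stats::runif(n, sigma_range[1], sigma_range[2]),
      height = stats::runif(n, height_range[1], height_range[2])))
  })
}

#' Load the packaged score-table fixtures
#'
#' Two fixed candidate score tables shipped with the package (16 and 24
#' compounds) used to exercise the cascade criteria exactly as printed.
#'
#' @return List with `table1` and `table2` data.frames
#'   (`name`, `deepbindbc`, `docking`, `dfcnn`).
#' @export
load_table_fixtures <- function() {
  p1 <- system.file("extdata", "table1_scores.csv", package = "vscascade",
                    mustWork = TRUE)
  p2 <- system.file("extdata", "table2_scores.csv", package = "vscascade",
                    mustWork = TRUE)
  list(table1 = read_score_table(p1), table2 = read_score_table(p2))
}

#' Paths and checksums of the packaged fixtures
#'
#' @return data.frame with `file`, `path`, `md5`.
#' @export
fixture_checksums <- function() {
  files <- c("table1_scores.csv", "table2_scores.csv")
  paths <- vapply(files, function(f) {
    system.file("extdata", f, package = "vscascade", mustWork = TRUE)
  }, character(1))
  data.frame(file = files, path = unname(paths),
             md5 = unname(tools::md5sum(paths)), stringsAsFactors = FALSE)
}
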