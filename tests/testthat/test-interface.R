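toy_protein <- function(df) {
  data.frame(element = df$element, name = df$element, resname = "TOY",
             resno = seq_len(nrow(df)), chain = "A",
             x = df$x, y = df$y, z = df$z, stringsAsFactors = FALSE)
}

test_that("empty interfaces give an all-pad map and single contacts one row", {
  prot <- toy_protein(data.frame(element = "C", x = 100, y = 0, z = 0))
  pose <- data.frame(element = "C", x = 0, y = 0, z = 0)
  m <- featurize_interface(prot, pose, cutoff = 10, max_rows = 16)
  expect_equal(dim(unclass(m)), c(16L, 15L))
  expect_true(all(unclass(m) == 0))

  prot2 <- toy_protein(data.frame(element = "C", x = 3, y = 0, z = 0))
  m2 <- featurize_interface(prot2, pose, cutoff = 10, max_rows = 16)
  expect_equal(sum(rowSums(abs(unclass(m2))) > 0), 1)
  expect_equal(unname(unclass(m2)[1, "dist"]), 0.3)  # 3.0 A / 10 A cutoff
  expect_equal(unname(unclass(m2)[1, "p_C"]), 1)
  expect_equal(unname(unclass(m2)[1, "l_C"]), 1)
})

test_that("contact rows equal the brute-force sorted pair list", {
  # constructed 5-contact toy
  prot <- toy_protein(data.frame(element = c("N", "C", "O"),
                                 x = c(0, 4, 8), y = 0, z = 0))
  pose <- data.frame(element = c("C", "Cl"), x = c(2, 6), y = 0, z = 0)
  m <- featurize_interface(prot, pose, cutoff = 6, max_rows = 8)
  want <- oracle_interface_rows(prot, pose, 6)
  got_d <- unclass(m)[, "dist"][rowSums(abs(unclass(m))) > 0]
  expect_equal(got_d, want$d / 6, tolerance = 1e-12)
  # element classes line up row by row (halogen grouping included)
  cls <- vscascade:::interface_element_class
  for (r in seq_len(nrow(want))) {
    expect_equal(which(unclass(m)[r, 1:7] == 1),
                 as.integer(cls(prot$element[want$i[r]])),
                 ignore_attr = TRUE)
    expect_equal(which(unclass(m)[r, 8:14] == 1),
                 as.integer(cls(pose$element[want$j[r]])),
                 ignore_attr = TRUE)
  }
})

test_that("featurization matches the all-pairs oracle on random toys", {
  withr::local_seed(31)
  for (k in 1:25) {
    np <- sample(5:40, 1); nl <- sample(2:10, 1)
    prot <- toy_protein(data.frame(
      element = sample(c("C", "N", "O", "S", "F", "Zn"), np, TRUE),
      x = runif(np, -12, 12), y = runif(np, -12, 12),
      z = runif(np, -12, 12)))
    pose <- data.frame(element = sample(c("C", "N", "O", "Br"), nl, TRUE),
                       x = runif(nl, -6, 6), y = runif(nl, -6, 6),
                       z = runif(nl, -6, 6))
    m <- featurize_interface(prot, pose, cutoff = 10, max_rows = 64)
    want <- oracle_interface_rows(prot, pose, 10)
    nonpad <- which(rowSums(abs(unclass(m))) > 0)
    if (is.null(want)) {
      expect_length(nonpad, 0)
    } else {
      expect_length(nonpad, min(nrow(want), 64))
      expect_equal(unclass(m)[nonpad, "dist"],
                   want$d[seq_along(nonpad)] / 10, tolerance = 1e-12)
    }
  }
})

test_that("maps are invariant to atom order and truncate to the closest", {
  withr::local_seed(32)
  prot <- toy_protein(data.frame(element = sample(c("C", "N", "O"), 20, TRUE),
                                 x = runif(20, -8, 8), y = runif(20, -8, 8),
                                 z = runif(20, -8, 8)))
  pose <- data.frame(element = c("C", "O", "N"), x = runif(3, -4, 4),
                     y = runif(3, -4, 4), z = runif(3, -4, 4))
  m <- featurize_interface(prot, pose, cutoff = 10, max_rows = 64)
  perm <- sample(nrow(prot)); permL <- sample(nrow(pose))
  m2 <- featurize_interface(prot[perm, ], pose[permL, ], cutoff = 10,
                            max_rows = 64)
  expect_equal(unclass(m)[, "dist"], unclass(m2)[, "dist"],
               tolerance = 1e-12)
  # truncation keeps the smallest distances
  mt <- featurize_interface(prot, pose, cutoff = 10, max_rows = 4)
  want <- oracle_interface_rows(prot, pose, 10)
  expect_equal(unclass(mt)[, "dist"], want$d[1:4] / 10, tolerance = 1e-12)
})

test_that("cross-docking decoys avoid cognate pairs and are reproducible", {
  cpx <- generate_complex_set(3, seed = 21)
  d1 <- build_cross_docking_decoys(cpx, n_per_complex = 2, seed = 9)
  expect_length(d1, 6)
  for (d in d1) {
    expect_false(identical(d$receptor_id, sub("lig", "cpx", d$ligand_id)))
    expect_identical(d$label, "decoy")
    expect_identical(d$origin, "cross_docked")
  }
  d2 <- build_cross_docking_decoys(cpx, n_per_complex = 2, seed = 9)
  expect_identical(
    lapply(d1, function(d) d[c("receptor_id", "ligand_id", "affinity")]),
    lapply(d2, function(d) d[c("receptor_id", "ligand_id", "affinity")]))
  expect_error(build_cross_docking_decoys(cpx[1], n_per_complex = 1),
               "at least 2")
})

test_that("pose classifier scores both classes and rejects one-class input", {
  cpx <- generate_complex_set(8, seed = 22)
  nat <- lapply(cpx, function(cx) {
    featurize_interface(cx$receptor, cx$ligand_coords)
  })
  dec <- build_cross_docking_decoys(cpx, n_per_complex = 1, seed = 23)
  ids <- vapply(cpx, `[[`, character(1), "id")
  dmaps <- lapply(dec, function(d) {
    featurize_interface(cpx[[match(d$receptor_id, ids)]]$receptor, d$pose)
  })
  expect_error(train_interface_classifier(nat, rep(1, length(nat))),
               "both")
  clf <- train_interface_classifier(c(nat, dmaps),
                                    c(rep(1, length(nat)),
                                      rep(0, length(dmaps))),
                                    epochs = 30, seed = 2)
  s <- predict_pose_score(clf, c(nat, dmaps))
  expect_true(all(s >= 0 & s <= 1))
  # an all-pad map still yields a valid probability
  pad <- featurize_interface(
    toy_protein(data.frame(element = "C", x = 1e3, y = 0, z = 0)),
    data.frame(element = "C", x = 0, y = 0, z = 0))
  expect_true(predict_pose_score(clf, pad) >= 0 &&
                predict_pose_score(clf, pad) <= 1)
})

test_that("permuted pose labels remove the learnable signal on average", {
  cpx <- generate_complex_set(20, seed = 24)
  nat <- lapply(cpx, function(cx) {
    featurize_interface(cx$receptor, cx$ligand_coords)
  })
  dec <- build_cross_docking_decoys(cpx, n_per_complex = 2, seed = 25)
  ids <- vapply(cpx, `[[`, character(1), "id")
  dmaps <- lapply(dec, function(d) {
    featurize_interface(cpx[[match(d$receptor_id, ids)]]$receptor, d$pose)
  })
  maps <- c(nat, dmaps)
  y <- c(rep(1, length(nat)), rep(0, length(dmaps)))
  tr <- seq_len(40); te <- setdiff(seq_along(y), tr)
  # permute ALL labels so train and test carry no association with the
  # features; the null is then exchangeable and centred at AUC 0.5
  aucs <- vapply(1:6, function(k) {
    yp <- withr::with_seed(300 + k, sample(y))
    clf <- train_interface_classifier(maps[tr], yp[tr], epochs = 30,
                                      seed = 2)
    auc_score(predict_pose_score(clf, maps[te]), yp[te])
  }, numeric(1))
  expect_gte(mean(aucs), 0.4)
  expect_lte(mean(aucs), 0.6)
})
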