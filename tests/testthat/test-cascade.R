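test_that("the packaged fixtures load verbatim with pinned checksums", {
  tabs <- load_table_fixtures()
  expect_equal(nrow(tabs$table1), 16)
  expect_equal(nrow(tabs$table2), 24)
  r <- tabs$table1[tabs$table1$name == "Sennoside_A", ]
  expect_equal(unlist(r[, -1], use.names = FALSE), c(1, -11.3, 0.9908))
  r2 <- tabs$table2[tabs$table2$name == "UM-164", ]
  expect_equal(unlist(r2[, -1], use.names = FALSE), c(0.9968, -10.9, 0.9994))
  # any edit to the shipped tables must fail here
  sums <- fixture_checksums()
  expect_equal(sums$md5[sums$file == "table1_scores.csv"],
               "4617f3f8a89c8888b5690c34fa83d8ec")
  expect_equal(sums$md5[sums$file == "table2_scores.csv"],
               "7b43c7d841d5f62d72549bacdd7b171b")
})

test_that("threshold operators are strict for scores and inclusive for docking", {
  recs <- data.frame(name = c("at_dock_bound", "at_score_bound", "inside"),
                     deepbindbc = c(0.995, 0.99, 0.999),
                     docking = c(-8.5, -9, -10),
                     dfcnn = c(0.999, 0.9985, 0.9995))
  kept <- apply_criteria(recs, cascade_criteria(0.99, -8.5, 0.998))
  # docking exactly at the bound is kept; deepbindbc exactly at it is not
  expect_setequal(kept$name, c("at_dock_bound", "inside"))
  # the fixture confirms the docking boundary behaviour
  tabs <- load_table_fixtures()
  k2 <- apply_criteria(tabs$table2, criteria_preset("list2"))
  expect_true("Dehydroandrographolide succinate" %in% k2$name)
})

test_that("exclusion lists drop candidates regardless of score", {
  tabs <- load_table_fixtures()
  k <- apply_criteria(tabs$table1,
                      criteria_preset("list1",
                                      exclude = c("Sennoside_A",
                                                  "Ponatinib")))
  expect_equal(nrow(k), 14)
  expect_false(any(c("Sennoside_A", "Ponatinib") %in% k$name))
})

test_that("apply_criteria is monotone, a subset, and idempotent", {
  withr::local_seed(51)
  recs <- data.frame(name = sprintf("m%03d", 1:120),
                     deepbindbc = runif(120), docking = runif(120, -13, -4),
                     dfcnn = runif(120))
  for (k in 1:10) {
    tight <- cascade_criteria(runif(1, 0.3, 0.9), runif(1, -11, -7),
                              runif(1, 0.3, 0.9))
    loose <- cascade_criteria(tight$min_deepbindbc - runif(1, 0, 0.3),
                              tight$max_docking + runif(1, 0, 3),
                              tight$min_dfcnn - runif(1, 0, 0.3))
    kt <- apply_criteria(recs, tight)
    kl <- apply_criteria(recs, loose)
    expect_true(all(kt$name %in% kl$name))       # loosening never shrinks
    expect_true(all(kt$name %in% recs$name))     # subset of the input
    if (nrow(kt) > 0) {
      expect_equal(apply_criteria(kt, tight)$name, kt$name)  # idempotent
    }
  }
})

test_that("ranking is stable with ties kept in input order", {
  tabs <- load_table_fixtures()
  ranked <- rank_candidates(tabs$table1, "deepbindbc")
  expect_equal(ranked$name[1:2], c("Sennoside_A", "Sennoside_B"))
  single <- rank_candidates(tabs$table1[3, ], "docking")
  expect_equal(single$name, "Dabrafenib")
  # reversing tied rows reverses their output order (stability), while a
  # strictly-keyed table sorts identically from any input order
  fwd <- rank_candidates(tabs$table2, "docking")
  rev_in <- rank_candidates(tabs$table2[rev(seq_len(24)), ], "docking")
  expect_equal(sort(fwd$docking), sort(rev_in$docking))
  expect_equal(fwd$docking, rev_in$docking)
  ties <- data.frame(name = c("a", "b", "c"), deepbindbc = c(0.5, 0.9, 0.5),
                     docking = -9, dfcnn = 0.9)
  expect_equal(rank_candidates(ties, "deepbindbc")$name, c("b", "a", "c"))
})

test_that("score tables round-trip through CSV", {
  tabs <- load_table_fixtures()
  tf <- withr::local_tempfile(fileext = ".csv")
  write_score_table(tabs$table2, tf)
  back <- read_score_table(tf)
  expect_equal(back, tabs$table2)
  bad <- data.frame(name = c("x", "x"), deepbindbc = 1, docking = -9,
                    dfcnn = 1)
  expect_error(write_score_table(bad, tf), "duplicate")
})

test_that("identical molecules always share a cluster", {
  mols <- list(molecule_record("a", "CCO"), molecule_record("b", "OCC"),
               molecule_record("c", "c1ccccc1CCCCCC"))
  cl <- cluster_candidates(mols, similarity_threshold = 0.7)
  expect_equal(cl$assignments[["a"]], cl$assignments[["b"]])
  expect_false(cl$assignments[["a"]] == cl$assignments[["c"]])
})

test_that("unrelated scaffolds split while analog series stay together", {
  series1 <- c("CCCCCCCCO", "CCCCCCCCCO", "CCCCCCCCCCO")     # fatty alcohols
  series2 <- c("c1ccc2ccccc2c1CCCC", "c1ccc2ccccc2c1CCCCC",
               "c1ccc2ccccc2c1CCCCCC")                       # alkylnaphthalenes
  series3 <- c("NC(=O)CCCCC", "NC(=O)CCCCCC", "NC(=O)CCCCCCC")  # amides
  mols <- Map(molecule_record, sprintf("m%02d", 1:9),
              c(series1, series2, series3))
  # two unrelated scaffolds at 0.7 -> distinct clusters
  two <- cluster_candidates(mols[c(1, 4)], similarity_threshold = 0.7)
  expect_equal(length(two$representatives), 2)
  cl <- cluster_candidates(mols, similarity_threshold = 0.6)
  got <- split(names(cl$assignments), cl$assignments)
  expect_equal(length(got), 3)
  expect_setequal(vapply(got, paste, character(1), collapse = ","),
                  c("m01,m02,m03", "m04,m05,m06", "m07,m08,m09"))
})

test_that("clustering partitions the input and flags unparseables", {
  mols <- list(molecule_record("a", "CCO"), molecule_record("b", "CCN"),
               molecule_record("bad", "((broken"),
               molecule_record("c", "c1ccncc1"))
  expect_warning(cl <- cluster_candidates(mols, 0.5), "excluding")
  expect_equal(cl$excluded, "bad")
  expect_length(cl$assignments, 3)
  sizes <- table(cl$assignments)
  expect_equal(sum(sizes), 3)
  # representatives follow the highest deepbindbc member when scores given
  scores <- data.frame(name = c("a", "b", "c"),
                       deepbindbc = c(0.2, 0.9, 0.5),
                       docking = -9, dfcnn = 0.9)
  suppressWarnings(cl2 <- cluster_candidates(mols, 0.5, scores = scores))
  first_cluster <- names(cl2$assignments)[cl2$assignments == 1]
  expect_equal(cl2$representatives[1],
               first_cluster[which.max(
                 scores$deepbindbc[match(first_cluster, scores$name)])])
})

test_that("candidate reports are written as CSV plus summary", {
  tabs <- load_table_fixtures()
  kept <- apply_criteria(tabs$table1, criteria_preset("list1"))
  outdir <- withr::local_tempdir()
  write_candidate_report(kept, NULL, outdir)
  expect_true(file.exists(file.path(outdir, "candidates.csv")))
  sm <- readLines(file.path(outdir, "summary.txt"))
  expect_match(sm[1], "16 candidate")
  expect_match(sm[2], "deepbindbc > 0.99")
})
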