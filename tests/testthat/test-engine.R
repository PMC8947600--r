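# MILP cut-set engine against the exhaustive oracle

test_that("toy enumerations return the golden families", {
  cm1 <- toy_network("CM1")
  g1 <- build_g_matrix(cm1$model)
  genes_only <- enumerate_cutsets(cm1$model, g1)
  expect_identical(cutset_keys(genes_only), c("g3", "g1;g2"))
  expect_true(isTRUE(attr(genes_only, "closed")))
  expect_true(all(genes_only$classification == "gMCS"))

  with_nut <- enumerate_cutsets(
    cm1$model, extend_with_nutrients(g1, cm1$model, cm1$medium)
  )
  expect_setequal(cutset_keys(with_nut), c("M1", "g3", "g1;g2"))

  cm2 <- toy_network("CM2")
  g2 <- extend_with_nutrients(build_g_matrix(cm2$model), cm2$model, cm2$medium)
  full <- enumerate_cutsets(cm2$model, g2)
  expect_setequal(cutset_keys(full), c("M1;M2", "M2;g3", "M2;g1;g2"))
  expect_true("M2;g1;g2" %in% cutset_keys(full)) # the worked 3-element ngMCS
  expect_identical(full$classification, rep("ngMCS", 3L))
  # no purely genetic cut exists when the gene-less route is fed
  expect_identical(nrow(enumerate_cutsets(cm2$model, build_g_matrix(cm2$model))), 0L)
})

test_that("shortest_cutset honours exclusions and size caps", {
  cm1 <- toy_network("CM1")
  im <- split_reversible(cm1$model)
  g <- build_g_matrix(cm1$model)
  first <- shortest_cutset(im, g)
  expect_identical(first$elements[[1]], "g3")
  second <- shortest_cutset(im, g, exclusions = list("g3"))
  expect_identical(second$elements[[1]], c("g1", "g2"))
  capped <- enumerate_cutsets(cm1$model, g,
                              opts = engine_options(max_cutset_size = 1))
  expect_identical(cutset_keys(capped), "g3")
  none <- enumerate_cutsets(cm1$model, g, opts = engine_options(max_solutions = 0))
  expect_identical(nrow(none), 0L)
})

test_that("verification flags cuts and minimality correctly", {
  cm1 <- toy_network("CM1")
  cm2 <- toy_network("CM2")
  g1 <- build_g_matrix(cm1$model)
  v <- verify_cutset(cm1$model, g1, c("g1", "g2"))
  expect_true(v$verified_cut)
  expect_true(v$verified_minimal)
  v <- verify_cutset(cm1$model, g1, c("g1", "g2", "g3"))
  expect_true(v$verified_cut)
  expect_false(v$verified_minimal)
  v <- verify_cutset(cm1$model, g1, "g1")
  expect_false(v$verified_cut)
  # the same pair is not a cut when the second medium feeds the bypass
  g2 <- extend_with_nutrients(build_g_matrix(cm2$model), cm2$model, cm2$medium)
  expect_false(verify_cutset(cm2$model, g2, c("g1", "g2"))$verified_cut)
})

test_that("brute-force oracle enumerates toy cut sets and guards itself", {
  cm1 <- toy_network("CM1")
  g1 <- build_g_matrix(cm1$model)
  b <- brute_force_cutsets(cm1$model, g1, max_size = 3)
  expect_identical(cutset_keys(b), c("g3", "g1;g2"))
  expect_identical(nrow(brute_force_cutsets(cm1$model, g1, max_size = 0)), 0L)
  cm2 <- toy_network("CM2")
  g2 <- extend_with_nutrients(build_g_matrix(cm2$model), cm2$model, cm2$medium)
  expect_setequal(cutset_keys(brute_force_cutsets(cm2$model, g2, max_size = 3)),
                  c("M1;M2", "M2;g3", "M2;g1;g2"))
  big <- g2
  for (k in 1:20) big <- dplyr::bind_rows(big, g2[1, ])
  expect_error(brute_force_cutsets(cm2$model, ngmcs:::new_g_matrix(big)), "guard")
})

test_that("MILP enumeration equals the oracle on random fixtures", {
  for (s in 1:15) {
    fx <- random_network(s)
    g <- extend_with_nutrients(build_g_matrix(fx$model), fx$model, fx$medium)
    a <- enumerate_cutsets(fx$model, g, opts = engine_options(max_solutions = 10000))
    b <- brute_force_cutsets(fx$model, g)
    expect_identical(cutset_keys(a), cutset_keys(b), info = paste("seed", s))
    expect_true(isTRUE(attr(a, "closed")))
  }
})

test_that("enumeration output is an antichain with non-decreasing sizes", {
  for (s in c(2, 7, 13)) {
    fx <- random_network(s)
    g <- extend_with_nutrients(build_g_matrix(fx$model), fx$model, fx$medium)
    res <- enumerate_cutsets(fx$model, g, opts = engine_options(max_solutions = 10000))
    expect_true(all(diff(res$size) >= 0))
    els <- res$elements
    for (i in seq_along(els)) {
      for (j in seq_along(els)) {
        if (i != j) expect_false(all(els[[i]] %in% els[[j]]))
      }
    }
    expect_true(all(res$verified_cut & res$verified_minimal))
  }
})

test_that("gene-only cut sets survive the addition of nutrient rows", {
  for (s in c(4, 9, 17)) {
    fx <- random_network(s)
    g <- build_g_matrix(fx$model)
    gn <- extend_with_nutrients(g, fx$model, fx$medium)
    gene_only <- enumerate_cutsets(fx$model, g, opts = engine_options(max_solutions = 10000))
    with_nut <- enumerate_cutsets(fx$model, gn, opts = engine_options(max_solutions = 10000))
    expect_true(all(cutset_keys(gene_only) %in% cutset_keys(with_nut)),
                info = paste("seed", s))
  }
})

test_that("cut sets found under a richer medium still cut a poorer one", {
  for (s in c(3, 8)) {
    fx <- random_network(s)
    if (nrow(fx$medium) < 2L) next
    g <- extend_with_nutrients(build_g_matrix(fx$model), fx$model, fx$medium)
    full <- enumerate_cutsets(fx$model, g, opts = engine_options(max_solutions = 10000))
    sub <- fx$medium[-nrow(fx$medium), ]
    m_sub <- apply_medium(fx$model, sub)
    for (i in seq_len(nrow(full))) {
      v <- verify_cutset(m_sub, g, full$elements[[i]])
      expect_true(v$verified_cut, info = paste("seed", s, "set", i))
    }
  }
})

test_that("cut-set tables round-trip through JSON-lines and TSV", {
  cm2 <- toy_network("CM2")
  g2 <- extend_with_nutrients(build_g_matrix(cm2$model), cm2$model, cm2$medium)
  res <- enumerate_cutsets(cm2$model, g2)
  d <- withr::local_tempdir()
  write_cutsets(res, file.path(d, "cs.jsonl"))
  back <- read_cutsets(file.path(d, "cs.jsonl"))
  expect_identical(cutset_keys(back), cutset_keys(res))
  expect_identical(back$classification, res$classification)
  write_cutsets_tsv(res, file.path(d, "cs.tsv"))
  tb <- readr::read_tsv(file.path(d, "cs.tsv"), show_col_types = FALSE)
  expect_identical(nrow(tb), nrow(res))
  expect_true(all(c("classification", "elements", "verified_cut") %in% names(tb)))
})

test_that("tidy, glance and autoplot summarise results", {
  cm2 <- toy_network("CM2")
  g2 <- extend_with_nutrients(build_g_matrix(cm2$model), cm2$model, cm2$medium)
  res <- enumerate_cutsets(cm2$model, g2)
  td <- tidy(res)
  expect_identical(td$cutset, cutset_keys(res))
  gl <- glance(res)
  expect_identical(gl$n_cutsets, 3L)
  expect_identical(gl$n_ngmcs, 3L)
  expect_true(gl$closed)
  expect_s3_class(autoplot(res), "ggplot")
})
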