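# mapping expression + medium context onto cut sets

make_cutsets <- function(...) {
  sets <- list(...)
  dplyr::bind_rows(lapply(sets, function(s) {
    ngmcs:::cutset_row(c(s$genes, s$nutrients), s$genes, s$nutrients, TRUE, TRUE)
  }))
}

test_that("a gene backed only by an absent nutrient becomes essential", {
  # folate-antagonist style pair: the gene and its rescuing nutrient
  cs <- make_cutsets(list(genes = "DHFR", nutrients = "thymidine"))
  expr <- matrix(c(25), 1, dimnames = list("DHFR", "s1"))
  np <- matrix(FALSE, 1, 1, dimnames = list("thymidine", "s1"))
  ctx <- activity_context(expr, 1, nutrient_presence = np)
  calls <- essential_elements(cs, ctx, "s1")
  expect_identical(calls$element, "DHFR")
  expect_identical(calls$kind, "gene")
  expect_identical(calls$witness[[1]][[1]], c("DHFR", "thymidine"))
  # with the nutrient present, neither element is alone active
  np[] <- TRUE
  ctx2 <- activity_context(expr, 1, nutrient_presence = np)
  expect_identical(nrow(essential_elements(cs, ctx2, "s1")), 0L)
})

test_that("the three-element narrative case calls the remaining gene", {
  cs <- make_cutsets(list(genes = c("g1", "g2"), nutrients = "M2"))
  expr <- matrix(c(8, 0.4), 2, dimnames = list(c("g1", "g2"), "s1"))
  np <- matrix(FALSE, 1, 1, dimnames = list("M2", "s1"))
  ctx <- activity_context(expr, 1, nutrient_presence = np)
  calls <- essential_elements(cs, ctx, "s1")
  expect_identical(calls$element, "g1")
  # conversely, with both genes silenced and the nutrient present, the
  # nutrient is the dependency
  expr2 <- matrix(c(0.2, 0.4), 2, dimnames = list(c("g1", "g2"), "s1"))
  np2 <- matrix(TRUE, 1, 1, dimnames = list("M2", "s1"))
  ctx2 <- activity_context(expr2, 1, nutrient_presence = np2)
  calls2 <- essential_elements(cs, ctx2, "s1")
  expect_identical(calls2$element, "M2")
  expect_identical(calls2$kind, "nutrient")
})

test_that("no call is made when several elements stay active", {
  cs <- make_cutsets(list(genes = c("g1", "g2"), nutrients = character(0)))
  expr <- matrix(c(5, 5), 2, dimnames = list(c("g1", "g2"), "s1"))
  ctx <- activity_context(expr, 1)
  expect_identical(nrow(essential_elements(cs, ctx, "s1")), 0L)
  expect_error(essential_elements(cs, ctx, "s9"), "not in the activity context")
})

test_that("nutrient dependency matrix matches a hand truth table", {
  # inositol-synthase style pair plus an unconditional nutrient pair
  cs <- make_cutsets(
    list(genes = "ISYNA1", nutrients = "myo_inositol"),
    list(genes = character(0), nutrients = c("M1", "M2"))
  )
  expr <- matrix(c(0.5, 50, 0.9), 1, dimnames = list("ISYNA1", c("s1", "s2", "s3")))
  np <- matrix(TRUE, 3, 3, dimnames = list(c("myo_inositol", "M1", "M2"),
                                           c("s1", "s2", "s3")))
  np["M2", "s3"] <- FALSE
  ctx <- activity_context(expr, 1, nutrient_presence = np)
  M <- nutrient_dependency_matrix(cs, ctx)
  truth <- matrix(0L, 3, 3, dimnames = dimnames(np))
  truth["myo_inositol", c("s1", "s3")] <- 1L # ISYNA1 below 1 TPM
  truth["M1", "s3"] <- 1L # M2 absent leaves M1 the only active element
  expect_identical(unclass(M)[rownames(truth), ], truth)
  # consistency with the per-sample rule
  for (s in colnames(expr)) {
    calls <- essential_elements(cs, ctx, s)
    nut <- calls$element[calls$kind == "nutrient"]
    expect_setequal(nut, rownames(truth)[truth[, s] == 1L])
  }
})

test_that("expression at threshold keeps the backup active", {
  cs <- make_cutsets(list(genes = "ISYNA1", nutrients = "myo_inositol"))
  for (tpm in c(0.5, 50)) {
    expr <- matrix(tpm, 1, dimnames = list("ISYNA1", "s1"))
    ctx <- activity_context(expr, 1, nutrient_presence = matrix(
      TRUE, 1, 1, dimnames = list("myo_inositol", "s1")
    ))
    M <- nutrient_dependency_matrix(cs, ctx)
    expect_identical(unname(M[1, 1]), if (tpm < 1) 1L else 0L)
  }
})

test_that("raising the threshold only adds nutrient dependencies", {
  withr::local_seed(21)
  genes <- paste0("g", 1:6)
  cs <- make_cutsets(
    list(genes = sample(genes, 2), nutrients = "N1"),
    list(genes = sample(genes, 3), nutrients = "N1"),
    list(genes = sample(genes, 1), nutrients = c("N1", "N2"))
  )
  expr <- matrix(stats::runif(18, 0, 5), 6, 3,
                 dimnames = list(genes, c("s1", "s2", "s3")))
  np <- matrix(TRUE, 2, 3, dimnames = list(c("N1", "N2"), c("s1", "s2", "s3")))
  prev <- NULL
  for (th in c(0.5, 1, 2, 5)) {
    ctx <- activity_context(expr, th, nutrient_presence = np)
    M <- nutrient_dependency_matrix(cs, ctx)
    if (!is.null(prev)) expect_true(all(M >= prev))
    prev <- M
  }
})

test_that("gene calls persist while the gene itself stays active", {
  cs <- make_cutsets(list(genes = c("gA", "gB"), nutrients = character(0)))
  expr <- matrix(c(50, 0.8), 2, dimnames = list(c("gA", "gB"), "s1"))
  for (th in c(1, 2, 10)) {
    ctx <- activity_context(expr, th)
    calls <- essential_elements(cs, ctx, "s1")
    expect_identical(calls$element, "gA") # active at every threshold tried
  }
  # once the threshold silences the witness gene too, the call vanishes
  # rather than flagging an inactive element
  ctx <- activity_context(expr, 100)
  expect_identical(nrow(essential_elements(cs, ctx, "s1")), 0L)
})

test_that("unmeasured genes are treated as active and reported", {
  cs <- make_cutsets(list(genes = c("gA", "gGhost"), nutrients = character(0)))
  expr <- matrix(0.1, 1, dimnames = list("gA", "s1"))
  ctx <- activity_context(expr, 1)
  expect_identical(unmeasured_genes(cs, ctx), "gGhost")
  calls <- essential_elements(cs, ctx, "s1")
  expect_identical(calls$element, "gGhost") # only unmeasured one active
})

test_that("the limiting gene is the strongest backup across cut sets", {
  ctx <- activity_context(
    matrix(c(0.2, 3.1, 0.4), 3, dimnames = list(c("gA", "gB", "gC"), "s1")), 1
  )
  # one cut set, two partners: the better-expressed one limits
  cs <- make_cutsets(list(genes = c("gA", "gB"), nutrients = "nut"))
  lg <- limiting_gene(cs, "nut", ctx, "s1")
  expect_identical(lg$gene, "gB")
  expect_equal(lg$tpm, 3.1)
  # two cut sets with weak partners: the maximum across sets, still
  # auxotrophic at the 1 TPM threshold
  cs2 <- make_cutsets(
    list(genes = "gA", nutrients = "nut"),
    list(genes = "gC", nutrients = "nut")
  )
  lg2 <- limiting_gene(cs2, "nut", ctx, "s1")
  expect_equal(lg2$tpm, 0.4)
  expect_identical(lg2$gene, "gC")
  # a nutrient with no genetic backup has limiting value 0
  cs3 <- make_cutsets(list(genes = character(0), nutrients = "nut"))
  lg3 <- limiting_gene(cs3, "nut", ctx, "s1")
  expect_equal(lg3$tpm, 0)
  expect_true(is.na(lg3$gene))
  expect_error(limiting_gene(cs3, "other", ctx, "s1"), "no cut set")
})

test_that("linked knockouts extend a gene's reach", {
  # rY is the gene-less alternative route; without links gX is harmless
  m <- chain_model(c(r1 = "gX"), alt_route = TRUE)
  med <- medium("N", "EX_N", 10)
  m <- apply_medium(m, med)
  plain <- apply_linked_knockouts(m, "gX")
  expect_gt(max_target_flux(plain), 0)
  linked <- apply_linked_knockouts(m, "gX", links = list(gX = "rY"))
  expect_equal(max_target_flux(linked), 0)
  expect_error(apply_linked_knockouts(m, "gX", links = list(gX = "nope")),
               "unknown reaction")
  # empty links equal a plain knockout
  expect_identical(apply_linked_knockouts(m, "gX", links = list()), plain)

  # encoding the link in the GPRs makes {gX} a size-1 cut set in the search
  g0 <- build_g_matrix(m)
  expect_false("gX" %in% cutset_keys(brute_force_cutsets(m, g0)))
  m2 <- link_gene_reactions(m, list(gX = "rY"))
  g2 <- build_g_matrix(m2)
  expect_true("gX" %in% cutset_keys(brute_force_cutsets(m2, g2)))
  expect_true("gX" %in% cutset_keys(enumerate_cutsets(m2, g2)))
})

test_that("expression files are read and validated", {
  d <- withr::local_tempdir()
  p <- file.path(d, "expr.tsv")
  readr::write_tsv(tibble::tibble(gene = c("g1", "g2"), s1 = c(1.5, 0.2),
                                  s2 = c(0, 3)), p)
  ex <- read_expression(p)
  expect_identical(rownames(ex), c("g1", "g2"))
  expect_equal(ex["g1", "s2"], 0)
  writeLines(c("gene\ts1", "g1\tnot_a_number"), p)
  expect_error(read_expression(p), "not numeric")
  expect_error(activity_context(matrix(-1, 1, 1, dimnames = list("g", "s"))),
               "non-negative")
})
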