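# model container, file formats, media, patches, irreversible split

test_that("toy fixture matches its published species counts", {
  cm1 <- toy_network("CM1")
  expect_identical(sort(cm1$model$reactions$id),
                   sort(c("r_E1", "r1", "r2", "r3", "r4", "r_BM")))
  expect_identical(sort(cm1$model$metabolites$id), sort(c("M1", "A", "B", "C")))
  expect_identical(cm1$model$genes, c("g1", "g2", "g3"))
  cm2 <- toy_network("CM2")
  expect_setequal(setdiff(cm2$model$reactions$id, cm1$model$reactions$id),
                  c("r_E2", "r5"))
  expect_setequal(setdiff(cm2$model$metabolites$id, cm1$model$metabolites$id), "M2")
})

test_that("model invariants are enforced with informative errors", {
  mets <- tibble::tibble(id = c("A", "B"))
  st <- tibble::tibble(reaction_id = "r1", metabolite_id = c("A", "B"),
                       coefficient = c(-1, 1))
  rx <- tibble::tibble(id = "r1", lower_bound = 0, upper_bound = 10, gpr_string = "")
  expect_s3_class(metabolic_model(mets, rx, st, biomass = "r1"), "metabolic_model")
  expect_error(
    metabolic_model(mets, dplyr::mutate(rx, lower_bound = 20), st, "r1"),
    "lower_bound > upper_bound"
  )
  expect_error(
    metabolic_model(mets, rx, dplyr::mutate(st, coefficient = c(0, 1)), "r1"),
    "zero stoichiometric"
  )
  expect_error(metabolic_model(mets, rx, st, biomass = "nope"), "not found")
  expect_error(
    metabolic_model(mets, dplyr::mutate(rx, gpr_string = "gZ"), st, "r1",
                    genes = "gA"),
    "absent from catalogue"
  )
})

test_that("reactions without gene association parse to TRUE and are unknockable", {
  m <- chain_model(c(r1 = ""))
  expect_true(ngmcs:::is_gpr_true(m$reactions$gpr[[match("r1", m$reactions$id)]]))
  expect_identical(nrow(build_g_matrix(m)), 0L)
})

test_that("JSON and SBML round-trips preserve the model", {
  cm2 <- toy_network("CM2")$model
  for (ext in c("json", "xml")) {
    path <- file.path(withr::local_tempdir(), paste0("m.", ext))
    write_model(cm2, path)
    m <- read_model(path)
    S0 <- stoich_matrix(cm2)
    S1 <- stoich_matrix(m)[rownames(S0), colnames(S0)]
    expect_equal(S1, S0, info = ext)
    ord <- match(cm2$reactions$id, m$reactions$id)
    expect_equal(m$reactions$lower_bound[ord], cm2$reactions$lower_bound)
    expect_equal(m$reactions$upper_bound[ord], cm2$reactions$upper_bound)
    expect_identical(m$reactions$gpr_string[ord], cm2$reactions$gpr_string)
    expect_identical(m$biomass, cm2$biomass)
    expect_identical(m$genes, cm2$genes)
  }
})

test_that("malformed or incomplete model files name the problem", {
  d <- withr::local_tempdir()
  bad <- file.path(d, "bad.json")
  writeLines("{not json", bad)
  expect_error(read_model(bad), "malformed")
  writeLines('{"metabolites": [], "reactions": []}', bad)
  expect_error(read_model(bad), "biomass")
  expect_error(read_model(file.path(d, "absent.json")), "not found")
})

test_that("patches delete reactions and edit bounds", {
  cm1 <- toy_network("CM1")$model
  cm2 <- toy_network("CM2")$model
  patched <- apply_patch(cm2, tibble::tibble(
    action = "delete", reaction_id = "r5", lower_bound = NA, upper_bound = NA
  ))
  # deleting the alternative route leaves CM1's reactions plus r_E2
  expect_setequal(patched$reactions$id, c(cm1$reactions$id, "r_E2"))
  shared <- intersect(patched$reactions$id, cm1$reactions$id)
  S1 <- stoich_matrix(patched)
  S0 <- stoich_matrix(cm1)
  expect_equal(S1[rownames(S0), shared], S0[, shared])

  expect_identical(apply_patch(cm2, tibble::tibble()), cm2)
  expect_error(apply_patch(cm2, tibble::tibble(
    action = "delete", reaction_id = "r_BM", lower_bound = NA, upper_bound = NA
  )), "biomass")
  expect_error(apply_patch(cm2, tibble::tibble(
    action = "delete", reaction_id = "nope", lower_bound = NA, upper_bound = NA
  )), "nope")
  edited <- apply_patch(cm2, tibble::tibble(
    action = "set_bounds", reaction_id = "r1", lower_bound = 0, upper_bound = 5
  ))
  expect_equal(edited$reactions$upper_bound[edited$reactions$id == "r1"], 5)
})

test_that("input exchanges are single-metabolite importers", {
  expect_identical(find_input_exchanges(toy_network("CM1")$model), "r_E1")
  expect_identical(find_input_exchanges(toy_network("CM2")$model),
                   c("r_E1", "r_E2"))
  # a model with no boundary reactions has none
  mets <- tibble::tibble(id = c("A", "B"))
  rx <- tibble::tibble(id = c("r1", "r2"), lower_bound = 0, upper_bound = 10,
                       gpr_string = "")
  st <- tibble::tibble(reaction_id = c("r1", "r1", "r2", "r2"),
                       metabolite_id = c("A", "B", "B", "A"),
                       coefficient = c(-1, 1, -1, 1))
  m <- metabolic_model(mets, rx, st, biomass = "r1")
  expect_length(find_input_exchanges(m), 0L)
})

test_that("applying a medium closes unlisted imports and is idempotent", {
  cm2 <- toy_network("CM2")$model
  m1_only <- apply_medium(cm2, medium("M1", "r_E1", 10))
  expect_equal(
    m1_only$reactions$lower_bound[m1_only$reactions$id == "r_E2"], 0
  )
  # behaves like CM1: the gene pair is lethal again
  expect_true(is_blocked(m1_only, knocked_reactions = disabled_reactions(
    m1_only, genes = c("g1", "g2")
  )))
  both <- apply_medium(cm2, toy_network("CM2")$medium)
  expect_false(is_blocked(both, knocked_reactions = disabled_reactions(
    both, genes = c("g1", "g2")
  )))
  # idempotent
  expect_identical(apply_medium(m1_only, medium("M1", "r_E1", 10)), m1_only)
  # empty medium starves the cell
  starved <- apply_medium(cm2, medium(character(0), character(0)))
  expect_equal(max_target_flux(starved), 0)
  expect_error(apply_medium(cm2, medium("MX", "r_nope", 1)), "not an exchange")
  expect_error(apply_medium(cm2, medium("M2", "r_E1", 1)), "different metabolite")
})

test_that("fewer nutrients never increase growth (medium monotonicity)", {
  withr::local_seed(11)
  for (s in 1:8) {
    fx <- random_network(s)
    med <- fx$medium
    if (nrow(med) < 2L) next
    sub <- med[-nrow(med), ]
    m_full <- fx$model
    m_sub <- apply_medium(fx$model, sub)
    for (k in 1:3) {
      ko_genes <- sample(m_full$genes, sample(0:2, 1))
      ko <- disabled_reactions(m_full, genes = ko_genes)
      expect_lte(max_target_flux(m_sub, knocked_reactions = ko),
                 max_target_flux(m_full, knocked_reactions = ko) + 1e-9)
    }
  }
})

test_that("reversible splitting preserves flux optima", {
  # one reversible reaction becomes a forward/backward pair
  mets <- tibble::tibble(id = c("A", "B"), compartment = "c")
  rx <- tibble::tibble(id = c("EX_A", "rAB", "r_BM"),
                       lower_bound = c(-10, -1000, 0), upper_bound = 1000,
                       gpr_string = "")
  st <- tibble::tibble(
    reaction_id = c("EX_A", "rAB", "rAB", "r_BM"),
    metabolite_id = c("A", "A", "B", "B"),
    coefficient = c(-1, -1, 1, -1)
  )
  m <- metabolic_model(mets, rx, st, biomass = "r_BM")
  im <- split_reversible(m)
  expect_true(all(im$reactions$lower_bound >= 0))
  expect_identical(
    im$reversible_map$backward_id[im$reversible_map$original_id == "rAB"],
    "rAB_rev"
  )
  # swapped stoichiometry on the backward copy
  s_back <- im$stoichiometry[im$stoichiometry$reaction_id == "rAB_rev", ]
  expect_equal(s_back$coefficient[s_back$metabolite_id == "A"], 1)

  # an already irreversible model is unchanged apart from bookkeeping
  cm1 <- toy_network("CM1")$model
  cm1_irr <- apply_medium(cm1, toy_network("CM1")$medium)
  # note the exchange is reversible (uptake is negative flux), so only
  # fully forward models pass through untouched
  fwd <- chain_model(c(r1 = "gX"))
  fwd$reactions$lower_bound[fwd$reactions$id == "EX_N"] <- 0
  fwd$reactions$upper_bound[fwd$reactions$id == "EX_N"] <- 0
  im2 <- split_reversible(fwd)
  expect_identical(im2$reactions$id, fwd$reactions$id)

  # LP equivalence on random fixtures, with and without knockouts
  withr::local_seed(5)
  for (s in 1:20) {
    fx <- random_network(s)
    im <- split_reversible(fx$model)
    expect_equal(max_target_flux(im), max_target_flux(fx$model), tolerance = 1e-6)
    ko_genes <- sample(fx$model$genes, 2)
    ko <- disabled_reactions(fx$model, genes = ko_genes)
    expect_equal(max_target_flux(im, knocked_reactions = ko),
                 max_target_flux(fx$model, knocked_reactions = ko),
                 tolerance = 1e-6)
  }
})
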