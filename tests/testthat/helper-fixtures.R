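# shared helpers: random GPR rules and tiny hand-built models

# random AND/OR rule text over a gene pool; depth-limited
random_gpr_rule <- function(genes, depth = 3) {
  build <- function(d) {
    if (d == 0 || stats::runif(1) < 0.35) return(sample(genes, 1))
    op <- sample(c(" and ", " or "), 1)
    k <- sample(2:3, 1)
    parts <- vapply(seq_len(k), function(i) build(d - 1), character(1))
    paste0("(", paste(parts, collapse = op), ")")
  }
  build(depth)
}

# linear chain model: N -> A -> biomass, with per-reaction GPRs; the
# second argument optionally adds a parallel gene-less route N -> A
chain_model <- function(gprs = c(r1 = "gX"), alt_route = FALSE) {
  mets <- tibble::tibble(id = c("N", "A"), compartment = c("e", "c"))
  rxns <- tibble::tibble(
    id = c("EX_N", names(gprs), "r_BM"),
    lower_bound = c(-10, rep(0, length(gprs)), 0),
    upper_bound = 1000,
    gpr_string = c("", unname(gprs), "")
  )
  st <- dplyr::bind_rows(
    tibble::tibble(reaction_id = "EX_N", metabolite_id = "N", coefficient = -1),
    dplyr::bind_rows(lapply(names(gprs), function(r) {
      tibble::tibble(reaction_id = r, metabolite_id = c("N", "A"),
                     coefficient = c(-1, 1))
    })),
    tibble::tibble(reaction_id = "r_BM", metabolite_id = "A", coefficient = -1)
  )
  if (alt_route) {
    rxns <- dplyr::bind_rows(rxns, tibble::tibble(
      id = "rY", lower_bound = 0, upper_bound = 1000, gpr_string = ""
    ))
    st <- dplyr::bind_rows(st, tibble::tibble(
      reaction_id = "rY", metabolite_id = c("N", "A"), coefficient = c(-1, 1)
    ))
  }
  metabolic_model(mets, rxns, st, biomass = "r_BM")
}

toy_medium_cm1 <- function() medium("M1", "r_E1", 10)

expect_same_set_family <- function(a, b) {
  expect_identical(sort(cutset_keys(a)), sort(cutset_keys(b)))
}
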