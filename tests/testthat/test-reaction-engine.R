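test_that("the three-species toy displacement enumerates a single reaction", {
  duplex <- "{T^*} [x y]"
  invader <- "<T^ x y>"
  rx <- enumerate_reactions(c(duplex, invader))
  expect_equal(nrow(rx), 1L)
  expect_setequal(rx$reactants[[1L]], c(duplex, invader))
  expect_true("<x y>" %in% rx$products[[1L]])       # incumbent fully replaced
  expect_true("[T^ x y]" %in% rx$products[[1L]])    # saturated waste duplex
})

test_that("an empty pool yields an empty reaction list", {
  rx <- enumerate_reactions(character())
  expect_equal(nrow(rx), 0L)
})

test_that("closure of the NOT module plus a t input matches the hand enumeration", {
  g <- make_logic_gate("NOT", "m", "n")
  inp <- render_species(signal_strand("x", "t", "m", "t"))
  net <- close_crn(dplyr::bind_rows(gate_species(g)[, c("species", "conc_nM")],
                                    tibble::tibble(species = inp, conc_nM = 1e4)))
  # initial 3 species + the invaded waste complex + the released f output
  expect_equal(nrow(net$species), 5L)
  expect_equal(nrow(net$reactions), 2L)   # the exchange and its reverse
  expect_true("<mL^ t mR^ T^ nL^ f nR^>" %in% net$species$species)
  # the untouched f gate supports no reaction
  f_gate <- "{T^*} [mL^ f mR^ T^] <nL^ t nR^>"
  expect_false(any(purrr::map_lgl(net$reactions$reactants, ~ f_gate %in% .x)))
})

test_that("closure is idempotent and independent of pool order", {
  g <- make_amplification_gate("m", "n")
  inp <- render_species(signal_strand("u", "t", "m", "t"))
  pool <- dplyr::bind_rows(gate_species(g)[, c("species", "conc_nM")],
                           tibble::tibble(species = inp, conc_nM = 1e4))
  net1 <- close_crn(pool)
  # re-closing the closed species set reproduces the same CRN
  net2 <- close_crn(net1$species[, c("species", "conc_nM")])
  expect_setequal(net2$species$species, net1$species$species)
  expect_setequal(net2$reactions$id, net1$reactions$id)
  # order independence
  set.seed(5)
  for (i in 1:3) {
    net3 <- close_crn(pool[sample(nrow(pool)), ])
    expect_setequal(net3$species$species, net1$species$species)
    expect_setequal(net3$reactions$id, net1$reactions$id)
  }
})

test_that("every enumerated reaction conserves the physical strand multiset", {
  res <- run_adder(1, 0, 0)
  net <- res$crn
  for (i in seq_len(nrow(net$reactions))) {
    lhs <- sort(unlist(purrr::map(net$reactions$reactants[[i]], species_strands)))
    rhs <- sort(unlist(purrr::map(net$reactions$products[[i]], species_strands)))
    expect_identical(lhs, rhs)
  }
})

test_that("conservation laws annihilate the stoichiometry matrix", {
  net <- run_adder(1, 0, 0)$crn
  L <- conserved_moieties(net)
  expect_gt(ncol(L), 0L)
  S <- as.matrix(dsdlogic:::crn_indices(net)$S)
  expect_lt(max(abs(t(L) %*% S)), 1e-8)
})

test_that("only free single strands invade: no complex-complex reactions", {
  net <- run_adder(1, 1, 0)$crn
  free <- net$species$free
  names(free) <- net$species$species
  for (r in net$reactions$reactants) {
    expect_equal(sum(free[r]), 1L)   # exactly one free strand per reaction
  }
})

test_that("the catalytic amplifier closure regenerates its input strand", {
  g <- make_amplification_gate("m", "n")
  inp <- render_species(signal_strand("u", "t", "m", "t"))
  net <- close_crn(dplyr::bind_rows(gate_species(g)[, c("species", "conc_nM")],
                                    tibble::tibble(species = inp, conc_nM = 1e3)))
  regenerating <- purrr::map_lgl(seq_len(nrow(net$reactions)), function(i) {
    inp %in% net$reactions$products[[i]] && !(inp %in% net$reactions$reactants[[i]])
  })
  expect_true(any(regenerating))
})

test_that("detailed mode expands each step into bind/unbind/migrate", {
  g <- make_logic_gate("NOT", "m", "n")
  inp <- render_species(signal_strand("x", "t", "m", "t"))
  pool <- dplyr::bind_rows(gate_species(g)[, c("species", "conc_nM")],
                           tibble::tibble(species = inp, conc_nM = 1e4))
  lumped <- close_crn(pool)
  det <- close_crn(pool, rates = dsd_rates("detailed"))
  expect_setequal(unique(det$reactions$kind),
                  c("toehold_binding", "toehold_unbinding", "displacement"))
  expect_equal(nrow(det$reactions), 3L * nrow(lumped$reactions))
  # with a reporter draining the output, detailed kinetics still invert the
  # signal end to end
  rep <- make_reporter_gate("n")
  pool2 <- dplyr::bind_rows(pool, gate_species(rep)[, c("species", "conc_nM")])
  det2 <- close_crn(pool2, rates = dsd_rates("detailed"))
  traj <- simulate_crn(det2, t_end = 1e4)
  expect_gt(readout(traj, rep$meta$fluor[["f"]])$value, 0.9)
  expect_false(rep$meta$fluor[["t"]] %in% traj$species)
})

test_that("reaction-list and SBML exports are well-formed and deterministic", {
  g <- make_logic_gate("NOT", "m", "n")
  inp <- render_species(signal_strand("x", "t", "m", "t"))
  net <- close_crn(dplyr::bind_rows(gate_species(g)[, c("species", "conc_nM")],
                                    tibble::tibble(species = inp, conc_nM = 1e4)))
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_reaction_list(net, p1); write_reaction_list(net, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_true(all(grepl("->.*@", readLines(p1))))

  sb <- withr::local_tempfile(fileext = ".sbml")
  write_sbml(net, sb)
  doc <- xml2::read_xml(sb)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  expect_equal(length(xml2::xml_find_all(doc, ".//s:species", ns)),
               nrow(net$species))
  expect_equal(length(xml2::xml_find_all(doc, ".//s:reaction", ns)),
               nrow(net$reactions))
})

test_that("the closure species cap reports unbounded-looking systems", {
  g <- make_logic_gate("NOT", "m", "n")
  inp <- render_species(signal_strand("x", "t", "m", "t"))
  pool <- dplyr::bind_rows(gate_species(g)[, c("species", "conc_nM")],
                           tibble::tibble(species = inp, conc_nM = 1e4))
  expect_error(close_crn(pool, max_species = 3L), "species cap")
})
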