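test_that("a K-input mapping module expands to 2^K gate species", {
  for (K in 1:3) {
    tab <- enumerate_mapping_modules(K)$table[[2L]]
    g <- make_mapping_module(K, tab, paste0("p", seq_len(K)), "o")
    expect_equal(nrow(gate_species(g)), 2^K)
    expect_setequal(gate_species(g)$role, paste0("gate_", label_patterns(K)))
  }
  # constant-f table: every gate species carries the f output label
  g <- make_mapping_module(2, c(ff = "f", ft = "f", tf = "f", tt = "f"),
                           c("m", "n"), "h")
  expect_true(all(grepl("<hL\\^ f hR\\^>$", gate_species(g)$species)))
})

test_that("the NOT module matches the inverting 1-input listing", {
  g <- make_logic_gate("NOT", "m", "n")
  expect_setequal(gate_species(g)$species,
                  c("{T^*} [mL^ f mR^ T^] <nL^ t nR^>",
                    "{T^*} [mL^ t mR^ T^] <nL^ f nR^>"))
})

test_that("named gate tables implement AND, OR and XOR", {
  expect_equal(unname(logic_table("AND")[c("tt", "tf")]), c("t", "f"))
  expect_equal(unname(logic_table("OR")[c("ff", "ft")]), c("f", "t"))
  expect_equal(unname(logic_table("XOR")[c("tt", "ft", "tf", "ff")]),
               c("f", "t", "t", "f"))
})

test_that("module enumeration matches the brute-force map count", {
  expect_equal(nrow(enumerate_mapping_modules(1)), 4L)
  expect_equal(nrow(enumerate_mapping_modules(2)), 16L)
  k3 <- enumerate_mapping_modules(3)
  # oracle: enumerate all maps {f,t}^3 -> {f,t} directly
  brute <- expand.grid(rep(list(c("f", "t")), 8L), stringsAsFactors = FALSE)
  expect_equal(nrow(k3), nrow(unique(brute)))
  expect_equal(anyDuplicated(k3$bits), 0L)
})

test_that("gate constructors reject malformed arguments", {
  expect_error(make_mapping_module(2, c(ff = "f"), c("m", "n"), "h"), "partial")
  expect_error(make_mapping_module(2, logic_table("AND"), c("m", "m"), "h"),
               "duplicate")
  expect_error(make_amplification_gate("m", "n", target_concentration = -1),
               "positive")
  expect_error(make_fanout_gate(1, "m", "n"), "at least 2")
  expect_error(make_logic_gate("NAND", c("a", "b"), "c"), "unknown")
})

test_that("amplifier species and concentrations follow the 2x fuel rule", {
  g <- make_amplification_gate("m", "n")
  tbl <- gate_species(g)
  expect_equal(nrow(tbl), 4L)
  expect_equal(sort(tbl$conc_nM[grepl("gate", tbl$role)]), c(10000, 10000))
  expect_equal(sort(tbl$conc_nM[grepl("fuel", tbl$role)]), c(20000, 20000))
})

test_that("the amplifier's label channels are disjoint", {
  g <- make_amplification_gate("m", "n")
  inp <- render_species(signal_strand("u", "f", "m", "f"))
  net <- close_crn(dplyr::bind_rows(gate_species(g)[, c("species", "conc_nM")],
                                    tibble::tibble(species = inp, conc_nM = 1e4)))
  t_out <- "<mL^ t mR^ T^ nL^ t nR^>"
  expect_false(t_out %in% net$species$species)
  expect_true("<mL^ f mR^ T^ nL^ f nR^>" %in% net$species$species)
})

test_that("amplifier output settles at gate concentration for any input amplitude", {
  g <- make_amplification_gate("m", "n")
  rep <- make_reporter_gate("n")
  for (amp_in in c(0.1, 1)) {
    inp <- render_species(signal_strand("u", "t", "m", "t"))
    pool <- dplyr::bind_rows(gate_species(g)[, c("species", "conc_nM")],
                             gate_species(rep)[, c("species", "conc_nM")],
                             tibble::tibble(species = inp, conc_nM = amp_in * 1e4))
    traj <- simulate_crn(close_crn(pool), t_end = 2e4)
    out <- readout(traj, rep$meta$fluor[["t"]])$value
    expect_gt(out, 0.95)
    expect_lt(out, 1.001)
  }
})

test_that("the 2-fan-out is the eight-species system of the reference figure", {
  g2 <- make_fanout_gate(2, "m", c("n1", "n2"))
  tbl <- gate_species(g2)
  # four gate doubles and two fuels; with the two possible input strands the
  # figure's eight species are on the table
  expect_equal(nrow(tbl), 6L)
  expect_equal(sum(grepl("^gate", tbl$role)), 4L)
  expect_equal(sum(grepl("^fuel", tbl$role)), 2L)
  expect_equal(unique(tbl$conc_nM[grepl("^fuel", tbl$role)]), 2e4)
  inputs <- c(render_species(signal_strand("u", "f", "m", "f")),
              render_species(signal_strand("u", "t", "m", "t")))
  expect_equal(length(c(tbl$species, inputs)), 8L)
  # fuels scale with the fan-out degree
  g9 <- gate_species(make_fanout_gate(9, "m", paste0("n", 1:9)))
  expect_equal(unique(g9$conc_nM[grepl("^fuel", g9$role)]), 9e4)
  expect_equal(sum(grepl("^gate", g9$role)), 18L)
})

test_that("an f input fans out to f-labelled copies on every port, catalytically", {
  g <- make_fanout_gate(2, "m", c("n1", "n2"))
  reps <- list(make_reporter_gate("n1"), make_reporter_gate("n2"))
  inp <- render_species(signal_strand("u", "f", "m", "f"))
  pool <- dplyr::bind_rows(gate_species(g)[, c("species", "conc_nM")],
                           purrr::map_dfr(reps, ~ gate_species(.x)[, c("species", "conc_nM")]),
                           tibble::tibble(species = inp, conc_nM = 1e4))
  net <- close_crn(pool)
  expect_true(all(c("<mL^ f mR^ T^ n1L^ f n1R^>",
                    "<mL^ f mR^ T^ n2L^ f n2R^>") %in% net$species$species))
  # catalysis: some reaction regenerates the input strand
  expect_true(any(purrr::map_lgl(net$reactions$products, ~ inp %in% .x)))
  traj <- simulate_crn(net, t_end = 1e4)
  outs <- readout(traj, purrr::map_chr(reps, ~ .x$meta$fluor[["f"]]))
  expect_true(all(outs$value > 0.95))
  # the t channel never fires
  expect_false(any(purrr::map_chr(reps, ~ .x$meta$fluor[["t"]]) %in% net$species$species))
})

test_that("reporter fluorophores are terminal: never consumed by any reaction", {
  rep <- make_reporter_gate("q")
  inp <- render_species(signal_strand("u", "t", "q", "t"))
  net <- close_crn(dplyr::bind_rows(gate_species(rep)[, c("species", "conc_nM")],
                                    tibble::tibble(species = inp, conc_nM = 1e4)))
  fluors <- fluorophore_species(net)
  expect_gt(length(fluors), 0L)
  consumed <- unlist(net$reactions$reactants)
  expect_false(any(fluors %in% consumed))
})

test_that("mapping modules reproduce their tables through the full ODE path", {
  # spot checks at K = 3 (K <= 2 is covered exhaustively elsewhere)
  parity <- dsdlogic:::parity_table(3L)
  for (pat in c("ttt", "tft", "fff")) {
    expect_equal(simulate_module_pattern(3L, parity, pat),
                 as.integer(sum(strsplit(pat, "")[[1L]] == "t") %% 2L))
  }
})
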