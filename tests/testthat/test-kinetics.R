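test_that("a single bimolecular reaction follows the closed-form solution", {
  k <- 3e-5; c0 <- 1e4
  toy <- crn(tibble::tibble(species = c("A", "B", "C"), conc_nM = c(c0, c0, 0)),
             tibble::tibble(reactants = list(c("A", "B")), products = list("C"),
                            rate = k))
  traj <- simulate_crn(toy, t_end = 500)
  exact <- k * c0^2 * traj$times / (1 + k * c0 * traj$times)
  expect_lt(max(abs(traj$conc[, "C"] - exact)) / c0, 1e-6)
})

test_that("a reporter driven by one unit of t signal approaches one unit of fluorophore", {
  rep <- make_reporter_gate("q")
  inp <- render_species(signal_strand("u", "t", "q", "t"))
  net <- close_crn(dplyr::bind_rows(gate_species(rep)[, c("species", "conc_nM")],
                                    tibble::tibble(species = inp, conc_nM = 1e4)))
  traj <- simulate_crn(net, t_end = 1e4)
  fl_t <- rep$meta$fluor[["t"]]
  expect_equal(readout(traj, fl_t, t = 0)$value, 0)
  final <- readout(traj, fl_t)$value
  expect_gt(final, 0.95); expect_lt(final, 1.0001)
  # the other channel never fires
  expect_false(rep$meta$fluor[["f"]] %in% traj$species)
})

test_that("fluorophore trajectories are monotone non-decreasing", {
  res <- run_adder(1, 1, 0)
  traj <- res$trajectory
  for (s in fluorophore_species(traj)) {
    expect_gte(min(diff(traj$conc[, s])), -1e-4)   # within solver tolerance
  }
})

test_that("halving solver tolerances leaves final readouts unchanged to 1e-4 units", {
  res <- run_adder(1, 0, 0)
  fl <- fluorophore_species(res$trajectory)
  tight <- simulate_crn(res$crn, t_end = 1e4, rtol = 5e-9, atol = 5e-7)
  delta <- max(abs(readout(res$trajectory, fl)$value - readout(tight, fl)$value))
  expect_lt(delta, 1e-4)
})

test_that("conserved totals stay flat over a full circuit run", {
  res <- run_adder(0, 1, 0)
  expect_lt(conservation_drift(res$trajectory), 1e-6)
})

test_that("concentrations stay non-negative everywhere", {
  res <- run_adder(1, 1, 1)
  expect_gte(min(res$trajectory$conc), -1e-6)
})

test_that("readout validates species and time", {
  res <- run_adder(1, 0, 0)
  expect_error(readout(res$trajectory, "<no such>"), "unknown species")
  expect_error(readout(res$trajectory, fluorophore_species(res$trajectory)[1],
                       t = 1e6), "outside")
})

test_that("settledness is a derivative criterion", {
  res <- run_adder(1, 0, 0)
  expect_true(is_settled(res$trajectory))
  early <- simulate_crn(res$crn, t_end = 5)
  expect_false(is_settled(early))
})
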