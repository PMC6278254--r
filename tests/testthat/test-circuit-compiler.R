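test_that("the single-rail reference adder has 6 AND, 3 OR, 4 NOT in 6 layers", {
  nl <- single_rail_full_adder_netlist()
  expect_equal(sum(nl$logic == "AND"), 6L)
  expect_equal(sum(nl$logic == "OR"), 3L)
  expect_equal(sum(nl$logic == "NOT"), 4L)
  expect_equal(netlist_layers(nl), 6L)
  # and it adds correctly, e.g. 1 + 1 + 1 = 11
  v <- eval_netlist(nl, c(a = 1L, b = 1L, c = 1L))
  expect_equal(c(v$sum, v$carry), c(1L, 1L))
  for (a in 0:1) for (b in 0:1) for (ci in 0:1) {
    v <- eval_netlist(nl, c(a = a, b = b, c = ci))
    expect_equal(v$carry * 2L + v$sum, a + b + ci)
  }
})

test_that("the full-adder netlist twin matches binary arithmetic exhaustively", {
  fa <- adder_circuit()
  for (a in 0:1) for (b in 0:1) for (ci in 0:1) {
    o <- boolean_oracle(fa, adder_inputs(a, b, ci))
    expect_equal(unname(o[["S1"]] * 2L + o[["S0"]]), a + b + ci)
  }
})

test_that("the multiplier netlist twin equals the integer product for all 256 pairs", {
  m <- multiplier_circuit()
  for (a in 0:15) for (b in 0:15) {
    w <- dsdlogic:::oracle_word(m, multiplier_inputs(a, b))
    expect_equal(strtoi(w, base = 2L), a * b)
  }
})

test_that("the adder/subtractor netlist twin tracks modular arithmetic", {
  s <- addsub_circuit()
  expect_equal(dsdlogic:::oracle_word(s, addsub_inputs("00101101", "10010110", 1L)),
               "010010111")
  set.seed(11)
  for (i in 1:50) {
    a <- sample(0:255, 1L); b <- sample(0:255, 1L); sw <- sample(0:1, 1L)
    total <- if (sw == 1L) a + 256L - b else a + b
    expected <- paste(c(total %/% 256L,
                        rev(as.integer(intToBits(total %% 256L))[1:8])),
                      collapse = "")
    expect_equal(dsdlogic:::oracle_word(s, addsub_inputs(a, b, sw)), expected)
  }
})

test_that("compiled circuits carry the stated gate inventory", {
  fa <- adder_circuit()
  expect_equal(count_gates(fa, kind = "mapping"), 2L)
  expect_equal(count_gates(fa, kind = "fanout"), 3L)
  expect_equal(count_gates(fa, kind = "amplification"), 2L)

  m <- multiplier_circuit()
  expect_equal(count_gates(m, logic = "AND", stage = "partial_product"), 16L)

  s <- addsub_circuit()
  expect_equal(count_gates(s, kind = "amplification"), 24L)
  expect_equal(count_gates(s, logic = "XOR"), 8L)
  expect_equal(count_gates(s, kind = "fanout", N = 9L), 1L)
  expect_equal(count_gates(s, kind = "reporter"), 9L)
  expect_equal(sum(s$inputs$group %in% c("A", "B")), 16L)
})

test_that("operand encoding emits the reference input strands verbatim", {
  s <- addsub_circuit()
  enc <- encode_inputs(s, addsub_inputs("00101101", "10010110", 1L))
  expect_equal(enc$species[enc$name == "A0"], "<S2L^ t S2R^ T^ S2L^ t S2R^>")
  expect_equal(enc$species[enc$name == "A7"], "<S9L^ f S9R^ T^ S9L^ f S9R^>")
  expect_equal(enc$species[enc$name == "B0"], "<S10L^ f S10R^ T^ S10L^ f S10R^>")
  expect_equal(enc$species[enc$name == "B7"], "<S17L^ t S17R^ T^ S17L^ t S17R^>")
  expect_equal(enc$species[enc$name == "A#S"], "<S0L^ t S0R^ T^ S0L^ t S0R^>")
  expect_true(all(enc$conc_nM == 1e4))
  # all-zero word encodes all-f labels
  enc0 <- encode_inputs(s, addsub_inputs(0L, 0L, 0L))
  expect_true(all(grepl(" f ", enc0$species)))
  m <- multiplier_circuit()
  encm <- encode_inputs(m, multiplier_inputs("1111", "1111"))
  expect_true("<A0L^ t A0R^ T^ A0L^ t A0R^>" %in% encm$species)
  expect_error(encode_inputs(s, addsub_inputs(0L, 0L)[-1L]), "missing input")
})

test_that("two's-complement subtraction reproduces the worked arithmetic", {
  r <- twos_complement_sub(77, 150, 8)
  expect_equal(r$value, 183)
  expect_equal(r$word, "010110111")
  expect_equal(r$carry_out, 0L)
  expect_equal(twos_complement_sub(42, 42, 8)$value, 0)
  set.seed(3)
  for (i in 1:25) {
    a <- sample(0:255, 1L); b <- sample(0:255, 1L)
    expect_equal(twos_complement_sub(a, b, 8)$value, (a - b) %% 256)
  }
  expect_error(twos_complement_sub(300, 1, 8), "out of range")
})

test_that("word helpers invert each other", {
  expect_equal(unname(word_bits("1011", "A", 4L)), c(1L, 1L, 0L, 1L))
  expect_equal(bits_value(word_bits(173, "A", 8L)), 173)
  expect_error(word_bits("10", "A", 4L), "4 bits")
})

test_that("decoding flags mid-band readouts as ambiguous, never coercing them", {
  rep_gate <- make_reporter_gate("q")
  fake_traj <- structure(list(
    times = c(0, 1),
    conc = matrix(rep(c(0.97, 0.02, 1, 1) * 1e4, each = 2L), nrow = 2L,
                  dimnames = list(NULL, c(rep_gate$meta$fluor[["t"]],
                                          rep_gate$meta$fluor[["f"]],
                                          rep_gate$species$species))),
    species = c(rep_gate$meta$fluor[["t"]], rep_gate$meta$fluor[["f"]],
                rep_gate$species$species),
    unit_nM = 1e4, final_deriv = numeric(4L)
  ), class = "dsd_trajectory")
  fake_circuit <- structure(
    list(reporters = dsdlogic:::reporter_row(rep_gate, "S0", 0L)),
    class = "dsd_circuit")
  d <- decode_outputs(fake_traj, fake_circuit)
  expect_equal(d$bit, 1L)
  # (0.5, 0.5): between the bands
  fake_traj$conc[, 1:2] <- 0.5 * 1e4
  d <- decode_outputs(fake_traj, fake_circuit)
  expect_true(is.na(d$bit))
  expect_equal(d$status, "ambiguous")
  # mirrored case decodes 0
  fake_traj$conc[, 1L] <- 0.03 * 1e4; fake_traj$conc[, 2L] <- 0.95 * 1e4
  expect_equal(decode_outputs(fake_traj, fake_circuit)$bit, 0L)
})

test_that("netlist evaluation detects combinational cycles", {
  nl <- tibble::tibble(
    gate_id = c("g1", "g2"), type = "prim", logic = "NOT",
    K = 1L, N = NA_integer_, stage = NA_character_,
    inputs = list("x", "y"), outputs = list("y", "x"), table = list(NULL)
  )
  expect_error(eval_netlist(nl, c()), "combinational cycle")
})

test_that("strand-level simulation agrees with the netlist twin on the 1-bit adder", {
  res <- run_adder(1, 0, 0)
  expect_equal(res$word, "01")
  expect_equal(res$word, dsdlogic:::oracle_word(adder_circuit(), adder_inputs(1, 0, 0)))
  expect_true(res$settled)
  expect_equal(sum(res$decoded$status == "ambiguous"), 0L)
})
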