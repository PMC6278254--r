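# ---------------------------------------------------------------------------
# Circuit compiler: assembles cascades of domain-label gates, wires them by
# shared port (domain-pair) names, and keeps a logic-level netlist twin of
# every gate for oracle evaluation.
# ---------------------------------------------------------------------------

parity_table <- function(K) {
  pats <- label_patterns(K)
  out <- ifelse(vapply(strsplit(pats, ""), function(x) sum(x == "t") %% 2L, 1L) == 1L,
                "t", "f")
  names(out) <- pats
  out
}

majority_table <- function(K) {
  pats <- label_patterns(K)
  out <- ifelse(vapply(strsplit(pats, ""), function(x) sum(x == "t"), 1L) > K / 2,
                "t", "f")
  names(out) <- pats
  out
}

cb_new <- function() {
  env <- new.env(parent = emptyenv())
  env$gates <- list()
  env$nl <- list()
  env$counter <- 0L
  env
}

cb_port <- function(cb, n = 1L) {
  out <- paste0("w", cb$counter + seq_len(n))
  cb$counter <- cb$counter + n
  out
}

cb_add <- function(cb, gate, type, inputs, outputs, logic = NA_character_,
                   table = NULL, stage = NA_character_) {
  cb$gates[[length(cb$gates) + 1L]] <- gate
  cb$nl[[length(cb$nl) + 1L]] <- list(
    gate_id = gate$id, type = type, logic = logic,
    inputs = inputs, outputs = outputs, table = table, stage = stage,
    K = gate$meta$K %||% NA_integer_, N = gate$meta$N %||% NA_integer_)
  invisible(gate)
}

add_mapping <- function(cb, table, in_ports, out_port, stage, logic = NA_character_) {
  K <- length(in_ports)
  g <- make_mapping_module(K, table, in_ports, out_port)
  if (!is.na(logic)) g$meta$logic <- logic
  cb_add(cb, g, "map", in_ports, out_port, logic = logic,
         table = normalise_table(K, table), stage = stage)
  out_port
}

add_amp <- function(cb, in_port, out_port, stage) {
  g <- make_amplification_gate(in_port, out_port)
  cb_add(cb, g, "amp", in_port, out_port, stage = stage)
  out_port
}

add_fanout <- function(cb, in_port, n, stage) {
  outs <- cb_port(cb, n)
  g <- make_fanout_gate(n, in_port, outs)
  cb_add(cb, g, "fanout", in_port, outs, stage = stage)
  outs
}

add_reporter <- function(cb, port, stage) {
  g <- make_reporter_gate(port)
  cb_add(cb, g, "reporter", port, character(), stage = stage)
  g
}

# One-bit full adder: both outputs as two 3-input mapping modules (sum =
# parity, carry = majority), each input distributed to the two modules by a
# 2-fan-out, and an amplification gate restoring each module output to one
# unit.
add_full_adder <- function(cb, a, b, cin, stage) {
  fa <- add_fanout(cb, a, 2L, stage)
  fb <- add_fanout(cb, b, 2L, stage)
  fc <- add_fanout(cb, cin, 2L, stage)
  ps <- cb_port(cb); pc <- cb_port(cb)
  add_mapping(cb, parity_table(3L), c(fa[[1L]], fb[[1L]], fc[[1L]]), ps, stage)
  add_mapping(cb, majority_table(3L), c(fa[[2L]], fb[[2L]], fc[[2L]]), pc, stage)
  s_out <- cb_port(cb); c_out <- cb_port(cb)
  add_amp(cb, ps, s_out, stage)
  add_amp(cb, pc, c_out, stage)
  list(sum = s_out, carry = c_out)
}

add_half_adder <- function(cb, a, b, stage) {
  fa <- add_fanout(cb, a, 2L, stage)
  fb <- add_fanout(cb, b, 2L, stage)
  ps <- cb_port(cb); pc <- cb_port(cb)
  add_mapping(cb, logic_table("XOR"), c(fa[[1L]], fb[[1L]]), ps, stage, logic = "XOR")
  add_mapping(cb, logic_table("AND"), c(fa[[2L]], fb[[2L]]), pc, stage, logic = "AND")
  s_out <- cb_port(cb); c_out <- cb_port(cb)
  add_amp(cb, ps, s_out, stage)
  add_amp(cb, pc, c_out, stage)
  list(sum = s_out, carry = c_out)
}

cb_finish <- function(cb, kind, inputs, reporters, meta = list()) {
  nl <- tibble(
    gate_id = map_chr(cb$nl, "gate_id"),
    type = map_chr(cb$nl, "type"),
    logic = map_chr(cb$nl, ~ .x$logic %||% NA_character_),
    K = map_int(cb$nl, ~ as.integer(.x$K)),
    N = map_int(cb$nl, ~ as.integer(.x$N)),
    stage = map_chr(cb$nl, "stage"),
    inputs = map(cb$nl, ~ as.character(.x$inputs)),
    outputs = map(cb$nl, ~ as.character(.x$outputs)),
    table = map(cb$nl, "table")
  )
  gates_tbl <- tibble(
    gate_id = map_chr(cb$gates, "id"),
    kind = map_chr(cb$gates, "kind"),
    logic = map_chr(cb$gates, ~ .x$meta$logic %||% NA_character_),
    K = map_int(cb$gates, ~ as.integer(.x$meta$K %||% NA_integer_)),
    N = map_int(cb$gates, ~ as.integer(.x$meta$N %||% NA_integer_)),
    stage = nl$stage
  )
  structure(list(kind = kind, gates = cb$gates, gates_tbl = gates_tbl,
                 netlist = nl, inputs = inputs, reporters = reporters,
                 meta = meta),
            class = "dsd_circuit")
}

reporter_row <- function(gate, name, index) {
  tibble(name = name, index = index, port = gate$input_ports,
         fluor_t = gate$meta$fluor[["t"]], fluor_f = gate$meta$fluor[["f"]],
         gate_t = gate$species$species[[which(gate$species$role == "reporter_t")]],
         gate_f = gate$species$species[[which(gate$species$role == "reporter_f")]])
}

#' @export
print.dsd_circuit <- function(x, ...) {
  cat(sprintf("<dsd_circuit %s> %d gates, %d inputs, %d reporters\n",
              x$kind, nrow(x$gates_tbl), nrow(x$inputs), nrow(x$reporters)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dsd_circuit <- function(x, ...) x$gates_tbl

#' @exportS3Method generics::glance
glance.dsd_circuit <- function(x, ...) {
  tibble(kind = x$kind, n_gates = nrow(x$gates_tbl),
         n_species = nrow(species_pool(x)),
         n_inputs = nrow(x$inputs), n_reporters = nrow(x$reporters))
}

#' All gate species of a compiled circuit
#'
#' @param circuit A `dsd_circuit`.
#' @return Tibble with `species`, `conc_nM`, `role`, `gate_id`.
#' @export
species_pool <- function(circuit) {
  bind_rows(map(circuit$gates, ~ mutate(.x$species, gate_id = .x$id)))
}

#' Count gate instances in a compiled circuit
#'
#' @param circuit A `dsd_circuit`.
#' @param kind Gate kind (`"mapping"`, `"amplification"`, `"fanout"`,
#'   `"reporter"`), or `NULL` for any.
#' @param logic Logic tag (`"AND"`, `"XOR"`, ...), or `NULL`.
#' @param stage Compilation stage tag, or `NULL`.
#' @param N Fan-out degree, or `NULL`.
#' @return Integer count.
#' @export
count_gates <- function(circuit, kind = NULL, logic = NULL, stage = NULL,
                        N = NULL) {
  tbl <- circuit$gates_tbl
  if (!is.null(kind)) tbl <- tbl[tbl$kind %in% kind, ]
  if (!is.null(logic)) tbl <- tbl[!is.na(tbl$logic) & tbl$logic %in% logic, ]
  if (!is.null(stage)) tbl <- tbl[!is.na(tbl$stage) & tbl$stage %in% stage, ]
  if (!is.null(N)) tbl <- tbl[!is.na(tbl$N) & tbl$N %in% N, ]
  nrow(tbl)
}

# ---------------------------------------------------------------------------
# Reference circuits
# ---------------------------------------------------------------------------

#' Compile the 1-bit full adder
#'
#' Two 3-input mapping modules (sum = parity, carry = majority of A, B and
#' the carry-in), three 2-fan-out gates distributing the inputs to both
#' modules, one amplification gate per output, and optional reporter gates
#' on sum and carry.  The two-operand demonstration cases drive the adder
#' with the carry-in held at 0.
#'
#' @param a,b,cin Input port names.
#' @param include_reporters Attach reporters to sum (`S0`) and carry (`S1`)?
#' @return A `dsd_circuit`.
#' @export
compile_full_adder <- function(a = "A0", b = "B0", cin = "Cin",
                               include_reporters = TRUE) {
  cb <- cb_new()
  fa <- add_full_adder(cb, a, b, cin, stage = "full_adder")
  reporters <- tibble()
  if (include_reporters) {
    rs <- add_reporter(cb, fa$sum, "output")
    rc <- add_reporter(cb, fa$carry, "output")
    reporters <- bind_rows(reporter_row(rs, "S0", 0L), reporter_row(rc, "S1", 1L))
  }
  inputs <- tibble(name = c("A0", "B0", "Cin"), port = c(a, b, cin),
                   group = c("A", "B", "Cin"), index = c(0L, 0L, 0L))
  cb_finish(cb, "full_adder", inputs, reporters,
            meta = list(sum = fa$sum, carry = fa$carry))
}

#' Compile the 4x4 binary multiplier
#'
#' Sixteen AND mapping modules form the partial-product array (each operand
#' bit reaches its four AND gates through a 4-fan-out); four half adders and
#' eight full adders (reporters omitted inside) sum the columns; the eight
#' product bits S7..S0 end in reporter gates.  Input ports are A0..A3 and
#' B0..B3.
#'
#' @return A `dsd_circuit`.
#' @export
compile_multiplier_4x4 <- function() {
  cb <- cb_new()
  a_ports <- paste0("A", 0:3)
  b_ports <- paste0("B", 0:3)
  fa_copies <- map(a_ports, ~ add_fanout(cb, .x, 4L, "input_fanout"))
  fb_copies <- map(b_ports, ~ add_fanout(cb, .x, 4L, "input_fanout"))
  pp <- matrix("", 4L, 4L)   # pp[i, j] = A_(i-1) AND B_(j-1)
  for (i in 1:4) {
    for (j in 1:4) {
      out <- cb_port(cb)
      add_mapping(cb, logic_table("AND"),
                  c(fa_copies[[i]][[j]], fb_copies[[j]][[i]]), out,
                  stage = "partial_product", logic = "AND")
      pp[i, j] <- out
    }
  }
  ha_a <- add_half_adder(cb, pp[2, 1], pp[1, 2], "column_sum")
  fa_a <- add_full_adder(cb, pp[3, 1], pp[2, 2], ha_a$carry, "column_sum")
  fa_b <- add_full_adder(cb, pp[4, 1], pp[3, 2], fa_a$carry, "column_sum")
  ha_b <- add_half_adder(cb, pp[4, 2], fa_b$carry, "column_sum")
  ha_c <- add_half_adder(cb, fa_a$sum, pp[1, 3], "column_sum")
  fa_c <- add_full_adder(cb, fa_b$sum, pp[2, 3], ha_c$carry, "column_sum")
  fa_d <- add_full_adder(cb, ha_b$sum, pp[3, 3], fa_c$carry, "column_sum")
  fa_e <- add_full_adder(cb, ha_b$carry, pp[4, 3], fa_d$carry, "column_sum")
  ha_d <- add_half_adder(cb, fa_c$sum, pp[1, 4], "column_sum")
  fa_f <- add_full_adder(cb, fa_d$sum, pp[2, 4], ha_d$carry, "column_sum")
  fa_g <- add_full_adder(cb, fa_e$sum, pp[3, 4], fa_f$carry, "column_sum")
  fa_h <- add_full_adder(cb, fa_e$carry, pp[4, 4], fa_g$carry, "column_sum")
  s0 <- cb_port(cb)
  add_amp(cb, pp[1, 1], s0, "output")
  out_ports <- c(s0, ha_a$sum, ha_c$sum, ha_d$sum, fa_f$sum, fa_g$sum,
                 fa_h$sum, fa_h$carry)
  reporters <- bind_rows(imap(out_ports, function(p, i) {
    reporter_row(add_reporter(cb, p, "output"), paste0("S", i - 1L), i - 1L)
  }))
  inputs <- tibble(name = c(paste0("A", 0:3), paste0("B", 0:3)),
                   port = c(a_ports, b_ports),
                   group = rep(c("A", "B"), each = 4L),
                   index = rep(0:3, 2L))
  cb_finish(cb, "multiplier_4x4", inputs, reporters)
}

#' Compile the 8-bit ripple-carry adder/subtractor
#'
#' Eight XOR mapping modules conditionally invert the B operand under the
#' mode switch A#S, whose signal a 9-fan-out distributes to the XOR gates
#' and the initial carry-in; eight 1-bit full adders ripple the carry; 24
#' amplification gates (per stage: XOR output, sum, carry) restore levels;
#' nine reporters read S8..S0.  With A#S = 0 the circuit adds, with A#S = 1
#' it subtracts B from A by two's complement.  Input ports follow the
#' reference strand listing: A0..A7 on S2..S9, B0..B7 on S10..S17, the
#' switch on S0.
#'
#' @param width Operand width; the reference construction is 8.
#' @return A `dsd_circuit`.
#' @export
compile_adder_subtractor <- function(width = 8L) {
  if (width != 8L) abort("the reference construction has width 8")
  cb <- cb_new()
  a_ports <- paste0("S", 2:9)
  b_ports <- paste0("S", 10:17)
  switch_port <- "S0"
  sw <- add_fanout(cb, switch_port, 9L, "switch_fanout")
  carry <- sw[[9L]]                      # initial carry-in = A#S
  reporters <- list()
  for (i in seq_len(width)) {
    wx <- cb_port(cb)
    add_mapping(cb, logic_table("XOR"), c(b_ports[[i]], sw[[i]]), wx,
                stage = paste0("stage", i - 1L), logic = "XOR")
    bx <- cb_port(cb)
    add_amp(cb, wx, bx, paste0("stage", i - 1L))
    fa <- add_full_adder(cb, a_ports[[i]], bx, carry, paste0("stage", i - 1L))
    carry <- fa$carry
    rg <- add_reporter(cb, fa$sum, "output")
    reporters[[i]] <- reporter_row(rg, paste0("S", i - 1L), i - 1L)
  }
  rg <- add_reporter(cb, carry, "output")
  reporters[[width + 1L]] <- reporter_row(rg, paste0("S", width), width)
  inputs <- tibble(
    name = c(paste0("A", 0:7), paste0("B", 0:7), "A#S"),
    port = c(a_ports, b_ports, switch_port),
    group = c(rep("A", 8L), rep("B", 8L), "switch"),
    index = c(0:7, 0:7, 0L)
  )
  cb_finish(cb, "adder_subtractor_8bit", inputs, bind_rows(reporters),
            meta = list(width = width))
}

# ---------------------------------------------------------------------------
# Operand encoding and readout decoding
# ---------------------------------------------------------------------------

#' Bits of a binary word, named for circuit inputs
#'
#' @param word A most-significant-first bit string (e.g. `"00101101"`) or a
#'   non-negative integer.
#' @param group Input group (`"A"`, `"B"`).
#' @param width Word width.
#' @return Named integer vector, e.g. `c(A7 = 0, ..., A0 = 1)`.
#' @export
word_bits <- function(word, group, width) {
  if (is.numeric(word)) {
    stopifnot(word >= 0, word < 2^width)
    bits <- as.integer(intToBits(word))[seq_len(width)]   # LSB first
  } else {
    ch <- strsplit(word, "")[[1L]]
    if (length(ch) != width || !all(ch %in% c("0", "1")))
      abort(sprintf("word must be %d bits of 0/1", width))
    bits <- rev(as.integer(ch))
  }
  names(bits) <- paste0(group, seq_len(width) - 1L)
  bits
}

#' Integer value of a named or MSB-first bit vector
#'
#' @param bits Integer vector of 0/1, least-significant first.
#' @return Integer.
#' @export
bits_value <- function(bits) sum(bits * 2^(seq_along(bits) - 1L))

#' Encode operand words as domain-label input strands
#'
#' One signal strand per circuit input at one unit concentration, with both
#' halves on the input's port and the label `t` for bit 1 / `f` for bit 0.
#'
#' @param circuit A `dsd_circuit`.
#' @param bits Named 0/1 vector covering every input name of the circuit
#'   (see [word_bits()], [adder_inputs()], [multiplier_inputs()],
#'   [addsub_inputs()]).
#' @param concentration Strand concentration, nM.
#' @return Tibble with `species`, `conc_nM`, `name`.
#' @export
encode_inputs <- function(circuit, bits, concentration = DSD_UNIT_NM) {
  missing <- setdiff(circuit$inputs$name, names(bits))
  if (length(missing) > 0L)
    abort(paste0("missing input bits: ", paste(missing, collapse = ", ")))
  extra <- setdiff(names(bits), circuit$inputs$name)
  if (length(extra) > 0L)
    abort(paste0("unknown inputs: ", paste(extra, collapse = ", ")))
  rows <- pmap(circuit$inputs, function(name, port, group, index) {
    lab <- if (bits[[name]] == 1L) "t" else "f"
    tibble(species = render_species(signal_strand(port, lab, port, lab)),
           conc_nM = concentration, name = name)
  })
  bind_rows(rows)
}

#' @rdname encode_inputs
#' @param a,b Operand bits (0/1) for the full adder.
#' @param cin Carry-in bit.
#' @export
adder_inputs <- function(a, b, cin = 0L) {
  c(A0 = as.integer(a), B0 = as.integer(b), Cin = as.integer(cin))
}

#' @rdname encode_inputs
#' @param a_word,b_word Operand words (bit strings or integers).
#' @export
multiplier_inputs <- function(a_word, b_word) {
  c(word_bits(a_word, "A", 4L), word_bits(b_word, "B", 4L))
}

#' @rdname encode_inputs
#' @param switch Mode bit: 0 adds, 1 subtracts.
#' @export
addsub_inputs <- function(a_word, b_word, switch = 0L) {
  c(word_bits(a_word, "A", 8L), word_bits(b_word, "B", 8L),
    "A#S" = as.integer(switch))
}

#' Threshold-decode reporter fluorophores into bits
#'
#' A bit reads 1 when the `t`-fluorophore is at or above 0.9 units and the
#' `f`-fluorophore at or below 0.1 units; 0 in the mirrored case; anything
#' else is reported as `"ambiguous"` rather than silently coerced.
#'
#' @param traj A `dsd_trajectory` from simulating the compiled circuit.
#' @param circuit The `dsd_circuit`.
#' @param t Readout time, s (defaults to the trajectory end).
#' @param hi,lo Decode bands in units.
#' @return Tibble with one row per output bit: `name`, `index`, `t_units`,
#'   `f_units`, `bit` (NA when ambiguous) and `status`.
#' @export
decode_outputs <- function(traj, circuit, t = max(traj$times),
                           hi = 0.9, lo = 0.1) {
  missing <- setdiff(c(circuit$reporters$gate_t, circuit$reporters$gate_f),
                     traj$species)
  if (length(missing) > 0L)
    abort(paste0("reporter species missing from trajectory: ", missing[[1L]]))
  # a fluorophore that never fires is absent from the input-specific closure:
  # read it as zero concentration
  read0 <- function(s) {
    if (s %in% traj$species) readout(traj, s, t)$value else 0
  }
  rows <- pmap(circuit$reporters, function(name, index, port, fluor_t, fluor_f,
                                           gate_t, gate_f) {
    tv <- read0(fluor_t)
    fv <- read0(fluor_f)
    bit <- if (tv >= hi && fv <= lo) 1L else if (fv >= hi && tv <= lo) 0L else NA_integer_
    tibble(name = name, index = index, t_units = tv, f_units = fv, bit = bit,
           status = if (is.na(bit)) "ambiguous" else "ok")
  })
  arrange(bind_rows(rows), dplyr::desc(index))
}

#' Assemble a decoded word, most significant bit first
#'
#' @param decoded Output of [decode_outputs()].
#' @return Bit string; ambiguous bits print as `?`.
#' @export
decoded_word <- function(decoded) {
  d <- arrange(decoded, dplyr::desc(index))
  paste(ifelse(is.na(d$bit), "?", d$bit), collapse = "")
}

# ---------------------------------------------------------------------------
# End-to-end simulation
# ---------------------------------------------------------------------------

#' Compile-and-run: simulate a circuit on an input assignment
#'
#' Builds the species pool (gate species plus encoded input strands), closes
#' it into a CRN, integrates to `t_end` and threshold-decodes the reporters.
#'
#' @param circuit A `dsd_circuit`.
#' @param bits Named input bits (see [encode_inputs()]).
#' @param t_end Integration horizon, s.
#' @param rates A [dsd_rates()] set.
#' @param ... Passed to [simulate_crn()] (e.g. `rtol`).
#' @return A `dsd_result` with the CRN, trajectory, decoded bits and word.
#' @export
simulate_circuit <- function(circuit, bits, t_end = 1e4, rates = dsd_rates(),
                             ...) {
  pool <- bind_rows(
    species_pool(circuit)[, c("species", "conc_nM")],
    encode_inputs(circuit, bits)[, c("species", "conc_nM")]
  )
  net <- close_crn(pool, rates = rates)
  traj <- simulate_crn(net, t_end = t_end, ...)
  decoded <- decode_outputs(traj, circuit)
  structure(list(circuit = circuit, crn = net, trajectory = traj,
                 decoded = decoded, word = decoded_word(decoded),
                 bits = bits, settled = is_settled(traj)),
            class = "dsd_result")
}

#' @export
print.dsd_result <- function(x, ...) {
  cat(sprintf("<dsd_result %s> word = %s (%s)\n", x$circuit$kind, x$word,
              if (x$settled) "settled" else "NOT settled"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dsd_result <- function(x, ...) x$decoded

#' @exportS3Method generics::glance
glance.dsd_result <- function(x, ...) {
  tibble(kind = x$circuit$kind, word = x$word, settled = x$settled,
         n_species = nrow(x$crn$species), n_reactions = nrow(x$crn$reactions),
         ambiguous = sum(x$decoded$status == "ambiguous"))
}

#' @exportS3Method ggplot2::autoplot
autoplot.dsd_result <- function(object, ...) {
  autoplot.dsd_trajectory(object$trajectory,
    species = c(object$circuit$reporters$fluor_t,
                object$circuit$reporters$fluor_f), ...)
}

# ---------------------------------------------------------------------------
# Logic-level twin
# ---------------------------------------------------------------------------

#' Evaluate a netlist in topological order
#'
#' Pure Boolean evaluation of the logic-level twin: mapping modules apply
#' their truth table, amplification and fan-out gates copy their input,
#' reporters terminate wires.  Primitive AND/OR/NOT rows (reference
#' netlists) are evaluated directly.
#'
#' @param netlist A circuit netlist tibble.
#' @param inputs Named 0/1 vector keyed by input port/wire name.
#' @return Named list of all wire values.
#' @export
eval_netlist <- function(netlist, inputs) {
  vals <- as.list(inputs)
  pending <- seq_len(nrow(netlist))
  repeat {
    progress <- FALSE
    still <- integer()
    for (r in pending) {
      ins <- netlist$inputs[[r]]
      outs <- netlist$outputs[[r]]
      if (length(outs) == 0L) next
      if (!all(ins %in% names(vals))) { still <- c(still, r); next }
      iv <- unlist(vals[ins])
      ov <- switch(netlist$type[[r]],
        map = {
          pat <- paste(ifelse(iv == 1L, "t", "f"), collapse = "")
          as.integer(netlist$table[[r]][[pat]] == "t")
        },
        amp = iv[[1L]],
        fanout = rep(iv[[1L]], length(outs)),
        prim = switch(netlist$logic[[r]],
          AND = as.integer(all(iv == 1L)),
          OR = as.integer(any(iv == 1L)),
          NOT = as.integer(iv[[1L]] == 0L),
          XOR = as.integer(sum(iv) %% 2L),
          abort("unknown primitive gate")),
        abort("unknown netlist row type"))
      if (length(ov) == 1L) ov <- rep(ov, length(outs))
      for (q in seq_along(outs)) vals[[outs[[q]]]] <- ov[[q]]
      progress <- TRUE
    }
    pending <- still
    if (length(pending) == 0L) break
    if (!progress) abort("combinational cycle in netlist")
  }
  vals
}

#' Boolean oracle of a compiled circuit
#'
#' Evaluates the logic-level netlist twin on named input bits and returns
#' the output bits at the reporter wires, most significant first.
#'
#' @param circuit A `dsd_circuit`.
#' @param bits Named input bits as for [encode_inputs()].
#' @return Named integer vector of output bits (names `S0`, `S1`, ...).
#' @export
boolean_oracle <- function(circuit, bits) {
  port_of <- circuit$inputs$port
  names(port_of) <- circuit$inputs$name
  wires <- bits
  names(wires) <- port_of[names(bits)]
  vals <- eval_netlist(circuit$netlist, wires)
  out <- map_int(circuit$reporters$port, ~ as.integer(vals[[.x]]))
  names(out) <- circuit$reporters$name
  out[order(-circuit$reporters$index)]
}

oracle_word <- function(circuit, bits) {
  paste(boolean_oracle(circuit, bits), collapse = "")
}

#' Reference single-rail full-adder netlist
#'
#' The textbook one-bit full adder over AND/OR/NOT primitives (six AND,
#' three OR, four NOT in six layers), used as the single-rail reference
#' the mapping-module construction is compared against.
#'
#' @return A netlist tibble with primitive rows.
#' @export
single_rail_full_adder_netlist <- function() {
  prim <- function(logic, ins, out) {
    tibble(gate_id = out, type = "prim", logic = logic,
           K = length(ins), N = NA_integer_, stage = NA_character_,
           inputs = list(ins), outputs = list(out), table = list(NULL))
  }
  bind_rows(
    prim("NOT", "a", "na"), prim("NOT", "b", "nb"), prim("NOT", "c", "nc"),
    prim("AND", c("a", "nb"), "x1"), prim("AND", c("na", "b"), "x2"),
    prim("OR", c("x1", "x2"), "x"),                       # x = a xor b
    prim("NOT", "x", "nx"),
    prim("AND", c("x", "nc"), "y1"), prim("AND", c("nx", "c"), "y2"),
    prim("OR", c("y1", "y2"), "sum"),                     # sum = x xor c
    prim("AND", c("a", "b"), "z1"), prim("AND", c("x", "c"), "z2"),
    prim("OR", c("z1", "z2"), "carry")
  )
}

#' Layer count of a netlist
#'
#' Length of the longest input-to-output gate chain.
#'
#' @param netlist A netlist tibble.
#' @return Integer.
#' @export
netlist_layers <- function(netlist) {
  all_out <- unlist(netlist$outputs)
  depth <- new.env(parent = emptyenv())
  wire_depth <- function(w) {
    if (!is.null(depth[[w]])) return(depth[[w]])
    r <- which(map_lgl(netlist$outputs, ~ w %in% .x))
    d <- if (length(r) == 0L) 0L else {
      ins <- netlist$inputs[[r[[1L]]]]
      1L + if (length(ins) == 0L) 0L else max(map_int(ins, wire_depth))
    }
    depth[[w]] <- d
    d
  }
  if (length(all_out) == 0L) return(0L)
  max(map_int(unique(all_out), wire_depth))
}

# ---------------------------------------------------------------------------
# Complement arithmetic
# ---------------------------------------------------------------------------

#' Two's-complement subtraction
#'
#' Computes `a - b` on an n-bit adder as `a + (2^n - b) (mod 2^n)` and the
#' circuit-level output word `S_n..S0` (carry-out first; the carry-out is 1
#' exactly when no borrow occurs).
#'
#' @param a,b Operands with `0 <= a, b < 2^width`.
#' @param width Word width in bits.
#' @return List with `value` (the modular difference), `word` (the
#'   width+1-bit circuit word) and `carry_out`.
#' @examples
#' twos_complement_sub(77, 150, 8)
#' @export
twos_complement_sub <- function(a, b, width = 8L) {
  if (a < 0 || b < 0 || a >= 2^width || b >= 2^width)
    abort("operands out of range for the given width")
  total <- a + 2^width - b        # a + (2^width - 1 - b) + 1
  value <- total %% 2^width
  carry <- as.integer(total >= 2^width)
  bits <- word_bits(value, "S", width)
  word <- paste(c(carry, rev(unname(bits))), collapse = "")
  list(value = value, word = word, carry_out = carry)
}
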