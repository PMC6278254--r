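# ---------------------------------------------------------------------------
# Run configuration, verification runs, fixtures and file outputs.
# ---------------------------------------------------------------------------

#' Run configuration
#'
#' A fully serializable description of one verification run: the circuit,
#' the operand words, the mode switch, the rate set, solver settings and the
#' seed used for random-pair sweeps.  A run is reproducible from its config
#' alone.
#'
#' @param circuit `"full_adder"`, `"multiplier_4x4"` or
#'   `"adder_subtractor_8bit"`.
#' @param a,b Operand words (bit strings, MSB first) or single bits for the
#'   full adder.
#' @param cin Carry-in bit (full adder only).
#' @param switch Mode bit for the adder/subtractor: 0 adds, 1 subtracts.
#' @param t_end Integration horizon, s.
#' @param rtol,atol Solver tolerances.
#' @param rates A [dsd_rates()] set (or a list of its fields).
#' @param seed Seed for random-pair verification sweeps.
#' @param n_random Number of seeded random operand pairs in [cli_verify()].
#' @return A `dsd_config` list.
#' @export
dsd_config <- function(circuit, a = "0", b = "0", cin = 0L, switch = 0L,
                       t_end = 1e4, rtol = 1e-8, atol = 1e-6,
                       rates = dsd_rates(), seed = 1L, n_random = 0L) {
  circuit <- match.arg(circuit,
    c("full_adder", "multiplier_4x4", "adder_subtractor_8bit"))
  if (!inherits(rates, "dsd_rates")) rates <- do.call(dsd_rates, rates)
  structure(list(circuit = circuit, a = a, b = b, cin = cin, switch = switch,
                 t_end = t_end, rtol = rtol, atol = atol, rates = rates,
                 seed = seed, n_random = n_random),
            class = "dsd_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path File path.
#' @param config A `dsd_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  rates <- y$rates %||% list()
  dsd_config(circuit = y$circuit, a = as.character(y$a), b = as.character(y$b),
             cin = y$cin %||% 0L, switch = y$switch %||% 0L,
             t_end = y$t_end %||% 1e4, rtol = y$rtol %||% 1e-8,
             atol = y$atol %||% 1e-6, rates = rates,
             seed = y$seed %||% 1L, n_random = y$n_random %||% 0L)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  y <- unclass(config)
  y$rates <- unclass(y$rates)
  yaml::write_yaml(y, path)
  invisible(path)
}

config_circuit <- function(config) {
  switch(config$circuit,
    full_adder = compile_full_adder(),
    multiplier_4x4 = compile_multiplier_4x4(),
    adder_subtractor_8bit = compile_adder_subtractor())
}

config_bits <- function(config) {
  switch(config$circuit,
    full_adder = adder_inputs(as.integer(config$a), as.integer(config$b),
                              as.integer(config$cin)),
    multiplier_4x4 = multiplier_inputs(config$a, config$b),
    adder_subtractor_8bit = addsub_inputs(config$a, config$b, config$switch))
}

#' Compile a configured circuit to species, reaction-list and SBML files
#'
#' Writes the canonical DSD-notation species list (gate species plus the
#' configured input strands, with initial concentrations), the closed CRN as
#' a plain-text reaction list, and SBML Level 3.  Outputs are byte-stable
#' for a given config.
#'
#' @param config A `dsd_config`.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the written paths and the CRN.
#' @export
cli_compile <- function(config, out_dir = ".") {
  circuit <- config_circuit(config)
  pool <- bind_rows(
    species_pool(circuit)[, c("species", "conc_nM")],
    encode_inputs(circuit, config_bits(config))[, c("species", "conc_nM")]
  )
  net <- close_crn(pool, rates = config$rates)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    species = file.path(out_dir, paste0(config$circuit, "_species.txt")),
    reactions = file.path(out_dir, paste0(config$circuit, "_reactions.txt")),
    sbml = file.path(out_dir, paste0(config$circuit, ".sbml"))
  )
  sp <- arrange(net$species, species)
  write_species_file(sp, paths$species)
  write_reaction_list(net, paths$reactions)
  write_sbml(net, paths$sbml)
  invisible(c(paths, list(crn = net, circuit = circuit)))
}

verify_case <- function(circuit, bits, config) {
  res <- simulate_circuit(circuit, bits, t_end = config$t_end,
                          rates = config$rates, rtol = config$rtol,
                          atol = config$atol)
  expected <- oracle_word(circuit, bits)
  ambiguous <- any(res$decoded$status == "ambiguous")
  tibble(word = res$word, expected = expected,
         ambiguous = ambiguous, settled = res$settled,
         pass = !ambiguous && res$word == expected)
}

random_operands <- function(config, i) {
  switch(config$circuit,
    full_adder = adder_inputs(sample(0:1, 1L), sample(0:1, 1L), sample(0:1, 1L)),
    multiplier_4x4 = multiplier_inputs(sample(0:15, 1L), sample(0:15, 1L)),
    adder_subtractor_8bit = addsub_inputs(sample(0:255, 1L), sample(0:255, 1L),
                                          sample(0:1, 1L)))
}

#' Run a configured verification: compile, simulate, decode, compare
#'
#' Simulates the configured operand case and, if `n_random > 0`, a seeded
#' sweep of random operand assignments, comparing every decoded word with
#' the logic-level oracle.  The status code is 0 when everything passes, 1
#' on a logic mismatch and 2 when any decoded bit is ambiguous.
#'
#' @param config A `dsd_config`.
#' @param report_path Optional path for a JSON report.
#' @return A report list: `status`, `cases` tibble, decoded word and
#'   per-bit readouts of the configured case.
#' @export
cli_verify <- function(config, report_path = NULL) {
  circuit <- config_circuit(config)
  res <- simulate_circuit(circuit, config_bits(config), t_end = config$t_end,
                          rates = config$rates, rtol = config$rtol,
                          atol = config$atol)
  cases <- mutate(verify_case(circuit, config_bits(config), config),
                  case = "configured", .before = 1L)
  if (config$n_random > 0L) {
    set.seed(config$seed)
    for (i in seq_len(config$n_random)) {
      bits <- random_operands(config, i)
      cases <- bind_rows(cases,
        mutate(verify_case(circuit, bits, config),
               case = paste0("random", i), .before = 1L))
    }
  }
  status <- if (any(cases$ambiguous)) 2L else if (!all(cases$pass)) 1L else 0L
  report <- list(
    circuit = config$circuit,
    status = status,
    word = res$word,
    oracle = oracle_word(circuit, config_bits(config)),
    settled = res$settled,
    bits = res$decoded,
    cases = cases
  )
  if (!is.null(report_path)) {
    jsonlite::write_json(
      list(circuit = report$circuit, status = report$status,
           word = report$word, oracle = report$oracle,
           settled = report$settled,
           bits = as.data.frame(report$bits),
           cases = as.data.frame(report$cases)),
      report_path, auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @rdname cli_verify
#' @param ... Passed to [cli_verify()].
#' @export
dsd_run <- function(config, ...) cli_verify(config, ...)

# ---------------------------------------------------------------------------
# Fixtures
# ---------------------------------------------------------------------------

# independent schoolbook bit arithmetic (LSB-first bit vectors)
bit_add_words <- function(a_bits, b_bits, cin = 0L) {
  n <- length(a_bits)
  out <- integer(n); c <- cin
  for (i in seq_len(n)) {
    s <- a_bits[[i]] + b_bits[[i]] + c
    out[[i]] <- s %% 2L
    c <- s %/% 2L
  }
  c(out, c)
}

bit_mul_words <- function(a_bits, b_bits) {
  acc <- integer(length(a_bits) + length(b_bits))
  for (j in seq_along(b_bits)) {
    if (b_bits[[j]] == 1L) {
      shifted <- c(integer(j - 1L), a_bits, integer(length(b_bits) - j + 1L))
      acc <- bit_add_words(acc, shifted)[seq_along(acc)]
    }
  }
  acc
}

msb_string <- function(bits) paste(rev(bits), collapse = "")

#' Generate reproducible operand fixtures with oracle answers
#'
#' Seeded pseudo-random operand pairs for the three circuit operations, with
#' expected output words computed by independent schoolbook bit arithmetic.
#' The reference pairs (77, 150) for subtraction and 1111 x 1111 for
#' multiplication are always included.
#'
#' @param seed Integer seed.
#' @param n Number of random pairs per operation (at least 1).
#' @return Tibble with `op`, `a`, `b`, `switch`, `expected_word`.
#' @export
generate_fixtures <- function(seed, n) {
  stopifnot(n >= 1L)
  set.seed(seed)
  rows <- list(
    tibble(op = "sub", a = 77L, b = 150L),
    tibble(op = "mul", a = 15L, b = 15L)
  )
  for (i in seq_len(n)) {
    rows[[length(rows) + 1L]] <- tibble(op = "add", a = sample(0:255, 1L),
                                        b = sample(0:255, 1L))
    rows[[length(rows) + 1L]] <- tibble(op = "sub", a = sample(0:255, 1L),
                                        b = sample(0:255, 1L))
    rows[[length(rows) + 1L]] <- tibble(op = "mul", a = sample(0:15, 1L),
                                        b = sample(0:15, 1L))
  }
  fixtures <- bind_rows(rows)
  fixtures$switch <- ifelse(fixtures$op == "sub", 1L, 0L)
  fixtures$expected_word <- pmap_chr(fixtures, function(op, a, b, switch) {
    if (op == "mul") {
      msb_string(bit_mul_words(word_bits(a, "A", 4L), word_bits(b, "B", 4L)))
    } else {
      bb <- word_bits(b, "B", 8L)
      if (op == "sub") bb <- 1L - bb
      msb_string(bit_add_words(word_bits(a, "A", 8L), bb, cin = switch))
    }
  })
  fixtures
}

#' @importFrom purrr pmap_chr
#' @rdname generate_fixtures
#' @param fixtures Tibble from `generate_fixtures()`.
#' @param path CSV path.
#' @export
write_fixtures <- function(fixtures, path) {
  utils::write.csv(as.data.frame(fixtures), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
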