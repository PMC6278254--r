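# Shared generators and memoised simulation runs for the suite.

rand_token <- function(n = 1L) {
  name <- replicate(n, paste(sample(c(letters, LETTERS, 0:9), sample(1:4, 1L),
                                    replace = TRUE), collapse = ""))
  toe <- sample(c(TRUE, FALSE), n, replace = TRUE)
  comp <- sample(c(TRUE, FALSE), n, replace = TRUE)
  domain(name, toe, comp)
}

rand_free_strand <- function() {
  parse_species(paste0("<", paste(rand_token(sample(2:8, 1L)), collapse = " "), ">"))
}

rand_complex <- function() {
  n_seg <- sample(1:3, 1L)
  segs <- character(n_seg)
  for (i in seq_len(n_seg)) {
    parts <- character()
    if (i == 1L && runif(1) < 0.7) {
      parts <- c(parts, paste0("{", paste(rand_token(sample(1:2, 1L)), collapse = " "), "}"))
    }
    if (runif(1) < 0.3) {
      parts <- c(parts, paste0("<", paste(rand_token(sample(1:3, 1L)), collapse = " "), ">"))
    }
    parts <- c(parts, paste0("[", paste(rand_token(sample(2:4, 1L)), collapse = " "), "]"))
    if (runif(1) < 0.5) {
      parts <- c(parts, paste0("<", paste(rand_token(sample(1:3, 1L)), collapse = " "), ">"))
    }
    segs[[i]] <- paste(parts, collapse = " ")
  }
  parse_species(paste(segs, collapse = ":"))
}

# simulate a bare mapping module (with output amplifier and reporter) on one
# input pattern and return the decoded bit
simulate_module_pattern <- function(K, table, pattern, t_end = 1e4) {
  in_ports <- paste0("p", seq_len(K))
  mod <- make_mapping_module(K, table, in_ports, "o")
  amp <- make_amplification_gate("o", "q")
  rep <- make_reporter_gate("q")
  labs <- strsplit(pattern, "")[[1L]]
  inputs <- tibble::tibble(
    species = purrr::map2_chr(in_ports, labs,
      ~ render_species(signal_strand(paste0("u", .x), .y, .x, .y))),
    conc_nM = 1e4
  )
  pool <- dplyr::bind_rows(
    gate_species(mod)[, c("species", "conc_nM")],
    gate_species(amp)[, c("species", "conc_nM")],
    gate_species(rep)[, c("species", "conc_nM")],
    inputs
  )
  traj <- simulate_crn(close_crn(pool), t_end = t_end)
  fl <- rep$meta$fluor
  val <- function(s) {
    if (s %in% traj$species) readout(traj, s)$value else 0
  }
  tv <- val(fl[["t"]]); fv <- val(fl[["f"]])
  if (tv >= 0.9 && fv <= 0.1) 1L else if (fv >= 0.9 && tv <= 0.1) 0L else NA_integer_
}

# memoised expensive runs shared across test files
.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

adder_circuit <- function() cached("fa", compile_full_adder())
multiplier_circuit <- function() cached("mult", compile_multiplier_4x4())
addsub_circuit <- function() cached("addsub", compile_adder_subtractor())

run_adder <- function(a, b, cin = 0L) {
  cached(paste0("fa_run_", a, b, cin),
         simulate_circuit(adder_circuit(), adder_inputs(a, b, cin)))
}

run_multiplier_worked <- function() {
  cached("mult_worked",
         simulate_circuit(multiplier_circuit(), multiplier_inputs("1111", "1111")))
}

run_addsub_worked <- function() {
  cached("addsub_worked",
         simulate_circuit(addsub_circuit(),
                          addsub_inputs("00101101", "10010110", 1L)))
}
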