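# ---------------------------------------------------------------------------
# Dual-rail seesaw baseline.
#
# Concentration-encoded (dual-rail) circuits restore every logical wire with
# a thresholded catalytic seesaw stage: an irreversible threshold species
# absorbs sub-threshold input, and whatever survives catalyses the release
# of a restored output from a gate/fuel pair.  The baseline models the final
# restoration stage of each output wire of a 1-bit adder: the rail carrying
# the correct value arrives attenuated (0.85 units, the middle of the upper
# instability band), the opposite rail carries spurious sub-threshold
# chatter (0.15 units, the middle of the lower band).  A mid-range threshold
# cleans this up; a threshold inside either edge band loses the race and the
# wire decodes wrongly or not at all.
# ---------------------------------------------------------------------------

#' Seesaw baseline rate set
#'
#' Thresholding in seesaw circuits is designed to be much faster than gate
#' exchange; the defaults use a 1e-3 /nM/s threshold rate against the
#' 3e-5 /nM/s exchange rate of the displacement model.
#'
#' @param k_threshold Threshold absorption rate, /nM/s.
#' @param k_seesaw Gate exchange / fuel recovery rate, /nM/s.
#' @return Named list.
#' @export
seesaw_rates <- function(k_threshold = 1e-3, k_seesaw = 3e-5) {
  list(k_threshold = k_threshold, k_seesaw = k_seesaw)
}

seesaw_rail_crn <- function(wire, threshold_units, drive1, drive0,
                            rates, unit_nM = DSD_UNIT_NM) {
  species <- list(); reactions <- list()
  for (rail in c("1", "0")) {
    p <- function(s) paste0(wire, "_rail", rail, "_", s)
    drive <- if (rail == "1") drive1 else drive0
    species[[length(species) + 1L]] <- tibble(
      species = p(c("in", "th", "gate", "fuel", "out", "waste", "bound")),
      conc_nM = c(drive, threshold_units, 1, 2, 0, 0, 0) * unit_nM
    )
    reactions[[length(reactions) + 1L]] <- tibble(
      reactants = list(c(p("in"), p("th")),
                       c(p("in"), p("gate")),
                       c(p("fuel"), p("bound"))),
      products = list(p("waste"),
                      c(p("bound"), p("out")),
                      c(p("in"), p("waste"))),
      rate = c(rates$k_threshold, rates$k_seesaw, rates$k_seesaw),
      kind = c("threshold", "exchange", "fuel")
    )
  }
  list(species = bind_rows(species), reactions = bind_rows(reactions))
}

decode_rail_pair <- function(on1, on0, hi = 0.9, lo = 0.1) {
  if (on1 >= hi && on0 <= lo) 1L
  else if (on0 >= hi && on1 <= lo) 0L
  else NA_integer_
}

#' Simulate the dual-rail adder restoration fragment
#'
#' For the sum and carry wires of a 1-bit addition `a + b` (carry-in 0),
#' simulates the dual-rail restoration stage of each output wire at a given
#' per-rail threshold and decodes the restored rail pairs.  The rail
#' carrying the arithmetically correct value is driven at `on_drive` units
#' and the opposite rail at `off_drive` units; the verdict compares the
#' decoded bits with binary arithmetic, an ambiguous bit counting as
#' incorrect.
#'
#' @param threshold Threshold concentration in units, strictly inside (0, 1).
#' @param inputs Dual-rail input bits, e.g. `c(a = 1, b = 1)`.
#' @param t_end Integration horizon, s.
#' @param on_drive,off_drive Drive of the correct / spurious rail, units.
#' @param rates A [seesaw_rates()] list.
#' @return List with `decoded` (tibble per wire), `expected`, `verdict`
#'   (`"correct"` / `"incorrect"`) and the trajectory.
#' @examples
#' \donttest{
#' simulate_dual_rail_adder(0.5, c(a = 1, b = 1))$verdict
#' }
#' @export
simulate_dual_rail_adder <- function(threshold, inputs = c(a = 1, b = 1),
                                     t_end = 1e4, on_drive = 0.85,
                                     off_drive = 0.15,
                                     rates = seesaw_rates()) {
  if (!(threshold > 0 && threshold < 1))
    abort("threshold must lie strictly inside (0, 1) units")
  a <- as.integer(inputs[["a"]]); b <- as.integer(inputs[["b"]])
  expected <- c(sum = (a + b) %% 2L, carry = (a + b) %/% 2L)
  parts <- map(names(expected), function(w) {
    v <- expected[[w]]
    seesaw_rail_crn(w, threshold,
                    drive1 = if (v == 1L) on_drive else off_drive,
                    drive0 = if (v == 1L) off_drive else on_drive,
                    rates)
  })
  net <- crn(bind_rows(map(parts, "species")),
             bind_rows(map(parts, "reactions")))
  traj <- simulate_crn(net, t_end = t_end)
  decoded <- bind_rows(map(names(expected), function(w) {
    out1 <- readout(traj, paste0(w, "_rail1_out"))$value
    out0 <- readout(traj, paste0(w, "_rail0_out"))$value
    bit <- decode_rail_pair(out1, out0)
    tibble(wire = w, expected = expected[[w]],
           rail1 = out1, rail0 = out0, bit = bit,
           status = if (is.na(bit)) "ambiguous" else "ok")
  }))
  correct <- all(!is.na(decoded$bit) & decoded$bit == decoded$expected)
  list(decoded = decoded, expected = expected,
       verdict = if (correct) "correct" else "incorrect",
       threshold = threshold, trajectory = traj)
}
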