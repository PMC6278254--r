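# ---------------------------------------------------------------------------
# Domain-label gate constructors.
#
# Every gate expands into a small set of species with initial concentrations.
# The unit concentration is 10,000 nM; gate double strands default to one
# unit and catalytic fuels to the multiple of the gate concentration that
# the catalytic cycle consumes.
# ---------------------------------------------------------------------------

DSD_UNIT_NM <- 1e4

mk_species <- function(segs) render_species(new_species(segs))

free_strand_text <- function(toks) {
  render_species(new_species(list(new_segment(upper_post = toks))))
}

new_gate <- function(kind, id, input_ports, output_ports, species, meta = list()) {
  structure(list(kind = kind, id = id,
                 input_ports = input_ports, output_ports = output_ports,
                 species = species, meta = meta),
            class = "dsd_gate")
}

#' Species table of a gate
#'
#' @param gate A `dsd_gate`.
#' @return Tibble with `species`, `conc_nM`, `role`.
#' @export
gate_species <- function(gate) {
  stopifnot(inherits(gate, "dsd_gate"))
  gate$species
}

#' @export
print.dsd_gate <- function(x, ...) {
  cat(sprintf("<dsd_gate %s> %s: %s -> %s (%d species)\n", x$kind, x$id,
              paste(x$input_ports, collapse = ","),
              paste(x$output_ports, collapse = ","), nrow(x$species)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dsd_gate <- function(x, ...) {
  mutate(x$species, gate_id = x$id, kind = x$kind, .before = 1L)
}

# ---------------------------------------------------------------------------
# Truth tables
# ---------------------------------------------------------------------------

#' Input label patterns of a K-input module
#'
#' Patterns are ordered lexicographically with `f` before `t` and the first
#' input most significant: for K = 2 this is `ff, ft, tf, tt`, matching the
#' (ff, n1), (ft, n2), (tf, n3), (tt, n4) bookkeeping of the gate listings.
#'
#' @param K Input arity.
#' @return Character vector of label patterns, length `2^K`.
#' @export
label_patterns <- function(K) {
  stopifnot(K >= 1L)
  grid <- expand.grid(rep(list(c("f", "t")), K), stringsAsFactors = FALSE)
  sort(apply(grid, 1L, paste, collapse = ""))
}

normalise_table <- function(K, table) {
  pats <- label_patterns(K)
  if (is.character(table) && length(table) == 1L && is.null(names(table))) {
    bits <- strsplit(table, "")[[1L]]
    if (length(bits) != length(pats) || !all(bits %in% c("0", "1", "t", "f")))
      abort(sprintf("table bit-string must have length %d over 0/1 or f/t", length(pats)))
    out <- ifelse(bits %in% c("1", "t"), "t", "f")
    names(out) <- pats
    return(out)
  }
  if (is.null(names(table)) || !setequal(names(table), pats))
    abort(sprintf("partial or misnamed table: need one entry per pattern (%s)",
                  paste(pats, collapse = ", ")))
  out <- unname(table[pats])
  if (!all(out %in% c("t", "f"))) abort("table values must be 't' or 'f'")
  names(out) <- pats
  out
}

#' Truth tables of the named logic gates
#'
#' NOT is the inverting 1-input table; AND outputs `t` only on `tt`, OR
#' outputs `f` only on `ff`, XOR outputs `t` on `ft` and `tf`.
#'
#' @param kind One of `"NOT"`, `"AND"`, `"OR"`, `"XOR"`.
#' @return Named character vector over the input patterns.
#' @export
logic_table <- function(kind) {
  switch(kind,
    NOT = c(f = "t", t = "f"),
    AND = c(ff = "f", ft = "f", tf = "f", tt = "t"),
    OR  = c(ff = "f", ft = "t", tf = "t", tt = "t"),
    XOR = c(ff = "f", ft = "t", tf = "t", tt = "f"),
    abort(sprintf("unknown logic gate kind '%s'", kind)))
}

#' All truth tables of K-input mapping modules
#'
#' A K-input module maps `{t,f}^K` to `{t,f}`, so there are `2^(2^K)`
#' distinct modules: 4 at K = 1, 16 at K = 2, 256 at K = 3.
#'
#' @param K Input arity (kept to K <= 4; the count is `2^(2^K)`).
#' @return Tibble with `table_id`, `bits` (output labels over the ordered
#'   patterns, as an f/t string) and list-column `table`.
#' @export
enumerate_mapping_modules <- function(K) {
  stopifnot(K >= 1L)
  if (K > 4L) abort("K > 4 enumerates more than 2^16 tables; not supported")
  pats <- label_patterns(K)
  m <- length(pats)
  outs <- expand.grid(rep(list(c("f", "t")), m), stringsAsFactors = FALSE)
  bits <- sort(apply(outs, 1L, paste, collapse = ""))
  tibble(
    table_id = seq_along(bits),
    bits = bits,
    table = map(bits, function(b) {
      v <- strsplit(b, "")[[1L]]
      names(v) <- pats
      v
    })
  )
}

# ---------------------------------------------------------------------------
# Mapping module
# ---------------------------------------------------------------------------

#' Construct a K-input mapping module
#'
#' The module consists of `2^K` gate double strands, one per input label
#' pattern `x1...xK`: `{T^*} [p1L^ x1 p1R^ T^]:...:[pKL^ xK pKR^ T^]
#' <oL^ n oR^>` with `n = table(x1...xK)`.  Inputs invade sequentially left
#' to right by toehold exchange; the final exchange releases the output
#' signal strand carrying the table's label.
#'
#' @param K Input arity (1 to 4).
#' @param table Output labels: a named character vector over
#'   [label_patterns()] or a bit-string of length `2^K`.
#' @param input_ports Character vector of K distinct port names.
#' @param output_port Output port name.
#' @param concentration Initial concentration of each gate species, nM.
#' @param toehold Universal toehold domain name.
#' @param id Gate instance id (defaults to a name derived from the ports).
#' @return A `dsd_gate`.
#' @examples
#' make_mapping_module(1, c(f = "t", t = "f"), "m", "n")
#' @export
make_mapping_module <- function(K, table, input_ports, output_port,
                                concentration = DSD_UNIT_NM, toehold = "T",
                                id = NULL) {
  stopifnot(K >= 1L, K <= 4L)
  if (length(input_ports) != K) abort("need exactly K input ports")
  ports <- c(input_ports, output_port)
  if (anyDuplicated(ports)) abort("duplicate port names in mapping module")
  tab <- normalise_table(K, table)
  id <- id %||% paste0("map_", paste(input_ports, collapse = "."), ".", output_port)
  tt <- domain(toehold, toehold = TRUE)
  op <- port_domains(output_port)
  species <- imap(tab, function(n, pat) {
    labs <- strsplit(pat, "")[[1L]]
    segs <- map2(input_ports, labs, function(p, x) {
      pd <- port_domains(p)
      new_segment(duplex = c(pd[[1L]], x, pd[[2L]], tt))
    })
    segs[[1L]]$lower_pre <- complement_of(tt)
    segs[[K]]$upper_post <- c(op[[1L]], n, op[[2L]])
    mk_species(segs)
  })
  tbl <- tibble(species = unname(unlist(species)),
                conc_nM = concentration,
                role = paste0("gate_", names(tab)))
  new_gate("mapping", id, input_ports, output_port, tbl,
           meta = list(K = K, table = tab, concentration = concentration))
}

#' Construct a named logic gate as a mapping module
#'
#' @param kind `"NOT"` (K = 1), `"AND"`, `"OR"` or `"XOR"` (K = 2).
#' @param input_ports One port for NOT, two for the binary gates.
#' @param output_port Output port name.
#' @param ... Passed to [make_mapping_module()].
#' @return A `dsd_gate` with `meta$logic` set.
#' @export
make_logic_gate <- function(kind, input_ports, output_port, ...) {
  tab <- logic_table(kind)
  K <- if (kind == "NOT") 1L else 2L
  g <- make_mapping_module(K, tab, input_ports, output_port, ...)
  g$meta$logic <- kind
  g
}

# ---------------------------------------------------------------------------
# Amplification gate
# ---------------------------------------------------------------------------

#' Construct an amplification gate
#'
#' Two gate double strands (one per label channel) and two fuel single
#' strands at twice the gate concentration.  The upstream signal acts as a
#' catalyst: it releases the output by toehold exchange and is itself
#' displaced back into solution by the fuel, so the output amplitude equals
#' the gate concentration regardless of the (positive) input amplitude.
#' The two label channels are disjoint: an `f` input can never release the
#' `t` output.
#'
#' @param input_port,output_port Port names.
#' @param target_concentration Gate concentration, nM; this is the restored
#'   output amplitude.  Fuels are loaded at twice this value.
#' @param toehold Universal toehold domain name.
#' @param id Gate instance id.
#' @return A `dsd_gate`.
#' @export
make_amplification_gate <- function(input_port, output_port,
                                    target_concentration = DSD_UNIT_NM,
                                    toehold = "T", id = NULL) {
  if (target_concentration <= 0) abort("target_concentration must be positive")
  id <- id %||% paste0("amp_", input_port, ".", output_port)
  tt <- domain(toehold, toehold = TRUE)
  pd <- port_domains(input_port)
  od <- port_domains(output_port)
  fd <- port_domains(paste0(id, "_i"))
  fuel_tail <- c(fd[[1L]], paste0(id, "_j"), fd[[2L]])
  rows <- map(c("f", "t"), function(x) {
    gate <- mk_species(list(new_segment(
      lower_pre = complement_of(tt),
      duplex = c(pd[[1L]], x, pd[[2L]], tt),
      upper_post = c(od[[1L]], x, od[[2L]])
    )))
    fuel <- free_strand_text(c(pd[[1L]], x, pd[[2L]], tt, fuel_tail))
    tibble(species = c(gate, fuel),
           conc_nM = c(target_concentration, 2 * target_concentration),
           role = paste0(c("gate_", "fuel_"), x))
  })
  new_gate("amplification", id, input_port, output_port, bind_rows(rows),
           meta = list(concentration = target_concentration))
}

# ---------------------------------------------------------------------------
# Fan-out gate
# ---------------------------------------------------------------------------

#' Construct an N fan-out gate
#'
#' Converts one signal strand into N identical-value signal strands on N
#' distinct output ports, each at the gate concentration.  Per label
#' channel the gate carries one double strand per output port plus one fuel
#' at N times the gate concentration; after each release the fuel displaces
#' the bound input back into solution, so the input acts as a catalyst.
#' For N = 2 this is the eight-species system of the reference figure: the
#' two possible input strands, four gate doubles and two fuels.
#'
#' @param N Fan-out degree, at least 2.
#' @param input_port Input port name.
#' @param output_ports Character vector of N output port names.
#' @param concentration Gate concentration per output species, nM.
#' @param toehold Universal toehold domain name.
#' @param id Gate instance id.
#' @return A `dsd_gate`.
#' @export
make_fanout_gate <- function(N, input_port, output_ports,
                             concentration = DSD_UNIT_NM, toehold = "T",
                             id = NULL) {
  if (N < 2L) abort("fan-out degree N must be at least 2")
  if (length(output_ports) != N) abort("need exactly N output ports")
  if (anyDuplicated(c(input_port, output_ports))) abort("duplicate port names")
  id <- id %||% paste0("fan", N, "_", input_port)
  tt <- domain(toehold, toehold = TRUE)
  pd <- port_domains(input_port)
  fd <- port_domains(paste0(id, "_i"))
  fuel_tail <- c(fd[[1L]], paste0(id, "_j"), fd[[2L]])
  rows <- map(c("f", "t"), function(x) {
    gates <- map_chr(output_ports, function(op) {
      od <- port_domains(op)
      mk_species(list(new_segment(
        lower_pre = complement_of(tt),
        duplex = c(pd[[1L]], x, pd[[2L]], tt),
        upper_post = c(od[[1L]], x, od[[2L]])
      )))
    })
    fuel <- free_strand_text(c(pd[[1L]], x, pd[[2L]], tt, fuel_tail))
    tibble(species = c(gates, fuel),
           conc_nM = c(rep(concentration, N), N * concentration),
           role = c(paste0("gate_", x, "_", output_ports), paste0("fuel_", x)))
  })
  new_gate("fanout", id, input_port, output_ports, bind_rows(rows),
           meta = list(N = N, concentration = concentration))
}

# ---------------------------------------------------------------------------
# Reporter gate
# ---------------------------------------------------------------------------

#' Construct a reporter (detection) gate
#'
#' Two fluorophore/quencher duplexes, one per label channel.  A signal
#' strand fully displaces the matching fluorophore strand
#' `<pL^ x pR^ fluor>` (no residual toehold, hence irreversible); the
#' released fluorophore strand is inert and its concentration is the
#' readout.
#'
#' @param input_port Port the reporter listens on.
#' @param concentration Reporter duplex concentration, nM.
#' @param toehold Universal toehold domain name.
#' @param id Gate instance id.
#' @return A `dsd_gate`; `meta$fluor` maps label to fluorophore species.
#' @export
make_reporter_gate <- function(input_port, concentration = DSD_UNIT_NM,
                               toehold = "T", id = NULL) {
  id <- id %||% paste0("rep_", input_port)
  tt <- domain(toehold, toehold = TRUE)
  pd <- port_domains(input_port)
  fluor <- c(f = free_strand_text(c(pd[[1L]], "f", pd[[2L]], "fluor")),
             t = free_strand_text(c(pd[[1L]], "t", pd[[2L]], "fluor")))
  rows <- map(c("f", "t"), function(x) {
    gate <- mk_species(list(new_segment(
      lower_pre = complement_of(tt),
      duplex = c(pd[[1L]], x, pd[[2L]]),
      upper_post = "fluor"
    )))
    tibble(species = gate, conc_nM = concentration, role = paste0("reporter_", x))
  })
  new_gate("reporter", id, input_port, character(), bind_rows(rows),
           meta = list(fluor = fluor, concentration = concentration))
}

# ---------------------------------------------------------------------------
# Gate-library configuration files
# ---------------------------------------------------------------------------

#' Read a gate-library configuration (YAML)
#'
#' Each entry names a gate kind and its ports; mapping entries give `K` and
#' the table as a bit-string of length `2^K`, logic entries a gate name,
#' fan-out entries the degree `N`.  Concentrations are optional and default
#' to the unit concentration.
#'
#' @param path YAML file: a list of entries with fields `kind`
#'   (`mapping`, `logic`, `amplification`, `fanout`, `reporter`), `ports`
#'   (named: `inputs`, `output` as appropriate), and kind-specific fields
#'   (`K`, `table`, `logic`, `N`, `concentration` in nM).
#' @return List of `dsd_gate` objects.
#' @export
read_gate_config <- function(path) {
  entries <- yaml::read_yaml(path)
  map(entries, function(e) {
    conc <- e$concentration %||% DSD_UNIT_NM
    switch(e$kind,
      mapping = make_mapping_module(e$K, e$table, as.character(e$inputs),
                                    e$output, concentration = conc,
                                    id = e$id %||% NULL),
      logic = make_logic_gate(e$logic, as.character(e$inputs), e$output,
                              concentration = conc, id = e$id %||% NULL),
      amplification = make_amplification_gate(e$input, e$output,
                                              target_concentration = conc,
                                              id = e$id %||% NULL),
      fanout = make_fanout_gate(e$N, e$input, as.character(e$outputs),
                                concentration = conc, id = e$id %||% NULL),
      reporter = make_reporter_gate(e$input, concentration = conc,
                                    id = e$id %||% NULL),
      abort(sprintf("unknown gate kind '%s' in config", e$kind)))
  })
}
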