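# ---------------------------------------------------------------------------
# Scaffold view of a complex
#
# Every complex in this gate architecture is a single lower backbone strand
# with one or more upper strands ("occupants") each pairing a contiguous run
# of backbone positions; unpaired ends of occupants dangle.  The scaffold
# view flattens the segment notation into (backbone tokens, occupants) so
# displacement can be enumerated positionally.
# ---------------------------------------------------------------------------

as_scaffold <- function(sp) {
  lower <- character()
  occ <- list()
  for (seg in sp$segments) {
    lower <- c(lower, seg$lower_pre)
    if (length(seg$duplex) > 0L) {
      toks <- c(seg$upper_pre, seg$duplex, seg$upper_post)
      occ[[length(occ) + 1L]] <- list(
        tokens = toks,
        arm_from = length(seg$upper_pre) + 1L,
        arm_len = length(seg$duplex),
        pos = length(lower) + 1L
      )
      lower <- c(lower, complement_of(seg$duplex))
    }
  }
  list(lower = lower, occ = occ)
}

scaffold_species <- function(scaf) {
  lower <- scaf$lower
  occ <- scaf$occ[order(map_int(scaf$occ, "pos"))]
  segs <- list()
  pending <- character()
  pos <- 1L
  for (o in occ) {
    if (o$pos > pos) {
      pending <- c(pending, lower[pos:(o$pos - 1L)])
    }
    arm_to <- o$arm_from + o$arm_len - 1L
    segs[[length(segs) + 1L]] <- new_segment(
      lower_pre = pending,
      upper_pre = if (o$arm_from > 1L) o$tokens[1:(o$arm_from - 1L)] else character(),
      duplex = o$tokens[o$arm_from:arm_to],
      upper_post = if (arm_to < length(o$tokens)) o$tokens[(arm_to + 1L):length(o$tokens)] else character()
    )
    pending <- character()
    pos <- o$pos + o$arm_len
  }
  if (pos <= length(lower)) pending <- c(pending, lower[pos:length(lower)])
  if (length(pending) > 0L) {
    segs[[length(segs) + 1L]] <- new_segment(lower_pre = pending)
  }
  new_species(segs)
}

#' Physical strands of a species
#'
#' Returns one entry per physical DNA strand: the lower backbone (if any)
#' and each upper strand, as space-joined token strings.  Used to check
#' strand conservation across reactions.
#'
#' @param sp A `dsd_species` or its DSD text.
#' @return Character vector of strand signatures.
#' @export
species_strands <- function(sp) {
  if (is.character(sp)) sp <- parse_species(sp)
  if (is_free_strand(sp)) return(paste(strand_tokens(sp), collapse = " "))
  scaf <- as_scaffold(sp)
  c(paste(scaf$lower, collapse = " "),
    map_chr(scaf$occ, ~ paste(.x$tokens, collapse = " ")))
}

# ---------------------------------------------------------------------------
# Displacement sites and invader offers
#
# A reaction requires an exposed backbone toehold adjacent to a paired
# region.  An invader whose own toehold lands there displaces the incumbent
# rightward or leftward provided its flanking arm matches the full paired
# run (complete displacement) or the run minus a terminal toehold (toehold
# exchange, the incumbent's last hold dissociating spontaneously).  Both are
# collapsed into single irreversible bimolecular steps in lumped mode.
# ---------------------------------------------------------------------------

site_key <- function(dir, tau, arm) paste(dir, tau, paste(arm, collapse = " "), sep = "|")

complex_sites <- function(scaf) {
  lower <- scaf$lower
  covered <- integer(length(lower))          # occupant index covering a position
  for (j in seq_along(scaf$occ)) {
    o <- scaf$occ[[j]]
    covered[o$pos:(o$pos + o$arm_len - 1L)] <- j
  }
  sites <- list()
  add <- function(dir, i, occ_id, arm, exchange) {
    sites[[length(sites) + 1L]] <<- list(
      dir = dir, i = i, occ_id = occ_id, arm = arm, exchange = exchange,
      key = site_key(dir, complement_of(lower[[i]]), arm)
    )
  }
  for (i in which(covered == 0L)) {
    if (!(is_toehold(lower[[i]]) && is_complement(lower[[i]]))) next
    # rightward invasion into the occupant starting at i + 1
    if (i < length(lower) && covered[[i + 1L]] != 0L) {
      j <- covered[[i + 1L]]
      o <- scaf$occ[[j]]
      if (o$pos == i + 1L) {
        e <- o$pos + o$arm_len - 1L
        arm_full <- complement_of(lower[(i + 1L):e])
        add("R", i, j, arm_full, exchange = FALSE)
        last_tok <- o$tokens[[o$arm_from + o$arm_len - 1L]]
        if (o$arm_len >= 2L && is_toehold(last_tok)) {
          add("R", i, j, arm_full[-length(arm_full)], exchange = TRUE)
        }
      }
    }
    # leftward invasion into the occupant ending at i - 1
    if (i > 1L && covered[[i - 1L]] != 0L) {
      j <- covered[[i - 1L]]
      o <- scaf$occ[[j]]
      if (o$pos + o$arm_len - 1L == i - 1L) {
        b <- o$pos
        arm_full <- complement_of(lower[b:(i - 1L)])
        add("L", i, j, arm_full, exchange = FALSE)
        first_tok <- o$tokens[[o$arm_from]]
        if (o$arm_len >= 2L && is_toehold(first_tok)) {
          add("L", i, j, arm_full[-1L], exchange = TRUE)
        }
      }
    }
  }
  sites
}

strand_offers <- function(toks) {
  offers <- list()
  m <- length(toks)
  for (k in seq_len(m)) {
    tok <- toks[[k]]
    if (!(is_toehold(tok) && !is_complement(tok))) next
    if (k < m) {
      offers[[length(offers) + 1L]] <- list(
        dir = "R", k = k, key = site_key("R", tok, toks[(k + 1L):m])
      )
    }
    if (k > 1L) {
      offers[[length(offers) + 1L]] <- list(
        dir = "L", k = k, key = site_key("L", tok, toks[1:(k - 1L)])
      )
    }
  }
  offers
}

apply_displacement <- function(scaf, site, invader_toks, offer_k) {
  released <- scaf$occ[[site$occ_id]]$tokens
  occ <- scaf$occ[-site$occ_id]
  len <- length(site$arm)
  new_occ <- if (site$dir == "R") {
    list(tokens = invader_toks, arm_from = offer_k, arm_len = len + 1L, pos = site$i)
  } else {
    list(tokens = invader_toks, arm_from = 1L, arm_len = len + 1L, pos = site$i - len)
  }
  occ[[length(occ) + 1L]] <- new_occ
  list(complex = list(lower = scaf$lower, occ = occ), released = released)
}

# ---------------------------------------------------------------------------
# Rate sets
# ---------------------------------------------------------------------------

#' Displacement rate parameters
#'
#' In `"lumped"` mode every enumerated step (toehold binding, branch
#' migration and dissociation collapsed together) is one irreversible
#' bimolecular reaction at `k_displacement`.  The default 3e-5 /nM/s is an
#' effective toehold-exchange rate (the invader gains no net toehold in any
#' of these gates, which slows the lumped step one to two orders of
#' magnitude below fresh-toehold displacement) and puts cascade settling on
#' the 1e2--1e3 s scale.  In `"detailed"` mode each step expands into
#' reversible toehold binding (`k_on`, `k_off`) followed by unimolecular
#' branch migration (`k_migrate`).
#'
#' @param mode `"lumped"` or `"detailed"`.
#' @param k_displacement Lumped bimolecular rate, /nM/s.
#' @param k_on Toehold binding rate, /nM/s (detailed mode).
#' @param k_off Toehold unbinding rate, /s (detailed mode).
#' @param k_migrate Branch-migration/dissociation rate, /s (detailed mode).
#' @return A `dsd_rates` list.
#' @export
dsd_rates <- function(mode = c("lumped", "detailed"), k_displacement = 3e-5,
                      k_on = 3e-4, k_off = 0.1, k_migrate = 1) {
  mode <- match.arg(mode)
  structure(list(mode = mode, k_displacement = k_displacement,
                 k_on = k_on, k_off = k_off, k_migrate = k_migrate),
            class = "dsd_rates")
}

# ---------------------------------------------------------------------------
# CRN container
# ---------------------------------------------------------------------------

#' Construct a chemical reaction network
#'
#' Container for a finite species set with initial concentrations and a list
#' of mass-action reactions.  [close_crn()] builds one from DSD species;
#' this constructor also accepts abstract (non-DSD) species names, which the
#' seesaw baseline uses.
#'
#' @param species Tibble with columns `species` and `conc_nM`.
#' @param reactions Tibble with list-columns `reactants`, `products`
#'   (character vectors of species names), numeric `rate` and character
#'   `kind`.
#' @param rates The `dsd_rates` set used (metadata).
#' @param unit_nM The unit concentration, nM.
#' @return A `dsd_crn`.
#' @export
crn <- function(species, reactions, rates = dsd_rates(), unit_nM = 1e4) {
  stopifnot(all(c("species", "conc_nM") %in% names(species)))
  stopifnot(all(c("reactants", "products", "rate") %in% names(reactions)))
  if (!"kind" %in% names(reactions)) reactions$kind <- "displacement"
  if (!"id" %in% names(reactions)) {
    reactions$id <- map2_chr(reactions$reactants, reactions$products,
      ~ paste(paste(sort(.x), collapse = " + "), "->",
              paste(sort(.y), collapse = " + ")))
  }
  all_named <- unique(c(unlist(reactions$reactants), unlist(reactions$products)))
  missing <- setdiff(all_named, species$species)
  if (length(missing) > 0L)
    abort(paste0("reaction references unknown species: ", missing[[1L]]))
  structure(list(species = as_tibble(species), reactions = as_tibble(reactions),
                 rates = rates, unit_nM = unit_nM),
            class = "dsd_crn")
}

#' @importFrom purrr map2_chr
#' @export
print.dsd_crn <- function(x, ...) {
  cat(sprintf("<dsd_crn> %d species, %d reactions (%s mode)\n",
              nrow(x$species), nrow(x$reactions), x$rates$mode))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.dsd_crn <- function(x, ...) {
  tibble(n_species = nrow(x$species), n_reactions = nrow(x$reactions),
         mode = x$rates$mode, total_nM = sum(x$species$conc_nM))
}

#' @exportS3Method generics::tidy
tidy.dsd_crn <- function(x, ...) {
  mutate(x$reactions,
         reaction = map2_chr(reactants, products,
                             ~ paste(paste(.x, collapse = " + "), "->",
                                     paste(.y, collapse = " + "))))[,
    c("id", "reaction", "rate", "kind")]
}

# ---------------------------------------------------------------------------
# Enumeration and closure
# ---------------------------------------------------------------------------

normalise_pool <- function(pool) {
  if (is.character(pool)) pool <- tibble(species = pool, conc_nM = 0)
  if (inherits(pool, "dsd_species")) pool <- tibble(species = render_species(pool), conc_nM = 0)
  stopifnot(is.data.frame(pool), "species" %in% names(pool))
  if (!"conc_nM" %in% names(pool)) pool$conc_nM <- 0
  pool |>
    mutate(species = map_chr(species, ~ render_species(parse_species(.x)))) |>
    group_by(species) |>
    summarise(conc_nM = sum(conc_nM), .groups = "drop")
}

# Incremental closure engine.  Species are keyed by canonical text; an index
# of displacement sites (complex side) and invader offers (strand side)
# makes each new species a constant-time lookup against everything seen.
closure_engine <- function(pool, rates, expand = TRUE,
                           max_species = 50000L) {
  reg <- new.env(parent = emptyenv())        # text -> entry
  site_idx <- new.env(parent = emptyenv())   # key -> list of (cx, site)
  offer_idx <- new.env(parent = emptyenv())  # key -> list of (strand, k)
  reactions <- new.env(parent = emptyenv())
  k_lump <- rates$k_displacement
  n_species <- 0L
  queue <- character()

  emit <- function(cx_text, site, strand_text, offer_k) {
    entry <- get(cx_text, envir = reg)
    strand_entry <- get(strand_text, envir = reg)
    out <- apply_displacement(entry$scaf, site, strand_entry$tokens, offer_k)
    prod_cx <- render_species(scaffold_species(out$complex))
    prod_strand <- render_species(new_species(list(new_segment(upper_post = out$released))))
    reactants <- c(strand_text, cx_text)
    products <- c(prod_cx, prod_strand)
    if (setequal(reactants, products) &&
        identical(sort(reactants), sort(products))) return(invisible())
    id <- paste(paste(sort(reactants), collapse = " + "), "->",
                paste(sort(products), collapse = " + "))
    if (!exists(id, envir = reactions)) {
      assign(id, list(id = id, reactants = reactants, products = products,
                      rate = k_lump, kind = "displacement"), envir = reactions)
      if (expand) queue <<- c(queue, prod_cx, prod_strand)
    }
    invisible()
  }

  register <- function(text, conc = 0) {
    if (exists(text, envir = reg)) {
      if (conc > 0) {
        e <- get(text, envir = reg); e$conc <- e$conc + conc
        assign(text, e, envir = reg)
      }
      return(invisible())
    }
    n_species <<- n_species + 1L
    if (n_species > max_species)
      abort("CRN closure exceeded the species cap; a gate is producing unbounded species")
    sp <- parse_species(text)
    if (is_free_strand(sp)) {
      toks <- strand_tokens(sp)
      offers <- strand_offers(toks)
      assign(text, list(free = TRUE, tokens = toks, conc = conc, order = n_species),
             envir = reg)
      for (of in offers) {
        lst <- if (exists(of$key, envir = offer_idx)) get(of$key, envir = offer_idx) else list()
        lst[[length(lst) + 1L]] <- list(strand = text, k = of$k)
        assign(of$key, lst, envir = offer_idx)
        # react with every complex already exposing this site
        if (exists(of$key, envir = site_idx)) {
          for (s in get(of$key, envir = site_idx)) emit(s$cx, s$site, text, of$k)
        }
      }
    } else {
      scaf <- as_scaffold(sp)
      sites <- complex_sites(scaf)
      assign(text, list(free = FALSE, scaf = scaf, conc = conc, order = n_species),
             envir = reg)
      for (s in sites) {
        lst <- if (exists(s$key, envir = site_idx)) get(s$key, envir = site_idx) else list()
        lst[[length(lst) + 1L]] <- list(cx = text, site = s)
        assign(s$key, lst, envir = site_idx)
        if (exists(s$key, envir = offer_idx)) {
          for (of in get(s$key, envir = offer_idx)) emit(text, s, of$strand, of$k)
        }
      }
    }
    invisible()
  }

  for (i in seq_len(nrow(pool))) register(pool$species[[i]], pool$conc_nM[[i]])
  while (length(queue) > 0L) {
    text <- queue[[1L]]
    queue <- queue[-1L]
    register(text)
  }

  keys <- ls(reg)
  entries <- map(keys, ~ get(.x, envir = reg))
  ord <- order(map_int(entries, "order"))
  species <- tibble(
    species = keys[ord],
    conc_nM = map_dbl(entries, "conc")[ord],
    free = map_lgl(entries, "free")[ord]
  )
  rxn <- map(ls(reactions), ~ get(.x, envir = reactions))
  rxn_tbl <- if (length(rxn) == 0L) {
    tibble(id = character(), reactants = list(), products = list(),
           rate = numeric(), kind = character())
  } else {
    tibble(
      id = map_chr(rxn, "id"),
      reactants = map(rxn, "reactants"),
      products = map(rxn, "products"),
      rate = map_dbl(rxn, "rate"),
      kind = map_chr(rxn, "kind")
    ) |> arrange(id)
  }
  list(species = species, reactions = rxn_tbl, reg = reg)
}

#' Enumerate displacement reactions over a species pool
#'
#' Single-pass enumeration: reports every toehold-mediated displacement
#' possible among the species given, without adding product species (see
#' [close_crn()] for the fixed point).
#'
#' @param pool Character vector of DSD species texts, or a tibble with a
#'   `species` column (and optional `conc_nM`).
#' @param rates A [dsd_rates()] set.
#' @return Tibble of reactions (`id`, `reactants`, `products`, `rate`,
#'   `kind`).
#' @examples
#' enumerate_reactions(c("{T^*} [mL^ t mR^ T^] <nL^ f nR^>",
#'                       "<aL^ f aR^ T^ mL^ t mR^>"))
#' @export
enumerate_reactions <- function(pool, rates = dsd_rates()) {
  pool <- normalise_pool(pool)
  closure_engine(pool, rates, expand = FALSE)$reactions
}

# expand lumped displacements into bind / unbind / migrate triples
detail_expand <- function(species, reactions, rates) {
  extra_species <- list()
  out <- list()
  reg <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(reactions))) {
    rx <- reactions[i, ]
    strand_text <- rx$reactants[[1L]][[1L]]
    cx_text <- rx$reactants[[1L]][[2L]]
    # rebuild the encounter complex: invader paired at its toehold only
    sp_cx <- parse_species(cx_text)
    scaf <- as_scaffold(sp_cx)
    toks <- strand_tokens(parse_species(strand_text))
    enc_text <- NULL
    for (s in complex_sites(scaf)) {
      for (of in strand_offers(toks)) {
        if (of$key != s$key) next
        occ <- scaf$occ
        occ[[length(occ) + 1L]] <- list(tokens = toks, arm_from = of$k,
                                        arm_len = 1L, pos = s$i)
        enc_text <- render_species(scaffold_species(list(lower = scaf$lower, occ = occ)))
        break
      }
      if (!is.null(enc_text)) break
    }
    if (is.null(enc_text)) next
    if (!exists(enc_text, envir = reg)) {
      assign(enc_text, TRUE, envir = reg)
      extra_species[[length(extra_species) + 1L]] <- enc_text
    }
    out[[length(out) + 1L]] <- list(reactants = rx$reactants[[1L]],
                                    products = enc_text,
                                    rate = rates$k_on, kind = "toehold_binding")
    out[[length(out) + 1L]] <- list(reactants = enc_text,
                                    products = rx$reactants[[1L]],
                                    rate = rates$k_off, kind = "toehold_unbinding")
    out[[length(out) + 1L]] <- list(reactants = enc_text,
                                    products = rx$products[[1L]],
                                    rate = rates$k_migrate, kind = "displacement")
  }
  sp2 <- bind_rows(species,
                   tibble(species = unlist(extra_species) %||% character(),
                          conc_nM = 0, free = FALSE))
  rx2 <- tibble(
    reactants = map(out, ~ as.character(.x$reactants)),
    products = map(out, ~ as.character(.x$products)),
    rate = map_dbl(out, "rate"),
    kind = map_chr(out, "kind")
  )
  rx2$id <- map2_chr(rx2$reactants, rx2$products, function(r, p) {
    paste(paste(sort(r), collapse = " + "), "->", paste(sort(p), collapse = " + "))
  })
  list(species = sp2, reactions = rx2[, c("id", "reactants", "products", "rate", "kind")])
}

#' Close a species pool into a finite CRN
#'
#' Fixed-point iteration: every displacement among known species adds its
#' product species, whose own reactions are then enumerated, until nothing
#' new appears.  Only free single strands invade complexes; waste complexes
#' with no exposed toehold and fluorophore strands take part in no further
#' reaction, so the closure terminates for gate-library circuits.
#'
#' @inheritParams enumerate_reactions
#' @param max_species Safety cap on the closed species count.
#' @return A `dsd_crn`.
#' @examples
#' gate <- make_logic_gate("NOT", input_ports = "m", output_port = "n")
#' pool <- dplyr::bind_rows(gate_species(gate),
#'   tibble::tibble(species = render_species(signal_strand("x", "t", "m", "t")),
#'                  conc_nM = 1e4))
#' close_crn(pool)
#' @export
close_crn <- function(pool, rates = dsd_rates(), max_species = 50000L) {
  pool <- normalise_pool(pool)
  res <- closure_engine(pool, rates, expand = TRUE, max_species = max_species)
  species <- res$species
  reactions <- res$reactions
  if (rates$mode == "detailed") {
    det <- detail_expand(species, reactions, rates)
    species <- det$species
    reactions <- det$reactions
  }
  crn(species, reactions, rates = rates)
}

# ---------------------------------------------------------------------------
# Exports: plain-text reaction list and SBML Level 3
# ---------------------------------------------------------------------------

#' Write a CRN as a plain-text reaction list
#'
#' One `A + B -> C + D @ rate` line per reaction, lexicographically ordered;
#' byte-stable across runs.
#'
#' @param x A `dsd_crn`.
#' @param path Output path.
#' @export
write_reaction_list <- function(x, path) {
  stopifnot(inherits(x, "dsd_crn"))
  lines <- map2_chr(x$reactions$reactants, x$reactions$products,
                    ~ paste(paste(.x, collapse = " + "), "->",
                            paste(.y, collapse = " + ")))
  lines <- sprintf("%s @ %.10g", lines, x$reactions$rate)
  writeLines(lines[order(lines)], path)
  invisible(path)
}

#' Write a CRN as SBML Level 3
#'
#' Species, initial concentrations (nM) and irreversible mass-action kinetic
#' laws.
#'
#' @param x A `dsd_crn`.
#' @param path Output path.
#' @export
write_sbml <- function(x, path) {
  stopifnot(inherits(x, "dsd_crn"))
  ids <- paste0("s", seq_len(nrow(x$species)))
  names(ids) <- x$species$species
  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  model <- xml2::xml_add_child(doc, "model", id = "dsd_crn")
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", size = "1", constant = "true")
  spl <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(x$species))) {
    xml2::xml_add_child(spl, "species",
      id = ids[[i]], name = x$species$species[[i]], compartment = "cell",
      initialConcentration = sprintf("%.10g", x$species$conc_nM[[i]]),
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
  }
  rxl <- xml2::xml_add_child(model, "listOfReactions")
  for (i in seq_len(nrow(x$reactions))) {
    rx <- xml2::xml_add_child(rxl, "reaction", id = paste0("r", i),
                              reversible = "false")
    rl <- xml2::xml_add_child(rx, "listOfReactants")
    for (s in x$reactions$reactants[[i]]) {
      xml2::xml_add_child(rl, "speciesReference", species = ids[[s]],
                          stoichiometry = "1", constant = "true")
    }
    pl <- xml2::xml_add_child(rx, "listOfProducts")
    for (s in x$reactions$products[[i]]) {
      xml2::xml_add_child(pl, "speciesReference", species = ids[[s]],
                          stoichiometry = "1", constant = "true")
    }
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
      xmlns = "http://www.w3.org/1998/Math/MathML")
    ap <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(ap, "times")
    cn <- xml2::xml_add_child(ap, "cn", type = "real")
    xml2::xml_set_text(cn, sprintf("%.10g", x$reactions$rate[[i]]))
    for (s in x$reactions$reactants[[i]]) {
      ci <- xml2::xml_add_child(ap, "ci")
      xml2::xml_set_text(ci, ids[[s]])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
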