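#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select bind_rows arrange group_by summarise
#'   ungroup left_join distinct pull n rename count across
#' @importFrom purrr map map_chr map_int map_dbl map_lgl map2 pmap imap keep
#'   compact walk reduce
#' @importFrom stringr str_detect str_remove str_split str_trim
NULL

# ---------------------------------------------------------------------------
# Domain tokens
#
# A domain is stored as its canonical token string: name, then "^" if it is a
# toehold, then "*" if it is the Watson-Crick complement ("^" always before
# "*").  The logic labels are the two distinguished long domains "t" and "f";
# they sit in the strand body like any other domain, so hybridization itself
# distinguishes logic 1 from logic 0.
# ---------------------------------------------------------------------------

#' Build a domain token
#'
#' @param name Domain name (letters, digits, `_`, `#`).
#' @param toehold Is this a (short) toehold domain?
#' @param complement Is this the complementary strand of the domain?
#' @return A canonical token string such as `"mL^"` or `"T^*"`.
#' @examples
#' domain("T", toehold = TRUE, complement = TRUE)
#' @export
domain <- function(name, toehold = FALSE, complement = FALSE) {
  stopifnot(is.character(name), length(name) >= 1L)
  paste0(name, ifelse(toehold, "^", ""), ifelse(complement, "*", ""))
}

#' Domain token accessors
#'
#' `dom_name()` strips the flags, `is_toehold()`/`is_complement()` test the
#' flags, `complement_of()` toggles the complement flag and `is_label()`
#' tests whether a token is one of the two logic labels `t` / `f`.
#'
#' @param tok Character vector of domain tokens.
#' @return `dom_name()` a character vector; the predicates logical vectors.
#' @name domain-accessors
NULL

#' @rdname domain-accessors
#' @export
dom_name <- function(tok) sub("\\^?\\*?$", "", tok)

#' @rdname domain-accessors
#' @export
is_toehold <- function(tok) grepl("\\^\\*?$", tok)

#' @rdname domain-accessors
#' @export
is_complement <- function(tok) grepl("\\*$", tok)

#' @rdname domain-accessors
#' @export
complement_of <- function(tok) {
  ifelse(is_complement(tok), sub("\\*$", "", tok), paste0(tok, "*"))
}

#' @rdname domain-accessors
#' @export
is_label <- function(tok) tok %in% c("t", "f")

#' Can two domains hybridize?
#'
#' Two domains pair iff they share name and toehold flag and carry opposite
#' complement flags.  The predicate is symmetric and anti-reflexive.
#'
#' @param a,b Domain tokens.
#' @return Logical.
#' @export
can_hybridize <- function(a, b) {
  dom_name(a) == dom_name(b) &
    is_toehold(a) == is_toehold(b) &
    is_complement(a) != is_complement(b)
}

valid_token <- function(tok) {
  grepl("^[A-Za-z0-9_.#]+\\^?\\*?$", tok)
}

# ---------------------------------------------------------------------------
# Species
#
# A species is an ordered list of segments joined by ":".  Each segment holds
# up to four parts, rendered in canonical order
#     {lower_pre} <upper_pre> [duplex] <upper_post>
# where the duplex is written as its upper-strand tokens (the backbone below
# is their implied complement), `{...}` is an unpaired stretch of the lower
# backbone and `<...>` are unpaired upper-strand overhangs.  A free single
# strand is the special case of one segment with only an upper part.
# ---------------------------------------------------------------------------

new_segment <- function(lower_pre = character(), upper_pre = character(),
                        duplex = character(), upper_post = character()) {
  list(lower_pre = lower_pre, upper_pre = upper_pre,
       duplex = duplex, upper_post = upper_post)
}

new_species <- function(segments) {
  structure(list(segments = segments), class = "dsd_species")
}

#' Is a species a free single strand?
#'
#' @param sp A `dsd_species`.
#' @return Logical.
#' @export
is_free_strand <- function(sp) {
  segs <- sp$segments
  length(segs) == 1L &&
    length(segs[[1L]]$duplex) == 0L &&
    length(segs[[1L]]$lower_pre) == 0L &&
    length(segs[[1L]]$upper_pre) == 0L &&
    length(segs[[1L]]$upper_post) > 0L
}

#' Tokens of a free single strand
#'
#' @param sp A free-strand `dsd_species`.
#' @return Character vector of domain tokens, 5' to 3' as written.
#' @export
strand_tokens <- function(sp) {
  if (!is_free_strand(sp)) abort("not a free single strand")
  sp$segments[[1L]]$upper_post
}

#' Parse a species from DSD notation
#'
#' Accepts the segment notation used throughout the gate listings:
#' `{...}` lower-backbone overhang, `<...>` upper strand / overhang, `[...]`
#' duplex (written as upper-strand tokens), `^` toehold suffix, `*`
#' complement suffix and `:` joining segments.  Tokens are separated by
#' whitespace.
#'
#' @param text A single string, e.g. `"{T^*} [mL^ f mR^ T^] <nL^ t nR^>"`.
#' @return A `dsd_species`.
#' @examples
#' parse_species("<mL^ t mR^ T^ nL^ t nR^>")
#' @export
parse_species <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  n <- nchar(text)
  segs <- list()
  seg <- new_segment()
  seen <- character()      # part kinds already seen in this segment
  i <- 1L
  flush_segment <- function() {
    if (length(seen) > 0L) segs[[length(segs) + 1L]] <<- seg
    seg <<- new_segment()
    seen <<- character()
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == ":") {
      if (length(seen) == 0L)
        abort(sprintf("syntax error at position %d: empty segment before ':'", i))
      flush_segment(); i <- i + 1L; next
    }
    open <- ch
    close <- switch(open, "{" = "}", "<" = ">", "[" = "]", NA_character_)
    if (is.na(close))
      abort(sprintf("syntax error at position %d: unexpected '%s'", i, ch))
    j <- regexpr(close, substr(text, i + 1L, n), fixed = TRUE)
    if (j < 0L)
      abort(sprintf("syntax error at position %d: unbalanced '%s'", i, open))
    inner <- substr(text, i + 1L, i + j - 1L)
    toks <- strsplit(str_trim(inner), "\\s+")[[1L]]
    toks <- toks[nzchar(toks)]
    bad <- toks[!valid_token(toks)]
    if (length(bad) > 0L)
      abort(sprintf("syntax error at position %d: invalid domain token '%s'",
                    i, bad[[1L]]))
    kind <- switch(open,
      "{" = "lower_pre",
      "[" = "duplex",
      "<" = if ("duplex" %in% seen) "upper_post" else "upper_pre")
    if (kind %in% seen)
      abort(sprintf("syntax error at position %d: repeated '%s...%s' part in segment",
                    i, open, close))
    ok_order <- switch(kind,
      lower_pre = length(seen) == 0L,
      upper_pre = !("duplex" %in% seen),
      duplex = TRUE,
      upper_post = TRUE)
    if (!ok_order)
      abort(sprintf("syntax error at position %d: '%s...%s' out of canonical order",
                    i, open, close))
    seg[[kind]] <- toks
    seen <- c(seen, kind)
    i <- i + j + 1L
  }
  if (length(seen) == 0L && length(segs) == 0L)
    abort("syntax error: empty species text")
  if (length(seen) == 0L)
    abort("syntax error: empty segment after trailing ':'")
  flush_segment()
  # a bare upper part with nothing else is a free strand: normalise the slot
  segs <- map(segs, function(s) {
    if (length(s$duplex) == 0L && length(s$upper_pre) > 0L &&
        length(s$upper_post) == 0L) {
      s$upper_post <- s$upper_pre
      s$upper_pre <- character()
    }
    s
  })
  sp <- new_species(segs)
  validate_species(sp)
  sp
}

validate_species <- function(sp) {
  segs <- sp$segments
  for (k in seq_along(segs)) {
    s <- segs[[k]]
    if (length(s$duplex) == 0L && (length(s$upper_pre) > 0L))
      abort("invalid species: upper overhang without a duplex to anchor it")
    if (length(s$duplex) == 0L && length(s$upper_post) > 0L && length(segs) > 1L)
      abort("invalid species: dangling upper part inside a multi-segment complex")
  }
  invisible(sp)
}

render_part <- function(toks, open, close) {
  if (length(toks) == 0L) return(NULL)
  paste0(open, paste(toks, collapse = " "), close)
}

#' Render a species to canonical DSD notation
#'
#' Deterministic inverse of [parse_species()]: single spaces between tokens,
#' parts in the order `{lower} <upper> [duplex] <upper>`, segments joined by
#' `:`, empty parts omitted.
#'
#' @param sp A `dsd_species`.
#' @return A single string.
#' @export
render_species <- function(sp) {
  stopifnot(inherits(sp, "dsd_species"))
  segs <- map_chr(sp$segments, function(s) {
    parts <- c(render_part(s$lower_pre, "{", "}"),
               render_part(s$upper_pre, "<", ">"),
               render_part(s$duplex, "[", "]"),
               render_part(s$upper_post, "<", ">"))
    paste(parts, collapse = " ")
  })
  paste(segs, collapse = ":")
}

#' @export
print.dsd_species <- function(x, ...) {
  cat(render_species(x), "\n")
  invisible(x)
}

#' @export
format.dsd_species <- function(x, ...) render_species(x)

# ---------------------------------------------------------------------------
# Signal strands and logic values
# ---------------------------------------------------------------------------

#' Domain pair naming a wire port
#'
#' A port named `"A0"` is carried by the flanking toehold domains
#' `A0L^` / `A0R^`.
#'
#' @param port Port name.
#' @return Character vector `c(left, right)` of domain tokens.
#' @export
port_domains <- function(port) {
  c(domain(paste0(port, "L"), toehold = TRUE),
    domain(paste0(port, "R"), toehold = TRUE))
}

#' Construct a domain-label signal strand
#'
#' A signal strand has the canonical shape
#' `<aL^ x aR^ T^ bL^ y bR^>`: a left (receiving) half whose label `x`
#' records the upstream value, a central toehold, and a right (passing) half
#' whose label `y` *is* the logic value of the strand.
#'
#' @param left_port,right_port Port names for the two flanking domain pairs.
#' @param left_label,right_label `"t"` or `"f"`.
#' @param toehold Name of the universal toehold domain.
#' @return A free-strand `dsd_species`.
#' @examples
#' signal_strand("A0", "t", "A0", "t")
#' @export
signal_strand <- function(left_port, left_label, right_port, right_label,
                          toehold = "T") {
  stopifnot(left_label %in% c("t", "f"), right_label %in% c("t", "f"))
  lp <- port_domains(left_port)
  rp <- port_domains(right_port)
  toks <- c(lp[[1L]], left_label, lp[[2L]],
            domain(toehold, toehold = TRUE),
            rp[[1L]], right_label, rp[[2L]])
  new_species(list(new_segment(upper_post = toks)))
}

signal_shape <- function(toks) {
  length(toks) == 7L &&
    is_toehold(toks[[4L]]) && !is_complement(toks[[4L]]) &&
    is_label(toks[[2L]]) && is_label(toks[[6L]]) &&
    all(is_toehold(toks[c(1L, 3L, 5L, 7L)])) &&
    !any(is_complement(toks[c(1L, 3L, 5L, 7L)]))
}

fluor_shape <- function(toks) {
  length(toks) == 4L && dom_name(toks[[4L]]) == "fluor" && is_label(toks[[2L]])
}

#' Logic value of a signal strand
#'
#' The value is carried solely by the right-hand label: `t` is logic 1, `f`
#' is logic 0; the left label only records where the strand came from.
#' Fluorophore strands `<bL^ x bR^ fluor>` are read the same way.
#'
#' @param sp A free-strand `dsd_species` (or its DSD-notation text).
#' @return `1L` or `0L`.
#' @export
logic_value <- function(sp) {
  if (is.character(sp)) sp <- parse_species(sp)
  if (!is_free_strand(sp))
    abort("logic_value() expects a free signal strand")
  toks <- strand_tokens(sp)
  if (signal_shape(toks)) return(if (toks[[6L]] == "t") 1L else 0L)
  if (fluor_shape(toks)) return(if (toks[[2L]] == "t") 1L else 0L)
  abort("strand does not have the canonical signal shape <aL^ x aR^ T^ bL^ y bR^>")
}

# ---------------------------------------------------------------------------
# Species files
# ---------------------------------------------------------------------------

#' Read / write DSD-notation species files
#'
#' One species per line; blank lines and `#` comments are ignored.  An
#' optional trailing `@ <concentration>` (in nM) is parsed into the
#' `conc_nM` column; the writer emits it for species with non-zero
#' concentration.  Output is canonical and byte-stable.
#'
#' @param path File path.
#' @param x A tibble with columns `species` (DSD text) and optionally
#'   `conc_nM`, or a character vector of species.
#' @return `read_species_file()` a tibble with `species` and `conc_nM`.
#' @export
read_species_file <- function(path) {
  lines <- readLines(path)
  lines <- str_trim(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  conc <- rep(NA_real_, length(lines))
  has_at <- grepl("@", lines, fixed = TRUE)
  conc[has_at] <- as.numeric(str_trim(sub("^.*@", "", lines[has_at])))
  text <- str_trim(sub("@.*$", "", lines))
  tibble(
    species = map_chr(text, ~ render_species(parse_species(.x))),
    conc_nM = ifelse(is.na(conc), 0, conc)
  )
}

#' @rdname read_species_file
#' @export
write_species_file <- function(x, path) {
  if (is.character(x)) x <- tibble(species = x, conc_nM = 0)
  stopifnot("species" %in% names(x))
  conc <- if ("conc_nM" %in% names(x)) x$conc_nM else rep(0, nrow(x))
  canon <- map_chr(x$species, ~ render_species(parse_species(.x)))
  lines <- ifelse(conc > 0, sprintf("%s @ %.10g", canon, conc), canon)
  writeLines(lines, path)
  invisible(path)
}
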