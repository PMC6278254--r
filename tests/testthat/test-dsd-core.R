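test_that("reference gate strands parse into the expected structure", {
  sp <- parse_species("{T^*} [mL^ f mR^ T^] <nL^ t nR^>")
  expect_length(sp$segments, 1L)
  seg <- sp$segments[[1L]]
  expect_equal(seg$lower_pre, "T^*")
  expect_length(seg$duplex, 4L)
  expect_length(seg$upper_post, 3L)

  fuel <- parse_species("<mL^ t mR^ T^ nL^ t nR^>")
  expect_true(is_free_strand(fuel))
  expect_length(strand_tokens(fuel), 7L)

  two <- parse_species("{T^*} [mL^ f mR^ T^]:[nL^ t nR^ T^] <hL^ f hR^>")
  expect_length(two$segments, 2L)
  expect_equal(two$segments[[2L]]$upper_post, c("hL^", "f", "hR^"))
})

test_that("rendering is canonical and whitespace-insensitive", {
  messy <- "  {T^*}[mL^ f    mR^ T^]  <nL^ t nR^> "
  expect_equal(render_species(parse_species(messy)),
               "{T^*} [mL^ f mR^ T^] <nL^ t nR^>")
  # parse . render is the identity on canonical text
  canon <- "{T^*} [mL^ f mR^ T^] <nL^ f nR^>"
  expect_equal(render_species(parse_species(canon)), canon)
})

test_that("parser/printer round trip is the identity on random species", {
  set.seed(7)
  for (i in 1:40) {
    sp <- if (i %% 2L == 0L) rand_free_strand() else rand_complex()
    txt <- render_species(sp)
    expect_equal(render_species(parse_species(txt)), txt)
  }
})

test_that("malformed input fails with a positioned syntax error", {
  expect_error(parse_species("{T^* [mL^ f mR^]"), "unbalanced")
  expect_error(parse_species("<mL^ t%bad>"), "invalid domain token")
  expect_error(parse_species("<a> : <b> :"), "empty segment")
  expect_error(parse_species("[a b] )"), "position")
  expect_error(parse_species(""), "empty species")
})

test_that("logic value is the right-hand label, for all four label pairs", {
  expect_equal(logic_value(signal_strand("a", "f", "b", "t")), 1L)
  expect_equal(logic_value(signal_strand("a", "t", "b", "t")), 1L)
  expect_equal(logic_value(signal_strand("a", "f", "b", "f")), 0L)
  expect_equal(logic_value(signal_strand("a", "t", "b", "f")), 0L)
  # fluorophore strands carry their label the same way
  expect_equal(logic_value("<J0L^ t J0R^ fluor>"), 1L)
  expect_equal(logic_value("<J3L^ f J3R^ fluor>"), 0L)
  expect_error(logic_value("<mL^ t mR^>"), "canonical signal shape")
})

test_that("hybridization is symmetric, anti-reflexive and label-sensitive", {
  toks <- c("mL^", "t", "f", "T^", "T^*", "mL^*", "t*")
  for (a in toks) {
    expect_false(can_hybridize(a, a))
    for (b in toks) expect_equal(can_hybridize(a, b), can_hybridize(b, a))
  }
  expect_true(can_hybridize("t", "t*"))
  expect_false(can_hybridize("t", "f*"))      # labels are distinct domains
  expect_false(can_hybridize("T^", "T*"))     # toehold flag must match
  expect_true(can_hybridize("T^", "T^*"))
  expect_equal(complement_of(complement_of("mL^")), "mL^")
})

test_that("species files round-trip bit-exactly with comments and concentrations", {
  tbl <- tibble::tibble(
    species = c("{T^*} [mL^ f mR^ T^] <nL^ t nR^>", "<aL^ t aR^ T^ bL^ f bR^>"),
    conc_nM = c(10000, 0)
  )
  path <- withr::local_tempfile(fileext = ".txt")
  write_species_file(tbl, path)
  writeLines(c("# a comment", readLines(path)), path)
  back <- read_species_file(path)
  expect_equal(back$species, tbl$species)
  expect_equal(back$conc_nM, tbl$conc_nM)
  # writer output is byte-stable
  p2 <- withr::local_tempfile(fileext = ".txt")
  write_species_file(back, p2)
  p3 <- withr::local_tempfile(fileext = ".txt")
  write_species_file(read_species_file(p2), p3)
  expect_identical(readLines(p2), readLines(p3))
})
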