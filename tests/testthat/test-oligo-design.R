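published_records <- tibble::tribble(
  ~id,          ~kind,      ~property, ~value, ~dtype,      ~unit,
  "start",      "terminal", "start",   NA,     NA,          NA,
  "(cty,GZ)",   "vertex",   "cty",     "GZ",   "string",    "undefined",
  "(qa,E)",     "vertex",   "qa",      "E",    "string",    "undefined",
  "(qa,null)",  "vertex",   "qa",      NA,     "undefined", "undefined",
  "(cc,0)",     "vertex",   "cc",      "0",    "integer",   "%",
  "(cc,null)",  "vertex",   "cc",      NA,     "undefined", "undefined",
  "end",        "terminal", "end",     NA,     NA,          NA
)

test_that("all published vertex oligos decode to their labelled records", {
  for (i in seq_len(nrow(published_records))) {
    rec <- decode_vertex(published_oligos[[published_records$id[i]]])
    expect_identical(rec$kind, published_records$kind[i], info = published_records$id[i])
    expect_identical(rec$property, published_records$property[i])
    expect_identical(rec$value, published_records$value[i])
    expect_identical(rec$dtype, published_records$dtype[i])
    expect_identical(rec$unit, published_records$unit[i])
  }
})

test_that("encode_vertex reproduces published oligos up to degenerate choice", {
  cases <- list(
    list(id = "(cty,GZ)", args = list("cty", "GZ", "string", "undefined"),
         tu = "TCGATGCA"),
    list(id = "(qa,E)", args = list("qa", "E", "string", "undefined"),
         tu = "TCGATGCA"),
    list(id = "(cc,0)", args = list("cc", "0", "integer", "%"),
         tu = "CATGGCAT"),
    list(id = "(qa,null)", args = list("qa", NA, "undefined", "undefined"),
         tu = "TGCATGCA")
  )
  for (cs in cases) {
    v <- do.call(encode_vertex, c(cs$args, seed = 4))
    expect_identical(nchar(v), 48L)
    expect_true(degenerate_equal(v, published_oligos[[cs$id]]), info = cs$id)
    # type and unit codes are verbatim, byte-exact
    expect_identical(substr(v, 25, 32), cs$tu)
  }
})

test_that("terminal oligos decode back to their padded labels", {
  for (lab in c("start", "end")) {
    t <- encode_terminal(lab, seed = 8)
    expect_identical(nchar(t), 48L)
    expect_true(degenerate_equal(t, published_oligos[[lab]]))
    expect_identical(decode_vertex(t)$property, lab)
  }
  expect_error(encode_terminal("middle"))
})

test_that("vertex encode/decode round-trips over random records", {
  types <- dna_type_codes()$name
  withr::with_seed(31, {
    for (i in 1:30) {
      dtype <- sample(setdiff(types, "undefined"), 1)
      unit <- sample(c("undefined", "%"), 1)
      name <- paste(sample(letters, sample(1:3, 1)), collapse = "")
      value <- if (dtype == "integer") {
        as.character(sample(0:99, 1))
      } else {
        paste(sample(LETTERS, sample(1:2, 1)), collapse = "")
      }
      v <- encode_vertex(name, value, dtype, unit)
      rec <- decode_vertex(v)
      expect_identical(rec$property, name)
      expect_identical(rec$value, value)
      expect_identical(rec$dtype, dtype)
      expect_identical(rec$unit, unit)
    }
  })
})

test_that("oversized fields and unregistered codes are rejected", {
  expect_error(encode_vertex("city", "GZ"), "3-character")
  expect_error(encode_vertex("cty", "GZH"), "2-character")
  expect_error(encode_vertex("cty", "GZ", dtype = "complex"), "unregistered")
  expect_error(encode_vertex("cty", "GZ", unit = "meter"), "unregistered")
  expect_error(encode_vertex("cty", NA, dtype = "string"), "undefined")
})

test_that("field widths are configurable and scale 8 nt per character", {
  v <- encode_vertex("spres", "1.85", dtype = "float", unit = "undefined",
                     seed = 2, name_width = 5, value_width = 4)
  expect_identical(nchar(v), 8L * 5L + 8L + 8L * 4L)
  rec <- decode_vertex(v, name_width = 5, value_width = 4)
  expect_identical(rec$value, "1.85")
  expect_identical(rec$property, "spres")
})

test_that("encode_edge reproduces the published edge oligo exactly", {
  e <- encode_edge(published_oligos[["(cty,GZ)"]], published_oligos[["(qa,E)"]])
  expect_identical(e, published_edge_cty_qa)
})

test_that("edge oligos complement the adjoining vertex halves", {
  expect_identical(
    toupper(dna_complement(substr(published_edge_cty_qa, 1, 24))),
    toupper(substr(published_oligos[["(cty,GZ)"]], 25, 48))
  )
  withr::with_seed(13, {
    for (i in 1:10) {
      vi <- encode_vertex(paste(sample(letters, 2), collapse = ""), "A")
      vj <- encode_vertex(paste(sample(letters, 2), collapse = ""), "B")
      e <- encode_edge(vi, vj)
      expect_identical(nchar(e), 48L)
      expect_identical(toupper(dna_complement(substr(e, 1, 24))),
                       toupper(substr(vi, 25, 48)))
      expect_identical(toupper(dna_complement(substr(e, 25, 48))),
                       toupper(substr(vj, 1, 24)))
    }
  })
  expect_error(encode_edge("ACGT", published_oligos[["(qa,E)"]]), "48-nt")
})

test_that("the null marker is TGCATGCA and appears exactly where expected", {
  expect_identical(null_marker(), "TGCATGCA")
  expect_identical(substr(published_oligos[["(qa,null)"]], 25, 32),
                   null_marker())
  expect_false(grepl(null_marker(), toupper(published_oligos[["(qa,E)"]]),
                     fixed = TRUE) &&
                 substr(published_oligos[["(qa,E)"]], 25, 32) == null_marker())
  v <- encode_vertex("ct", NA, "undefined", "undefined", seed = 6)
  expect_identical(substr(v, 25, 32), null_marker())
})

test_that("codebooks are extensible, collision-checked and serialisable", {
  uc <- register_code(dna_unit_codes(), "meter", "AATT")
  expect_identical(nrow(uc), 3L)
  expect_error(register_code(uc, "meter2", "AATT"), "already registered")
  expect_error(register_code(uc, "meter", "CCGG"), "already registered")
  # a unit code may reuse a type-code oligo (TGCA serves both registries)
  expect_identical(lookup <- dna_unit_codes()$oligo[1], "TGCA")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_codebook(uc, path)
  expect_identical(read_codebook(path), uc)
})
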