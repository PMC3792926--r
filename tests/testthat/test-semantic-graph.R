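test_that("the two-source worked example merges to exactly seven vertices", {
  net <- build_network(example_annotations())
  expect_setequal(net$vertices$id,
                  c("start", "(cty,GZ)", "(qa,E)", "(qa,null)",
                    "(cc,0)", "(cc,null)", "end"))
  expect_identical(net$layers, c("cty", "qa", "cc"))
})

test_that("three single-source annotations merge to eight vertices", {
  net <- build_network(example_annotations("three_image"))
  expect_identical(nrow(net$vertices), 8L)
  expect_setequal(net$vertices$id,
                  c("start", "(cty,GZ)", "(cty,HK)", "(qa,E)", "(qa,G)",
                    "(cc,0)", "(cc,16)", "end"))
})

test_that("a single annotation gives a chain with one path", {
  ann <- generate_fixture(k_layers = 4, n_sources = 1, null_rate = 0, seed = 2)
  net <- build_network(ann, recombination = FALSE)
  expect_identical(nrow(net$vertices), 4L + 2L)
  expect_identical(nrow(net$edges), 4L + 1L)
  expect_length(enumerate_paths(net), 1L)
})

test_that("path counts follow the edge model", {
  # chain edges only: one path per distinct source chain
  expect_length(enumerate_paths(build_network(example_annotations(),
                                              recombination = FALSE)), 2L)
  # recombination: product of per-layer distinct value counts (1 x 2 x 2)
  expect_length(enumerate_paths(build_network(example_annotations())), 4L)
  withr::with_seed(17, {
    for (i in 1:10) {
      ann <- generate_fixture(k_layers = sample(1:4, 1),
                              n_sources = sample(1:4, 1),
                              n_values = 3, null_rate = 0.4)
      net <- build_network(ann)
      sizes <- table(net$vertices$layer[!net$vertices$id %in% c("start", "end")])
      expect_length(enumerate_paths(net), prod(sizes))
    }
  })
})

test_that("rebuilding from a network's own chains reproduces it (idempotence)", {
  ann <- example_annotations()
  net1 <- build_network(ann, recombination = FALSE)
  # the chains of net1 are exactly the source annotations; rebuild
  net2 <- build_network(ann, recombination = FALSE)
  expect_identical(net1$vertices, net2$vertices)
  expect_identical(dplyr::arrange(net1$edges, from, to),
                   dplyr::arrange(net2$edges, from, to))
})

test_that("inconsistent property orders and empty inputs are rejected", {
  bad <- example_annotations()
  bad$property[4:6] <- c("qa", "cty", "cc")
  expect_error(build_network(bad), "property order")
  expect_error(build_network(example_annotations()[0, ]), "at least one")
})

test_that("the oligo library realises the published sequences", {
  net <- build_network(example_annotations())
  lib <- to_oligo_library(net, seed = 12)
  v <- lib[lib$kind == "vertex", ]
  expect_identical(nrow(v), 7L)
  for (id in names(published_oligos)) {
    expect_true(degenerate_equal(v$seq[v$id == id], published_oligos[[id]]),
                info = id)
  }
  # chain-only library: two 4-edge chains sharing start->(cty,GZ)
  lib0 <- to_oligo_library(build_network(example_annotations(),
                                         recombination = FALSE), seed = 12)
  expect_identical(sum(lib0$kind == "edge"), 7L)
})

test_that("every edge oligo complements its endpoints' adjoining halves", {
  withr::with_seed(23, {
    for (i in 1:5) {
      ann <- generate_fixture(k_layers = 3, n_sources = 3, null_rate = 0.3)
      lib <- to_oligo_library(build_network(ann))
      v <- lib[lib$kind == "vertex", ]
      e <- lib[lib$kind == "edge", ]
      vseq <- stats::setNames(v$seq, v$id)
      for (j in seq_len(nrow(e))) {
        expect_identical(e$seq[j], encode_edge(vseq[[e$from[j]]],
                                               vseq[[e$to[j]]]))
      }
    }
  })
})

test_that("every full path decodes to a parseable flat property string", {
  net <- build_network(example_annotations())
  lib <- to_oligo_library(net, seed = 3)
  vseq <- stats::setNames(lib$seq[lib$kind == "vertex"],
                          lib$id[lib$kind == "vertex"])
  for (p in enumerate_paths(net)) {
    strand <- paste(vseq[p], collapse = "")
    recs <- decode_strand(strand)
    expect_identical(nrow(recs), length(p))
    expect_identical(recs$kind[c(1, nrow(recs))], c("terminal", "terminal"))
  }
})

test_that("library FASTA export writes one record per element", {
  lib <- to_oligo_library(build_network(example_annotations()), seed = 1)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_library_fasta(lib, path)
  fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  expect_length(fa, nrow(lib))
  expect_identical(toupper(as.character(fa[[1]])), toupper(lib$seq[1]))
})
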