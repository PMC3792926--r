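test_that("the worked example fuses to the single complete record", {
  for (mode in c("exhaustive", "sampled")) {
    fus <- semantic_fuse(example_annotations(), mode = mode,
                         n_molecules = 10000, seed = 101)
    rec <- tidy(fus)
    expect_identical(nrow(rec), 1L, info = mode)
    expect_identical(rec$flat_text, published_flat_text)
    expect_identical(rec$n_vertices, 5L)
    expect_identical(rec$length_nt, 240L)
    entries <- rec$entries[[1]]
    expect_identical(entries$property, c("cty", "qa", "cc"))
    expect_identical(entries$value, c("GZ", "E", "0"))
    expect_identical(entries$dtype, c("string", "string", "integer"))
    expect_identical(entries$unit, c("undefined", "undefined", "%"))
    expect_identical(rec$flat_text, fuse_oracle(example_annotations())$flat_text)
  }
})

test_that("a single complete source passes through fusion unchanged", {
  ann <- example_annotations("three_image")
  one <- ann[ann$source_id == "E1EB7", ]
  fus <- semantic_fuse(one, mode = "exhaustive")
  rec <- tidy(fus)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$entries[[1]]$value, c("GZ", "E", "0"))
})

test_that("the oracle handles complementary and conflicting sources", {
  complementary <- tibble::tibble(
    source_id = rep(c("s1", "s2"), each = 2),
    property = rep(c("p", "q"), 2),
    value = c("A", NA, NA, "B"),
    dtype = c("string", "undefined", "undefined", "string"),
    unit = "undefined"
  )
  rec <- fuse_oracle(complementary)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$entries[[1]]$value, c("A", "B"))

  conflicting <- tibble::tibble(
    source_id = c("s1", "s2"), property = "p", value = c("A", "B"),
    dtype = "string", unit = "undefined"
  )
  rec2 <- fuse_oracle(conflicting)
  expect_identical(nrow(rec2), 2L)
  expect_setequal(vapply(rec2$entries, function(e) e$value, character(1)),
                  c("A", "B"))
})

test_that("exhaustive fusion equals the graph-search oracle on random fixtures", {
  withr::with_seed(47, {
    for (i in 1:25) {
      ann <- generate_fixture(k_layers = sample(1:4, 1),
                              n_sources = sample(1:4, 1),
                              n_values = sample(1:3, 1),
                              null_rate = stats::runif(1, 0, 0.6),
                              guarantee_complete = sample(c(TRUE, FALSE), 1))
      fus <- semantic_fuse(ann, mode = "exhaustive", seed = i)
      expect_identical(tidy(fus)$flat_text, fuse_oracle(ann)$flat_text)
    }
  })
})

test_that("sampled fusion converges to the oracle at 10,000 molecules", {
  withr::with_seed(53, {
    for (i in 1:5) {
      ann <- generate_fixture(k_layers = sample(2:4, 1), n_sources = 2,
                              null_rate = 0.3)
      fus <- semantic_fuse(ann, mode = "sampled", n_molecules = 10000,
                           seed = 1000 + i)
      expect_identical(tidy(fus)$flat_text, fuse_oracle(ann)$flat_text)
    }
  })
})

test_that("survivor strands always have K+2 vertices and 48(K+2) nt", {
  withr::with_seed(59, {
    for (k in 1:4) {
      ann <- generate_fixture(k_layers = k, n_sources = 3, null_rate = 0.3)
      fus <- semantic_fuse(ann, mode = "exhaustive")
      rec <- tidy(fus)
      if (nrow(rec) > 0) {
        expect_true(all(rec$n_vertices == k + 2L))
        expect_true(all(rec$length_nt == 48L * (k + 2L)))
      }
    }
  })
})

test_that("fusion is empty exactly when no null-free assignment exists", {
  # one layer is null in every source: nothing can survive screening
  ann <- tibble::tibble(
    source_id = rep(c("s1", "s2"), each = 2),
    property = rep(c("p", "q"), 2),
    value = c("A", NA, "B", NA),
    dtype = c("string", "undefined", "string", "undefined"),
    unit = "undefined"
  )
  fus <- semantic_fuse(ann, mode = "exhaustive")
  expect_identical(nrow(tidy(fus)), 0L)
  expect_false(fus$detected)
  expect_identical(nrow(fuse_oracle(ann)), 0L)
})

test_that("recombination is what lets values recombine across sources", {
  # the worked example's result path uses an edge absent from both chains
  fus0 <- semantic_fuse(example_annotations(), mode = "exhaustive",
                        recombination = FALSE)
  expect_identical(nrow(tidy(fus0)), 0L)
  fus1 <- semantic_fuse(example_annotations(), mode = "exhaustive")
  expect_identical(nrow(tidy(fus1)), 1L)
})

test_that("summary and plotting accessors work", {
  fus <- semantic_fuse(example_annotations(), mode = "sampled",
                       n_molecules = 2000, seed = 5)
  g <- glance(fus)
  expect_identical(g$k_layers, 3L)
  expect_identical(g$n_records, nrow(tidy(fus)))
  expect_true(g$detected)
  expect_s3_class(autoplot(fus), "ggplot")
  expect_s3_class(autoplot(fus$network), "ggplot")
  expect_output(print(fus), "fused record")
})

test_that("wider fields fuse values longer than two characters", {
  ann <- tibble::tibble(
    source_id = rep(c("s1", "s2"), each = 2),
    property = rep(c("spres", "qa"), 2),
    value = c("1.85", NA, NA, "good"),
    dtype = c("float", "undefined", "undefined", "string"),
    unit = "undefined"
  )
  fus <- semantic_fuse(ann, mode = "exhaustive", name_width = 5,
                       value_width = 4)
  rec <- tidy(fus)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$entries[[1]]$value, c("1.85", "good"))
  expect_identical(rec$length_nt, 80L * 4L)  # 8*(5+4+1) nt per vertex, 4 vertices
})
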