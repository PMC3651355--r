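test_that("matrix round-trips through tab-delimited text", {
  for (seed in 1:3) {
    m <- random_matrix(30, 4, seed = seed)
    f <- tempfile(fileext = ".tsv")
    write_matrix(m, f, precision = 12)
    back <- read_matrix(f)
    expect_identical(dimnames(back), dimnames(m))
    expect_equal(unclass(back), unclass(m), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_identical(exm_scale(back), "linear")
  }
})

test_that("a well-formed 3x2 file is parsed with the right shape", {
  f <- write_tsv_lines(c("feature_id\ts1\ts2",
                         "p1\t1.5\t2.5",
                         "p2\t3\t4",
                         "p3\t5\t6.25"))
  m <- read_matrix(f)
  expect_equal(dim(m), c(3L, 2L))
  expect_identical(rownames(m), c("p1", "p2", "p3"))
  expect_equal(unclass(m)["p3", "s2"], 6.25)
})

test_that("reader rejects malformed input with informative errors", {
  dup <- write_tsv_lines(c("feature_id\ts1", "p1\t1", "p1\t2"))
  expect_error(read_matrix(dup), "p1")
  ragged <- write_tsv_lines(c("feature_id\ts1\ts2", "p1\t1\t2", "p2\t3"))
  expect_error(read_matrix(ragged), "line 3")
  neg <- write_tsv_lines(c("feature_id\ts1", "p1\t-4"))
  expect_error(read_matrix(neg, expect = "linear"), "non-negative")
  nonnum <- write_tsv_lines(c("feature_id\ts1", "p1\tabc"))
  expect_error(read_matrix(nonnum), "non-numeric")
})

test_that("windows line endings are accepted", {
  f <- tempfile()
  writeLines(c("feature_id\ts1\r", "p1\t2\r", "p2\t3\r"), f, sep = "\n")
  m <- read_matrix(f)
  expect_equal(unname(unclass(m)[, 1]), c(2, 3))
})

test_that("writer honours significant digits and degenerate input", {
  m <- expression_matrix(matrix(pi * 1000, 1, 1,
                                dimnames = list("p1", "s1")))
  f <- tempfile()
  write_matrix(m, f, precision = 6)
  line <- readLines(f)[2]
  expect_match(line, "3141.59")
  empty <- matrix(numeric(0), nrow = 3, ncol = 0,
                  dimnames = list(c("a", "b", "c"), NULL))
  expect_error(write_matrix(empty, tempfile()))
})

test_that("scale tag is tracked and asserted by consumers", {
  m <- expression_matrix(matrix(c(1, 2), 2, 1,
                                dimnames = list(c("a", "b"), "s1")),
                         scale = "log2")
  expect_identical(exm_scale(m), "log2")
  expect_error(background_subtract(m), "linear")
  expect_error(find_median_chip(m), "linear")
  expect_error(expression_matrix(matrix(-1, 1, 1,
                                        dimnames = list("a", "s")),
                                 scale = "linear"),
               "non-negative")
  expect_silent(expression_matrix(matrix(-1, 1, 1,
                                         dimnames = list("a", "s")),
                                  scale = "log2"))
})

test_that("layout file parsing populates maps and flags", {
  f <- write_tsv_lines(c("probe_id\tprobeset_id\tflags",
                         "p1\tps1\t",
                         "p2\tps1\tmask",
                         "p3\tps2\tqc",
                         "p4\t\t"))
  lay <- read_layout(f)
  expect_identical(lay$masked, "p2")
  expect_identical(lay$qc_probes, "p3")
  expect_true(is.na(layout_probeset_of(lay, "p4")))
  expect_identical(layout_probeset_of(lay, c("p1", "p2")), c("ps1", "ps1"))
})

test_that("conflicting probeset assignment is an error, empty layout warns", {
  f <- write_tsv_lines(c("probe_id\tprobeset_id",
                         "p1\tps1",
                         "p1\tps2"))
  expect_error(read_layout(f), "more than one probeset")
  hdr <- write_tsv_lines("probe_id\tprobeset_id\tflags")
  expect_warning(lay <- read_layout(hdr), "no probes")
  expect_length(lay$probe_id, 0)
})

test_that("unknown flagged probes produce a warning", {
  expect_warning(chip_layout(c("p1", "p2"), c("ps1", "ps1"),
                             masked = "p9"),
                 "p9")
})

test_that("config validation enforces parameter ranges", {
  expect_error(iron_config(convergence_pct = 0))
  expect_error(iron_config(window_frac_sigma = 0.2, window_frac_fit = 0.1))
  expect_error(iron_config(extrapolation_points = 0))
  cfg <- iron_config()
  expect_equal(cfg$convergence_pct, 1.0)
  expect_equal(cfg$prune_decrement_pct, 0.5)
  expect_equal(cfg$window_frac_fit, 0.10)
  expect_equal(cfg$saturation_threshold, 64000)
})

test_that("flat key = value config files are parsed", {
  f <- write_tsv_lines(c("# comment", "convergence_pct = 2",
                         "do_background = FALSE"))
  cfg <- read_config(f)
  expect_equal(cfg$convergence_pct, 2)
  expect_false(cfg$do_background)
  bad <- write_tsv_lines("no_such_key = 1")
  expect_error(read_config(bad), "no_such_key")
})
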