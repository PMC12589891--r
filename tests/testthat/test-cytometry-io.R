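test_that("CSV events round-trip with metadata sidecar", {
  ev <- simulate_event_tables(cohort_config(n_donors = 1, events_per_sample = 200))
  p <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, p, dialect = "csv")
  back <- read_events(p, dialect = "csv")
  expect_equal(length(event_markers(back)), 33)
  expect_equal(as.matrix(back[, event_markers(back)]),
               as.matrix(ev[, event_markers(ev)]), tolerance = 1e-9)
  expect_identical(unique(back$donor), unique(ev$donor))
  expect_identical(scale_state(back), "raw")
})

test_that("a bare 33-column CSV reads as a 33-channel panel", {
  m <- matrix(runif(5 * 33, 1, 100), nrow = 5,
              dimnames = list(NULL, default_panel()))
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(m), p, row.names = FALSE)
  ev <- read_events(p, dialect = "csv")
  expect_length(event_markers(ev), 33)
  expect_error(read_events(tempfile(), dialect = "csv"), "not found")
})

test_that("unknown channels warn but pass through", {
  df <- data.frame(CD3 = 1:3, Mystery = 4:6)
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, p, row.names = FALSE)
  expect_warning(ev <- read_events(p, panel = default_panel()), "Mystery")
  expect_true("Mystery" %in% names(ev))
})

test_that("FCS writer/reader round-trips events at single precision", {
  ev <- simulate_event_tables(cohort_config(n_donors = 1, events_per_sample = 500))
  p <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(ev, p)
  back <- read_fcs(p)
  expect_equal(nrow(back), nrow(ev))
  expect_setequal(event_markers(back), event_markers(ev))
  orig <- as.matrix(ev[, event_markers(ev)])
  got <- as.matrix(back[, event_markers(ev)])
  expect_lt(max(abs(got - orig) / pmax(abs(orig), 1)), 1e-6)
  expect_error(read_fcs(p2 <- withr::local_tempfile(lines = "not an fcs file")),
               "FCS")
})

test_that("gating is hierarchical, monotone, and handles empty results", {
  withr::with_seed(9, {
    x <- c(rnorm(600, 2), rnorm(400, 10))   # bimodal, valley near 6
  })
  ev <- make_events(matrix(x, dimnames = list(NULL, "CD8")))
  tree <- gate_tree(
    gate_node("low", "all", "CD8", upper = 6),
    gate_node("verylow", "low", "CD8", upper = 0)
  )

  expect_equal(nrow(apply_gates(ev, gate_tree(gate_node("keep", "all", "CD8",
                                                        lower = min(x) - 1)),
                                "keep")), 1000)
  expect_equal(nrow(apply_gates(ev, gate_tree(gate_node("none", "all", "CD8",
                                                        lower = max(x) + 1)),
                                "none")), 0)

  # Valley threshold recovers the mixture weight within a binomial CI
  low <- apply_gates(ev, tree, "low")
  expect_lt(abs(nrow(low) / 1000 - 0.6), 3 * sqrt(0.6 * 0.4 / 1000))

  # Child is a subset of parent
  child <- apply_gates(ev, tree, "verylow")
  expect_true(all(child$CD8 %in% low$CD8))
  expect_lte(nrow(child), nrow(low))

  expect_error(gate_tree(gate_node("x", "ghost", "CD8")), "ghost")
})

test_that("boolean signature frequencies follow conjunction semantics", {
  withr::with_seed(21, {
    m <- cbind(A = runif(4000), B = runif(4000), C = rep(0, 4000))
  })
  ev <- make_events(m)
  th <- c(A = 0.5, B = 0.5, C = 0.5)

  # Vacuous conjunction: 100%
  expect_equal(signature_frequency(ev, boolean_signature("all", character()), th),
               100)
  # Constant-negative marker: 0%
  expect_equal(signature_frequency(ev, boolean_signature("c", "C"), th), 0)
  # Independent markers at ~50% each: joint ~25% within 3 binomial SDs
  joint <- signature_frequency(ev, boolean_signature("ab", c("A", "B")), th)
  expect_lt(abs(joint - 25), 300 * sqrt(0.25 * 0.75 / 4000))

  # Monotone: adding a conjunct never increases the frequency
  fa <- signature_frequency(ev, boolean_signature("a", "A"), th)
  expect_lte(joint, fa)

  # Negative polarity complements positive
  fneg <- signature_frequency(ev, boolean_signature("na", "A", "-"), th)
  expect_equal(fa + fneg, 100)

  # Empty parent flagged as missing
  expect_warning(
    out <- signature_frequency(ev[0, ], boolean_signature("a", "A"), th),
    "Empty parent"
  )
  expect_true(is.na(out))
})

test_that("gating config round-trips through YAML", {
  p <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    gates = list(
      list(node = "viable", parent = "all", channel = "Viability", upper = 100),
      list(node = "T", parent = "viable", channel = "CD3", lower = 500)
    ),
    signatures = list(
      list(name = "cytotox", markers = c("GrzB", "CD26"))
    )
  ), p)
  cfg <- read_gating_config(p)
  expect_equal(nrow(cfg$tree), 2)
  expect_equal(cfg$signatures$cytotox$markers, c("GrzB", "CD26"))
})
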