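test_that("SOM assignments equal exhaustive nearest-codebook search", {
  blobs <- make_blobs(250, matrix(c(0, 0, 6, 0, 0, 6, 6, 6), 4, byrow = TRUE),
                      seed = 13)
  fit <- fit_som(blobs$x, xdim = 10, ydim = 10, rlen = 10, seed = 3421)

  brute <- apply(blobs$x, 1, function(row) {
    which.min(colSums((t(fit$codebook) - row)^2))
  })
  expect_identical(fit$assignment, as.integer(brute))
})

test_that("SOM training is deterministic and handles degenerate inputs", {
  m <- matrix(rnorm(900, sd = 3), ncol = 3)
  f1 <- fit_som(m, xdim = 4, ydim = 4, rlen = 5, seed = 3421)
  f2 <- fit_som(m, xdim = 4, ydim = 4, rlen = 5, seed = 3421)
  expect_identical(f1$codebook, f2$codebook)
  expect_identical(f1$assignment, f2$assignment)

  # Single event: every node converges to it, assignment trivial
  one <- matrix(c(1, 2, 3), nrow = 1)
  expect_warning(f3 <- fit_som(one, xdim = 2, ydim = 2, rlen = 3), "empty")
  expect_true(all(abs(sweep(f3$codebook, 2, c(1, 2, 3))) < 1e-9))
  expect_equal(length(f3$assignment), 1)
  expect_error(fit_som(matrix(numeric(), 0, 3)), "one event")
})

test_that("tidy and glance summarise a SOM fit", {
  m <- matrix(rnorm(300), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  fit <- fit_som(m, xdim = 3, ydim = 3, rlen = 3)
  td <- tidy(fit)
  expect_setequal(unique(td$channel), c("a", "b", "c"))
  expect_equal(nrow(td), 9 * 3)
  gl <- glance(fit)
  expect_equal(gl$n_events, 100)
  expect_equal(gl$n_nodes, 9)
})

test_that("metaclustering consolidates nodes as average-linkage at k", {
  blobs <- make_blobs(500, matrix(c(0, 0, 0, 10, 10, 10), 2, byrow = TRUE),
                      seed = 17)
  fit <- fit_som(blobs$x, xdim = 5, ydim = 5, rlen = 10)

  # Two well-separated blobs at k = 2 are perfectly split
  mc <- event_metaclusters(fit, k = 2)
  expect_equal(ari(mc, blobs$labels), 1)

  # k = number of occupied nodes: identity (every occupied node its own cluster)
  occ <- length(unique(fit$assignment))
  ident <- metacluster(fit, k = occ)
  expect_equal(length(unique(ident[!is.na(ident)])), occ)

  expect_error(metacluster(fit, k = occ + 1), "occupied")
})

test_that("a 50-cluster SOM consolidates into 35 metaclusters", {
  withr::with_seed(19, {
    m <- matrix(rnorm(60000, sd = 4), ncol = 6)
  })
  fit <- fit_som(m, xdim = 10, ydim = 5, rlen = 10)   # 50 nodes
  mc <- metacluster(fit, k = 35)
  expect_equal(length(unique(stats::na.omit(mc[fit$assignment]))), 35)
})

test_that("abundance rows sum to 100 and match brute-force counting", {
  withr::with_seed(23, {
    cl <- sample(1:4, 2000, replace = TRUE)
    sid <- sample(c("s1", "s2", "s3"), 2000, replace = TRUE)
  })
  tab <- cluster_abundance(cl, sid)
  cls <- grep("^cl_", names(tab), value = TRUE)
  expect_equal(unname(rowSums(tab[, cls])), rep(100, 3), tolerance = 1e-9)

  # Brute-force count/total oracle
  for (s in c("s1", "s3")) {
    for (k in 1:4) {
      expect_equal(tab[[paste0("cl_", k)]][tab$sample_id == s],
                   100 * sum(cl == k & sid == s) / sum(sid == s))
    }
  }

  # Degenerate splits
  single <- cluster_abundance(rep(1, 10), rep("s", 10))
  expect_equal(single$cl_1, 100)
  even <- cluster_abundance(rep(1:4, 25), rep("s", 100))
  expect_equal(unname(unlist(even[, -1])), rep(25, 4))
})

test_that("delta mean abundance uses the fixed convention and conserves mass", {
  tab <- tibble::tibble(
    sample_id = c("a1", "a2", "b1"),
    product_group = c("C7R", "C7R", "GD2"),
    cl_1 = c(10, 20, 5), cl_2 = c(90, 80, 95)
  )
  d <- delta_mean_abundance(tab)
  expect_equal(d$delta[d$cluster == "1"], 10)   # mean(10,20) - 5
  expect_equal(sum(d$delta), 0, tolerance = 1e-9)
  expect_match(attr(d, "convention"), "C7R.*GD2")

  # Identical groups: all deltas zero
  same <- tab
  same$product_group <- c("C7R", "GD2", "GD2")
  same$cl_1 <- 15; same$cl_2 <- 85
  expect_true(all(delta_mean_abundance(same)$delta == 0))

  expect_error(delta_mean_abundance(tab[tab$product_group == "C7R", ]),
               "non-empty")
})

test_that("outcome association formalises the PD<SD<PR trend as Spearman", {
  tab <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    outcome = c("PD", "PD", "SD", "SD", "PR", "PR"),
    cl_1 = c(1, 1, 2, 2, 3, 3),  # increases with outcome, same tie pattern
    cl_2 = c(3, 3, 2, 2, 1, 1),  # decreases with outcome
    cl_3 = rep(2, 6)             # constant: undefined
  )
  a <- outcome_association(tab)
  expect_equal(a$rho[a$cluster == "1"], 1)
  expect_equal(a$rho[a$cluster == "2"], -1)
  expect_false(a$defined[a$cluster == "3"])

  # Random labels: mean rho over permutations near 0
  withr::with_seed(29, {
    rhos <- replicate(1000, {
      t2 <- tab[, c("sample_id", "outcome", "cl_1")]
      t2$cl_1 <- sample(t2$cl_1)
      outcome_association(t2)$rho
    })
  })
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("cluster profiles are min-max scaled with the tie convention", {
  # 5 clusters x 6 markers fixture with hand-computable calls at 0.58
  mfi_events <- rbind(
    matrix(rep(c(0, 10, 5, 100, 7, 3), each = 2), nrow = 2, byrow = FALSE),
    matrix(rep(c(10, 0, 5, 100, 1, 3), each = 2), nrow = 2, byrow = FALSE),
    matrix(rep(c(5, 5, 5, 100, 4, 3), each = 2), nrow = 2, byrow = FALSE),
    matrix(rep(c(2, 8, 0, 100, 0, 3), each = 2), nrow = 2, byrow = FALSE),
    matrix(rep(c(8, 2, 10, 100, 10, 3), each = 2), nrow = 2, byrow = FALSE)
  )
  colnames(mfi_events) <- paste0("m", 1:6)
  cl <- rep(1:5, each = 2)
  pr <- profile_clusters(mfi_events, cl, threshold = 0.58)

  expect_true(all(pr$scaled >= 0 & pr$scaled <= 1))
  # m4 constant across clusters: scaled 0 everywhere, absent
  expect_true(all(pr$scaled[, "m4"] == 0))
  expect_true(all(!pr$present[, "m4"]))
  # Hand-computed presence on m1 (range 0..10, threshold 5.8): clusters 2,5
  expect_identical(unname(pr$present[, "m1"]), c(FALSE, TRUE, FALSE, FALSE, TRUE))
  # Hand-computed presence on m5 (range 0..10): clusters 1 (7) and 5 (10)
  expect_identical(unname(pr$present[, "m5"]), c(TRUE, FALSE, FALSE, FALSE, TRUE))
  # Cluster attaining the max scales to exactly 1 and is present
  expect_equal(pr$scaled[2, "m1"], 1)
  expect_true(pr$present[2, "m1"])
  # Argmax preserved between raw MFI and scaled values
  expect_equal(apply(pr$mfi[, c("m1", "m2", "m5")], 2, which.max),
               apply(pr$scaled[, c("m1", "m2", "m5")], 2, which.max))

  # Min-max scaling is idempotent on already-scaled input
  pr2 <- profile_clusters(pr$scaled[rep(1:5, each = 2), ], cl,
                          threshold = 0.58)
  expect_equal(unname(pr2$scaled), unname(pr$scaled), tolerance = 1e-12)

  expect_error(profile_clusters(mfi_events, rep(1, 10)), "two clusters")
})

test_that("clustering recovers planted mixtures from generated events", {
  cohort <- cohort_config(n_donors = 2, events_per_sample = 2000, seed = 101)
  ev <- transform_arcsinh(simulate_event_tables(cohort))
  fit <- fit_som(ev, xdim = 8, ydim = 8, rlen = 10, seed = 3421)
  mc <- event_metaclusters(fit, k = 8)
  expect_gte(ari(mc, ev$.population), 0.9)
})
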