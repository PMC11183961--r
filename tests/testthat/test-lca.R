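test_that("valid-hit selection applies the e-value, bitscore and identity windows", {
  # 79 is below 80% of the best bitscore, so only the first two survive
  hits <- make_hits(taxa = "G1S1", pident = 60, bitscore = c(100, 85, 79))
  kept <- select_valid_hits(hits)
  expect_equal(kept$bitscore, c(100, 85))

  # single hit above the e-value ceiling: nothing survives
  expect_equal(nrow(select_valid_hits(make_hits("G1S1", 60, evalue = 1e-2))), 0L)

  # relative identity window: 5.9 < 10% of 60
  hits <- make_hits("G1S1", pident = c(60, 5.9, 6.0), bitscore = 100)
  expect_equal(select_valid_hits(hits)$percent_identity, c(60, 6.0))
})

test_that("absolute identity window is available as a configuration switch", {
  hits <- make_hits("G1S1", pident = c(80, 71, 69), bitscore = 100)
  kept <- select_valid_hits(hits, lca_params(identity_mode = "absolute"))
  expect_equal(kept$percent_identity, c(80, 71))  # 69 < 80 - 10
})

test_that("best-hit ties break by e-value, then identity, then input order", {
  hits <- make_hits("G1S1", pident = c(50, 90), bitscore = c(100, 100),
                    evalue = c(1e-10, 1e-20))
  kept <- select_valid_hits(hits)
  expect_equal(kept$best_identity[1], 90)   # lower e-value wins the tie
  hits2 <- make_hits("G1S1", pident = c(50, 90), bitscore = 100, evalue = 1e-20)
  expect_equal(select_valid_hits(hits2)$best_identity[1], 90)  # identity tie-break
})

test_that("single-hit ORFs assign at species when identity clears the floor", {
  res <- assign_orf_lca(make_hits("G1S1", 90), toy_tree())
  expect_equal(res$assigned_taxon, "G1S1")
  expect_equal(res$assigned_rank, "species")
  expect_equal(res$n_valid_hits, 1L)
})

test_that("the 90% support rule passes at exactly 9 of 10 hits", {
  # 9 hits in genus G1, 1 in sister genus G2 (same family F1)
  taxa <- c(rep("G1S1", 9), "G2S1")
  res <- assign_orf_lca(make_hits(taxa, 70), toy_tree())
  expect_equal(res$assigned_taxon, "G1")
  expect_equal(res$assigned_rank, "genus")
  # at 8 of 10 the genus fails and the call retreats to the shared family
  taxa2 <- c(rep("G1S1", 8), "G2S1", "G2S1")
  res2 <- assign_orf_lca(make_hits(taxa2, 70), toy_tree())
  expect_equal(res2$assigned_taxon, "F1")
  expect_equal(res2$assigned_rank, "family")
})

test_that("identity floors truncate unanimous deep assignments", {
  # unanimous species-level support but identity 45: below the class floor
  # (46), at or above the phylum floor (42)
  res <- assign_orf_lca(make_hits(rep("G1S1", 5), 45), toy_tree())
  expect_equal(res$assigned_rank, "phylum")
  expect_equal(res$assigned_taxon, "P1")
  # identity exactly at a floor assigns at that floor's rank
  res2 <- assign_orf_lca(make_hits(rep("G1S1", 5), 46), toy_tree())
  expect_equal(res2$assigned_rank, "class")
  # below the superkingdom floor nothing can be assigned
  res3 <- assign_orf_lca(make_hits(rep("G1S1", 5), 39), toy_tree())
  expect_true(is.na(res3$assigned_taxon))
  expect_true(is.na(res3$assigned_rank))
})

test_that("unlabeled hits count in the support denominator", {
  # 1 labeled + 1 unlabeled valid hit: support 1/2 < 90%
  res <- assign_orf_lca(make_hits(c("G1S1", NA), 90), toy_tree())
  expect_true(is.na(res$assigned_taxon))
  expect_equal(res$n_valid_hits, 2L)
})

test_that("hits naming taxa outside the tree raise an error", {
  expect_error(classify_orfs(make_hits("Narnia", 90), toy_tree()), "Narnia")
})

test_that("support monotonicity: raising support_fraction never deepens a call", {
  set.seed(41)
  pool <- c("G1S1", "G1S2", "G2S1", "G3S1", "G4S1", NA)
  depth_of <- function(r) if (is.na(r)) 0L else match(r, tax_ranks())
  for (i in 1:40) {
    hits <- make_hits(sample(pool, sample(1:6, 1), replace = TRUE),
                      pident = runif(1, 39, 100))
    d <- vapply(c(0.5, 0.7, 0.9, 1.0), function(s) {
      depth_of(assign_orf_lca(hits, toy_tree(),
                              lca_params(support_fraction = s))$assigned_rank)
    }, integer(1))
    expect_true(all(diff(d) <= 0))
  }
})

test_that("identity monotonicity: lowering identity never deepens a call", {
  set.seed(42)
  pool <- c("G1S1", "G1S2", "G2S1", "G3S1")
  depth_of <- function(r) if (is.na(r)) 0L else match(r, tax_ranks())
  for (i in 1:40) {
    taxa <- sample(pool, sample(1:6, 1), replace = TRUE)
    d <- vapply(c(95, 80, 59, 48, 41, 39), function(id) {
      depth_of(assign_orf_lca(make_hits(taxa, id), toy_tree())$assigned_rank)
    }, integer(1))
    expect_true(all(diff(d) <= 0))
  }
})

test_that("vectorized classification matches per-query calls and keeps empty queries", {
  hits <- dplyr::bind_rows(
    make_hits(rep("G1S1", 3), 90, query = "q1"),
    make_hits("G3S1", 55, query = "q2"),
    make_hits("G4S1", 90, evalue = 1, query = "q3")  # filtered out entirely
  )
  res <- classify_orfs(hits, toy_tree())
  expect_equal(res$orf_id, c("q1", "q2", "q3"))
  expect_equal(res$assigned_taxon, c("G1S1", "F2", NA))
  expect_equal(res$n_valid_hits, c(3L, 1L, 0L))
  for (q in c("q1", "q2")) {
    single <- assign_orf_lca(hits[hits$query_id == q, ], toy_tree())
    expect_equal(single$assigned_taxon, res$assigned_taxon[res$orf_id == q])
  }
})
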