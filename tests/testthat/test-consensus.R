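orf_tax_of <- function(taxa) {
  tibble::tibble(
    orf_id = sprintf("o%02d", seq_along(taxa)),
    assigned_taxon = taxa,
    assigned_rank = NA_character_,
    best_identity = NA_real_,
    n_valid_hits = 1L
  )
}

test_that("unanimous ORFs give their shared taxon at its own rank", {
  res <- consensus_contig_taxonomy(orf_tax_of(rep("G1", 4)), toy_tree())
  expect_equal(res$assigned_taxon, "G1")
  expect_equal(res$assigned_rank, "genus")
  expect_equal(res$n_orfs, 4L)
})

test_that("the 50%/70% thresholds pass exactly at their boundaries", {
  # 10 ORFs, 6 annotated at phylum, 5 of them P1: 5/10 = 50%, 5/6 = 83%
  taxa <- c(rep("P1", 5), "P2", rep(NA, 4))
  res <- consensus_contig_taxonomy(orf_tax_of(taxa), toy_tree())
  expect_equal(res$assigned_taxon, "P1")
  expect_equal(res$assigned_rank, "phylum")
})

test_that("a contig with under half its ORFs annotated is unclassified", {
  taxa <- c(rep("P1", 4), rep(NA, 6))
  res <- consensus_contig_taxonomy(orf_tax_of(taxa), toy_tree())
  expect_true(is.na(res$assigned_taxon))
  expect_true(is.na(res$assigned_rank))
})

test_that("the annotated-fraction rule can block a majority taxon", {
  # 6/10 ORFs say P1 (60% of all) but 4 say P2: 6/10 annotated = 60% < 70%
  taxa <- c(rep("P1", 6), rep("P2", 4))
  res <- consensus_contig_taxonomy(orf_tax_of(taxa), toy_tree())
  # superkingdom Bac still passes (10/10), phylum cannot
  expect_equal(res$assigned_taxon, "Bac")
  expect_equal(res$assigned_rank, "superkingdom")
})

test_that("consensus descends only while parent-consistent taxa qualify", {
  # all ORFs share class C1 via G1/G2; genus splits 3/2
  taxa <- c(rep("G1S1", 3), rep("G2S1", 2))
  res <- consensus_contig_taxonomy(orf_tax_of(taxa), toy_tree())
  expect_equal(res$assigned_taxon, "F1")
  expect_equal(res$assigned_rank, "family")
})

test_that("consensus containment: shallower consensus is an ancestor of deeper", {
  set.seed(7)
  pool <- c("G1S1", "G1S2", "G2S1", "G3S1", "P1", NA)
  for (i in 1:40) {
    taxa <- sample(pool, sample(2:10, 1), replace = TRUE)
    res <- consensus_contig_taxonomy(orf_tax_of(taxa), toy_tree())
    if (is.na(res$assigned_taxon)) next
    lin <- climb_lineage(toy_tree_df(), res$assigned_taxon)
    expect_equal(lin[[res$assigned_rank]], res$assigned_taxon)
    # tightening the thresholds can only move the consensus to an ancestor
    stricter <- consensus_contig_taxonomy(
      orf_tax_of(taxa), toy_tree(),
      consensus_params(min_fraction_all = 0.8, min_fraction_annotated = 0.9))
    if (!is.na(stricter$assigned_taxon)) {
      expect_equal(lin[[stricter$assigned_rank]], stricter$assigned_taxon)
    }
  }
})

test_that("read fractions are direct proportions with an unclassified bucket", {
  tax <- toy_tree()
  contigs <- tibble::tibble(contig_id = c("A", "B"),
                            assigned_taxon = c("P1", "P2"))
  reads <- tibble::tibble(contig_id = c("A", "B"), reads = c(70, 30))
  fr <- taxon_read_fractions(contigs, reads, tax, "phylum")
  expect_equal(fr$fraction[match(c("P1", "P2"), fr$taxon)], c(0.7, 0.3))

  contigs2 <- tibble::tibble(contig_id = c("A", "B", "C"),
                             assigned_taxon = c("P1", "P2", NA))
  reads2 <- tibble::tibble(contig_id = c("A", "B", "C"),
                           reads = c(70, 20, 10))
  fr2 <- taxon_read_fractions(contigs2, reads2, tax, "phylum")
  expect_equal(fr2$fraction[fr2$taxon == "unclassified"], 0.10)
  expect_equal(sum(fr2$fraction), 1, tolerance = 1e-9)
})

test_that("genus-level contigs roll up through their lineage", {
  # hand-summed 5-contig fixture: P1 collects G1 (40+15) and G1S2 (10)
  # reads; P2 collects G4S1 (20); superkingdom-only contig cannot reach
  # phylum and lands in the unclassified bucket (15)
  tax <- toy_tree()
  contigs <- tibble::tibble(
    contig_id = c("c1", "c2", "c3", "c4", "c5"),
    assigned_taxon = c("G1", "G1", "G1S2", "G4S1", "Bac")
  )
  reads <- tibble::tibble(contig_id = paste0("c", 1:5),
                          reads = c(40, 15, 10, 20, 15))
  fr <- taxon_read_fractions(contigs, reads, tax, "phylum")
  expect_equal(fr$fraction[fr$taxon == "P1"], 0.65)
  expect_equal(fr$fraction[fr$taxon == "P2"], 0.20)
  expect_equal(fr$fraction[fr$taxon == "unclassified"], 0.15)
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-9)
})

test_that("zero mapped reads is an error", {
  contigs <- tibble::tibble(contig_id = "A", assigned_taxon = "P1")
  reads <- tibble::tibble(contig_id = "A", reads = 0)
  expect_error(taxon_read_fractions(contigs, reads, toy_tree()), "zero")
})
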