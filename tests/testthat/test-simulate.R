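test_that("community trajectories hit their endpoints and renormalize", {
  taxa <- tibble::tibble(
    taxon_id = c("Polaribacter", "Thioglobus"),
    initial_fraction = c(0.5, 0.5), final_fraction = c(0.5, 0.5),
    trajectory = "linear"
  )
  sc <- community_scenario(taxa, n_samples = 5, seed = 1)
  fr <- simulate_community(sc)
  expect_true(all(abs(fr$fraction - 0.5) < 1e-12))

  sc2 <- default_scenario()
  fr2 <- simulate_community(sc2)
  first <- fr2[fr2$sample_id == "s01" & fr2$taxon_id == "Polaribacter", ]
  last <- fr2[fr2$sample_id == "s13" & fr2$taxon_id == "Polaribacter", ]
  expect_equal(first$raw_fraction, 0.09)   # endpoint before renormalization
  expect_equal(last$raw_fraction, 0.55)
  sums <- tapply(fr2$fraction, fr2$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("the simulator is deterministic under a fixed seed", {
  sc <- default_scenario(n_samples = 3, seed = 9)
  s1 <- simulate_study(sc)
  s2 <- simulate_study(sc)
  expect_identical(s1$samples, s2$samples)
  s3 <- simulate_study(default_scenario(n_samples = 3, seed = 10))
  expect_false(identical(s1$samples, s3$samples))
})

test_that("noiseless single-taxon samples recover exact copy numbers", {
  taxa <- tibble::tibble(taxon_id = "Thioglobus", initial_fraction = 1,
                         final_fraction = 1, trajectory = "linear")
  sc <- community_scenario(taxa, n_samples = 2, reads_per_sample = Inf,
                           noise_cv = 0, seed = 1)
  st <- simulate_study(sc)
  s <- st$samples[["s01"]]
  fun <- annotate_cogs(s$hits)
  prof <- abundance_profile(s$coverage, fun, default_markers(),
                            default_catalog(), "s01")
  comp <- default_genomes()$complements
  thio <- comp[comp$taxon_id == "Thioglobus", ]
  got <- prof$cn_by_cog$copy_number[match(thio$cog_id, prof$cn_by_cog$cog_id)]
  expect_equal(got, as.numeric(thio$copies), tolerance = 1e-12)
})

test_that("a cheater-only community has zero synthesis copy number", {
  taxa <- tibble::tibble(taxon_id = "Polaribacter", initial_fraction = 1,
                         final_fraction = 1, trajectory = "linear")
  sc <- community_scenario(taxa, n_samples = 2, noise_cv = 0, seed = 2)
  st <- simulate_study(sc)
  s <- st$samples[["s01"]]
  fun <- annotate_cogs(s$hits)
  prof <- abundance_profile(s$coverage, fun, default_markers(),
                            default_catalog(), "s01")
  net <- pathway_network(default_pathway_edges())
  expect_equal(quantify_synthesis(prof, net, default_catalog()), 0)
})

test_that("hit tables are built so the classifier recovers the true genus", {
  sc <- default_scenario(n_samples = 2, seed = 4)
  st <- simulate_study(sc)
  s <- st$samples[["s02"]]
  res <- classify_orfs(s$hits, st$tax)
  truth <- s$orf_truth
  m <- dplyr::inner_join(res, truth, by = c(orf_id = "orf_id"))
  expect_true(all(m$assigned_taxon == m$taxon_id))
  expect_true(all(m$assigned_rank == "genus"))
})

test_that("exported ground truth matches the construction", {
  sc <- default_scenario(n_samples = 3, seed = 5)
  net <- pathway_network(default_pathway_edges())
  truth <- export_ground_truth(sc, default_genomes(), default_taxonomy(), net)
  # producer pathway with a unique synthesis COG is PRESENT in truth
  expect_equal(truth$pathway_status$status[
    truth$pathway_status$pathway_id == "alcaligin"], "PRESENT")
  # a pathway whose gene sits in no genome is ABSENT
  expect_equal(truth$pathway_status$status[
    truth$pathway_status$pathway_id == "pyoverdin"], "ABSENT")
  expect_equal(sum(truth$pathway_status$status == "PRESENT"), 8L)
  expect_equal(sum(truth$pathway_status$status == "ABSENT"), 4L)
  # marker copy number is 1 in any community (single-copy constraint)
  mk <- truth$copy_numbers[truth$copy_numbers$cog_id %in% default_markers(), ]
  expect_true(all(abs(mk$copy_number - 1) < 1e-12))
})

test_that("read fractions track truth within multinomial error", {
  taxa <- tibble::tibble(
    taxon_id = c("Polaribacter", "Thioglobus"),
    initial_fraction = c(0.7, 0.3), final_fraction = c(0.7, 0.3),
    trajectory = "linear"
  )
  sc <- community_scenario(taxa, n_samples = 2, reads_per_sample = 1e5,
                           noise_cv = 0, seed = 6)
  st <- simulate_study(sc)
  s <- st$samples[["s01"]]
  orf_tax <- classify_orfs(s$hits, st$tax)
  contig_tax <- consensus_taxonomy(orf_tax, s$contig_map, st$tax)
  fr <- taxon_read_fractions(contig_tax, s$read_counts, st$tax, "phylum")
  # binomial standard error at 1e5 reads is ~0.0014; allow 4 SE
  expect_equal(fr$fraction[fr$taxon == "Bacteroidetes"], 0.7,
               tolerance = 4 * 0.0015 / 0.7)
})
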