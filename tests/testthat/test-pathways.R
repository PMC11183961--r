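test_that("detection is strict-greater-than the coverage floor", {
  prof <- tibble::tibble(cog_id = c("COG1629", "COG0609"), coverage = c(3, 0))
  expect_equal(detected_cogs(prof), "COG1629")
  expect_equal(detected_cogs(prof, 2.9), "COG1629")
  expect_equal(detected_cogs(prof, 3), character(0))
  expect_equal(detected_cogs(prof[0, ]), character(0))
})

test_that("one missing gene makes a pathway absent, listing the gene", {
  net <- pathway_network(toy_edges())
  call <- classify_pathway("amph", net, present_cogs = "C1")  # gB missing
  expect_equal(call$status, "ABSENT")
  expect_equal(call$missing_genes[[1]], "gB")
})

test_that("all genes present but only shared signatures gives MAYBE", {
  net <- pathway_network(toy_edges())
  # C3 serves both ferriox and ent, so it is not unique; C4 is unique
  call <- classify_pathway("ferriox", net, present_cogs = "C3")
  # gD missing -> first check the all-genes rule
  expect_equal(call$status, "ABSENT")
  # with both genes present via the shared C3 and a second shared signature:
  edges <- toy_edges()
  edges$cog_id[edges$gene_id == "gD"] <- "C3"
  net2 <- pathway_network(edges)
  call2 <- classify_pathway("ferriox", net2, present_cogs = "C3")
  expect_equal(call2$status, "MAYBE")
  expect_length(call2$supporting_unique_cogs[[1]], 0)
})

test_that("a unique unambiguous signature upgrades to PRESENT", {
  net <- pathway_network(toy_edges())
  call <- classify_pathway("amph", net, present_cogs = c("C1", "C2"))
  expect_equal(call$status, "PRESENT")
  expect_setequal(call$supporting_unique_cogs[[1]], c("C1", "C2"))
  # an ambiguous COG satisfies gene presence but cannot support uniqueness
  call2 <- classify_pathway("ent", net, present_cogs = c("C5", "C6"))
  expect_equal(call2$status, "PRESENT")  # via unique C5
  call3 <- classify_pathway("ent", net, present_cogs = "C6")
  expect_equal(call3$status, "ABSENT")   # gE missing
  expect_error(classify_pathway("nope", net, "C1"), "unknown pathway")
})

test_that("status never demotes when a COG is added", {
  net <- pathway_network(toy_edges())
  rank <- c(ABSENT = 1, MAYBE = 2, PRESENT = 3)
  cogs <- unique(toy_edges()$cog_id)
  set.seed(5)
  for (i in 1:30) {
    present <- sample(cogs, sample(0:5, 1))
    extra <- sample(setdiff(cogs, present), 1)
    for (pw in names(net$pathways)) {
      s1 <- classify_pathway(pw, net, present)$status
      s2 <- classify_pathway(pw, net, c(present, extra))$status
      expect_gte(rank[[s2]], rank[[s1]])
    }
  }
})

test_that("PRESENT calls always rest on a COG private to the pathway", {
  net <- pathway_network(toy_edges())
  cogs <- unique(toy_edges()$cog_id)
  set.seed(6)
  for (i in 1:30) {
    present <- sample(cogs, sample(1:6, 1))
    for (pw in names(net$pathways)) {
      call <- classify_pathway(pw, net, present)
      if (call$status == "PRESENT") {
        support <- call$supporting_unique_cogs[[1]]
        expect_gt(length(support), 0)
        for (cog in support) {
          in_paths <- unique(net$edges$pathway_id[net$edges$cog_id == cog])
          expect_equal(in_paths, pw)
        }
      }
    }
  }
})

test_that("synthesis quantitation excludes ambiguous COGs", {
  markers <- default_markers()
  catalog <- default_catalog()
  net <- pathway_network(default_pathway_edges())
  base <- stats::setNames(rep(5, 10), markers)

  # only synthesis signal is on the ambiguous COG0318: quantitation is 0
  t1 <- profile_tables(c(base, COG0318 = 7))
  p1 <- abundance_profile(t1$coverage, t1$functions, markers, catalog)
  expect_equal(quantify_synthesis(p1, net, catalog), 0)
  # ... while the same COG still counts for gene presence (criterion 1)
  call <- classify_pathway("petrobactin", net,
                           present_cogs = c("COG0318", "COG7004"))
  expect_equal(call$status, "PRESENT")

  # single unambiguous COG: c / m
  t2 <- profile_tables(c(base, COG7001 = 7))
  p2 <- abundance_profile(t2$coverage, t2$functions, markers, catalog)
  expect_equal(quantify_synthesis(p2, net, catalog), 7 / 5)

  # mixture: only the unambiguous subtotal is counted (hand-summed fixture)
  t3 <- profile_tables(c(base, COG0318 = 7, COG7001 = 2, COG1021 = 3,
                         COG3486 = 1))
  p3 <- abundance_profile(t3$coverage, t3$functions, markers, catalog)
  expect_equal(quantify_synthesis(p3, net, catalog), (2 + 3 + 1) / 5)
  # and it never exceeds the full category's copy number
  full_cn <- p3$cn_by_category$copy_number[
    p3$cn_by_category$category == "siderophore_synthesis"]
  expect_lte(quantify_synthesis(p3, net, catalog), full_cn)
})

test_that("multi-sample calls report per-sample and best study status", {
  net <- pathway_network(toy_edges())
  s1 <- tibble::tibble(cog_id = "C1", coverage = 1)            # gB missing
  s2 <- tibble::tibble(cog_id = c("C1", "C2"), coverage = 1)   # all + unique
  calls <- call_all_pathways(net, list(mar = s1, jun = s2))
  amph <- calls$per_sample[calls$per_sample$pathway_id == "amph", ]
  expect_equal(amph$status[match(c("mar", "jun"), amph$sample_id)],
               c("ABSENT", "PRESENT"))
  expect_equal(calls$study$status[calls$study$pathway_id == "amph"], "PRESENT")
  expect_equal(calls$study$status[calls$study$pathway_id == "ferriox"], "ABSENT")
  empty <- call_all_pathways(net, list())
  expect_equal(nrow(empty$per_sample), 0L)
  expect_equal(nrow(empty$study), 0L)
})
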