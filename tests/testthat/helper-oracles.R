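# Brute-force oracles, written as direct loop evaluations of the stated
# rules so they share no code with the implementation under test.

RANKS7 <- c("superkingdom", "phylum", "class", "order", "family", "genus",
            "species")
FLOORS7 <- c(superkingdom = 40, phylum = 42, class = 46, order = 50,
             family = 55, genus = 60, species = 85)

# full LCA oracle for one query: filtering + node-by-node support scan +
# identity floors
oracle_lca <- function(hits, tree_df,
                       evalue_cutoff = 1e-3, bitscore_fraction = 0.8,
                       identity_fraction = 0.1, support_fraction = 0.9) {
  unassigned <- list(taxon = NA_character_, rank = NA_character_)
  keep <- which(hits$evalue <= evalue_cutoff)
  if (!length(keep)) return(unassigned)
  h <- hits[keep, ]
  # best hit: max bitscore, then min evalue, then max identity, then order
  ord <- order(-h$bitscore, h$evalue, -h$percent_identity, seq_len(nrow(h)))
  best <- h[ord[1], ]
  valid <- h[h$bitscore >= bitscore_fraction * best$bitscore &
               h$percent_identity >= identity_fraction * best$percent_identity, ]
  n_valid <- nrow(valid)
  if (n_valid == 0) return(unassigned)
  lineages <- lapply(valid$subject_taxon, function(t) {
    if (is.na(t)) character() else climb_lineage(tree_df, t)
  })
  # every ranked node is tested for support
  candidate <- NULL
  for (ri in rev(seq_along(RANKS7))) {   # deepest rank first
    r <- RANKS7[ri]
    nodes <- tree_df$taxon_id[tree_df$rank == r]
    supported <- c()
    for (v in nodes) {
      cnt <- sum(vapply(lineages, function(l) r %in% names(l) && l[[r]] == v,
                        logical(1)))
      if (cnt / n_valid >= support_fraction - 1e-12) supported[v] <- cnt
    }
    if (length(supported)) {
      candidate <- list(taxon = names(supported)[order(-supported,
                                                       names(supported))][1],
                        depth = ri)
      break
    }
  }
  if (is.null(candidate)) return(unassigned)
  best_ident <- best$percent_identity
  lin <- climb_lineage(tree_df, candidate$taxon)
  for (ri in seq(candidate$depth, 1)) {
    r <- RANKS7[ri]
    if (best_ident >= FLOORS7[[r]] - 1e-12 && r %in% names(lin)) {
      return(list(taxon = lin[[r]], rank = r))
    }
  }
  unassigned
}

# direct evaluation of the 50%/70% consensus rule with parent consistency
oracle_consensus <- function(assigned_taxa, tree_df,
                             min_all = 0.5, min_annot = 0.7) {
  total <- length(assigned_taxa)
  lineages <- lapply(assigned_taxa, function(t) {
    if (is.na(t)) character() else climb_lineage(tree_df, t)
  })
  chosen <- NA_character_
  chosen_rank <- NA_character_
  for (ri in seq_along(RANKS7)) {
    r <- RANKS7[ri]
    at_rank <- vapply(lineages, function(l) {
      if (r %in% names(l)) l[[r]] else NA_character_
    }, character(1))
    annotated <- sum(!is.na(at_rank))
    if (annotated == 0) break
    nodes <- unique(at_rank[!is.na(at_rank)])
    if (!is.na(chosen)) {
      prev <- RANKS7[ri - 1]
      nodes <- nodes[vapply(nodes, function(v) {
        l <- climb_lineage(tree_df, v)
        prev %in% names(l) && l[[prev]] == chosen
      }, logical(1))]
    }
    counts <- vapply(nodes, function(v) sum(at_rank == v, na.rm = TRUE),
                     numeric(1))
    ok <- counts / total >= min_all - 1e-12 &
      counts / annotated >= min_annot - 1e-12
    if (!any(ok)) break
    counts <- counts[ok]
    chosen <- names(counts)[order(-counts, names(counts))][1]
    chosen_rank <- r
  }
  list(taxon = chosen, rank = chosen_rank)
}

# direct evaluation of the three written pathway criteria from an edge table
oracle_pathway <- function(edges, pathway, present_cogs) {
  amb <- unique(edges$cog_id[edges$ambiguous])
  counts <- table(unique(edges[c("pathway_id", "cog_id")])$cog_id)
  unique_cogs <- setdiff(names(counts)[counts == 1], amb)
  pe <- edges[edges$pathway_id == pathway, ]
  genes <- unique(pe$gene_id)
  gene_ok <- vapply(genes, function(g) {
    any(pe$cog_id[pe$gene_id == g] %in% present_cogs)
  }, logical(1))
  if (any(!gene_ok)) return("ABSENT")           # criterion 3
  has_unique <- any(pe$cog_id %in% intersect(present_cogs, unique_cogs))
  if (has_unique) "PRESENT" else "MAYBE"        # criteria 2 / 1
}
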