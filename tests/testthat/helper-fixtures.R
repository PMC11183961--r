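# Shared fixtures: a small ranked tree and hit-table builders.

# 29-node tree: two bacterial phyla (one with two classes, one genus pair
# sharing a family), one archaeal phylum.
toy_tree_df <- function() {
  row <- function(id, parent, rank) data.frame(taxon_id = id, parent_id = parent,
                                               rank = rank, name = id)
  do.call(rbind, list(
    row("root", NA, "norank"),
    row("Bac", "root", "superkingdom"), row("Arc", "root", "superkingdom"),
    row("P1", "Bac", "phylum"), row("P2", "Bac", "phylum"),
    row("P3", "Arc", "phylum"),
    row("C1", "P1", "class"), row("C2", "P1", "class"),
    row("C3", "P2", "class"), row("C4", "P3", "class"),
    row("O1", "C1", "order"), row("O2", "C2", "order"),
    row("O3", "C3", "order"), row("O4", "C4", "order"),
    row("F1", "O1", "family"), row("F2", "O2", "family"),
    row("F3", "O3", "family"), row("F4", "O4", "family"),
    row("G1", "F1", "genus"), row("G2", "F1", "genus"),
    row("G3", "F2", "genus"), row("G4", "F3", "genus"), row("G5", "F4", "genus"),
    row("G1S1", "G1", "species"), row("G1S2", "G1", "species"),
    row("G2S1", "G2", "species"), row("G3S1", "G3", "species"),
    row("G4S1", "G4", "species"), row("G5S1", "G5", "species")
  ))
}

toy_tree <- function() taxonomy(toy_tree_df())

# one query's hit table from parallel vectors
make_hits <- function(taxa, pident, bitscore = 100, evalue = 1e-50,
                      cog = NA_character_, query = "orf1") {
  n <- max(length(taxa), length(pident), length(bitscore), length(evalue))
  tibble::tibble(
    query_id = query,
    subject_id = paste0("s", seq_len(n)),
    percent_identity = rep_len(pident, n),
    alignment_length = 200L,
    bitscore = rep_len(bitscore, n),
    evalue = rep_len(evalue, n),
    subject_taxon = rep_len(taxa, n),
    subject_cog = rep_len(cog, n)
  )
}

# a 3-pathway toy network: one pathway with two private COGs, one sharing a
# COG with the third, one carrying an ambiguous signature
toy_edges <- function() {
  tibble::tibble(
    pathway_id = c("amph", "amph", "ferriox", "ferriox", "ent", "ent", "ent"),
    gene_id =    c("gA",   "gB",   "gC",      "gD",      "gE", "gF", "gF"),
    cog_id =     c("C1",   "C2",   "C3",      "C4",      "C5", "C3", "C6"),
    ambiguous =  c(FALSE,  FALSE,  FALSE,     FALSE,     FALSE, FALSE, TRUE)
  )
}

# per-COG coverage tables with one ORF per COG
profile_tables <- function(cov_by_cog) {
  list(
    coverage = tibble::tibble(orf_id = paste0("o_", names(cov_by_cog)),
                              coverage = unname(cov_by_cog)),
    functions = tibble::tibble(orf_id = paste0("o_", names(cov_by_cog)),
                               cog_id = names(cov_by_cog))
  )
}

# lineage as a named chain by climbing parent pointers (independent of the
# package's lineage table)
climb_lineage <- function(tree_df, taxon) {
  parent <- stats::setNames(tree_df$parent_id, tree_df$taxon_id)
  rank <- stats::setNames(tree_df$rank, tree_df$taxon_id)
  out <- character()
  cur <- taxon
  while (!is.na(cur)) {
    if (rank[[cur]] != "norank") out[rank[[cur]]] <- cur
    cur <- parent[[cur]]
  }
  out
}
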