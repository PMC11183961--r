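#' Bundled toy taxonomy for the synthetic study
#'
#' A small ranked tree covering five prokaryotic phyla with full
#' superkingdom-to-species lineages for six focal genera (plus a sister genus
#' per family to serve as decoy hit subjects). The arc it supports mirrors a
#' spring-summer Arctic bloom: a Bacteroidetes flavobacterium that blooms, an
#' alphaproteobacterial pelagibacterale and a gammaproteobacterial producer
#' clade, a declining thaumarchaeon, and minor actinobacterial and
#' verrucomicrobial lineages.
#'
#' @return A [taxonomy()] object.
#' @export
default_taxonomy <- function() {
  n <- function(id, parent, rank) list(id, parent, rank)
  rows <- list(
    n("root", NA, "norank"),
    n("Bacteria", "root", "superkingdom"),
    n("Archaea", "root", "superkingdom"),
    # Bacteroidetes: the bloomer (cheater clade)
    n("Bacteroidetes", "Bacteria", "phylum"),
    n("Flavobacteriia", "Bacteroidetes", "class"),
    n("Flavobacteriales", "Flavobacteriia", "order"),
    n("Flavobacteriaceae", "Flavobacteriales", "family"),
    n("Polaribacter", "Flavobacteriaceae", "genus"),
    n("Polaribacter_sp", "Polaribacter", "species"),
    n("Owenweeksia", "Flavobacteriaceae", "genus"),
    n("Owenweeksia_sp", "Owenweeksia", "species"),
    # Proteobacteria: alpha (transporter-poor) and gamma (producer clade)
    n("Proteobacteria", "Bacteria", "phylum"),
    n("Alphaproteobacteria", "Proteobacteria", "class"),
    n("Pelagibacterales", "Alphaproteobacteria", "order"),
    n("Pelagibacteraceae", "Pelagibacterales", "family"),
    n("Pelagibacter", "Pelagibacteraceae", "genus"),
    n("Pelagibacter_sp", "Pelagibacter", "species"),
    n("Planktomarina", "Pelagibacteraceae", "genus"),
    n("Planktomarina_sp", "Planktomarina", "species"),
    n("Gammaproteobacteria", "Proteobacteria", "class"),
    n("Thiomicrospirales", "Gammaproteobacteria", "order"),
    n("Thioglobaceae", "Thiomicrospirales", "family"),
    n("Thioglobus", "Thioglobaceae", "genus"),
    n("Thioglobus_sp", "Thioglobus", "species"),
    n("Thiomicrorhabdus", "Thioglobaceae", "genus"),
    n("Thiomicrorhabdus_sp", "Thiomicrorhabdus", "species"),
    # Thaumarchaeota: declining archaeon
    n("Thaumarchaeota", "Archaea", "phylum"),
    n("Nitrososphaeria", "Thaumarchaeota", "class"),
    n("Nitrosopumilales", "Nitrososphaeria", "order"),
    n("Nitrosopumilaceae", "Nitrosopumilales", "family"),
    n("Nitrosopumilus", "Nitrosopumilaceae", "genus"),
    n("Nitrosopumilus_sp", "Nitrosopumilus", "species"),
    n("Nitrosarchaeum", "Nitrosopumilaceae", "genus"),
    n("Nitrosarchaeum_sp", "Nitrosarchaeum", "species"),
    # minor phyla
    n("Actinobacteria", "Bacteria", "phylum"),
    n("Acidimicrobiia", "Actinobacteria", "class"),
    n("Acidimicrobiales", "Acidimicrobiia", "order"),
    n("Acidimicrobiaceae", "Acidimicrobiales", "family"),
    n("Actinomarina", "Acidimicrobiaceae", "genus"),
    n("Actinomarina_sp", "Actinomarina", "species"),
    n("Ilumatobacter", "Acidimicrobiaceae", "genus"),
    n("Ilumatobacter_sp", "Ilumatobacter", "species"),
    n("Verrucomicrobia", "Bacteria", "phylum"),
    n("Verrucomicrobiae", "Verrucomicrobia", "class"),
    n("Verrucomicrobiales", "Verrucomicrobiae", "order"),
    n("Rubritaleaceae", "Verrucomicrobiales", "family"),
    n("Luteolibacter", "Rubritaleaceae", "genus"),
    n("Luteolibacter_sp", "Luteolibacter", "species"),
    n("Roseibacillus", "Rubritaleaceae", "genus"),
    n("Roseibacillus_sp", "Roseibacillus", "species")
  )
  taxonomy(tibble::tibble(
    taxon_id = vapply(rows, `[[`, "", 1),
    parent_id = vapply(rows, function(r) {
      p <- r[[2]]; if (is.na(p[1])) NA_character_ else p
    }, ""),
    rank = vapply(rows, `[[`, "", 3),
    name = vapply(rows, `[[`, "", 1)
  ))
}

#' The ten universal single-copy marker COGs used by the synthetic study
#'
#' Placeholder identifiers for the housekeeping single-copy marker set; the
#' real marker list is a user configuration input, supplied to
#' [marker_median()] and [run_pipeline()].
#'
#' @return Character vector of 10 COG ids.
#' @export
default_markers <- function() sprintf("COG55%02d", 1:10)

#' Bundled iron-gene catalog (reduced synthetic fixture)
#'
#' A ~30-entry catalog spanning all nine iron-function categories, standing
#' in for a full supplementary catalog of real studies. The synthesis section
#' carries one deliberately ambiguous COG (an AMP-dependent ligase family,
#' COG0318) that conflates siderophore and non-siderophore enzymes.
#'
#' @return Catalog tibble (see [load_iron_catalog()]).
#' @export
default_catalog <- function() {
  e <- function(cog, cat, genes, amb = FALSE) {
    tibble::tibble(cog_id = cog, category = cat, gene_examples = genes,
                   ambiguous_synthesis = amb)
  }
  dplyr::bind_rows(
    e("COG0370", "Fe(II)", "feoB"),
    e("COG2822", "Fe(II)", "efeU"),
    e("COG1629", "Fe(III)-OM", "fhuA"),
    e("COG4771", "Fe(III)-OM", "fepA"),
    e("COG0609", "Fe(III)-CM", "fhuB"),
    e("COG0614", "Fe(III)-CM", "fhuD"),
    e("COG1121", "divalent_cation", "sitABC znuC"),
    e("COG0803", "divalent_cation", "sitA znuA"),
    e("COG4772", "dicitrate", "fecA"),
    e("COG4558", "heme", "hemR hmuT"),
    e("COG1528", "storage", "bfr ftnA"),
    e("COG0783", "storage", "dps"),
    e("COG0735", "regulators", "fur irr"),
    e("COG1321", "regulators", "mntR ideR"),
    e("COG0318", "siderophore_synthesis", "entE pvdL asbC", amb = TRUE),
    e("COG1021", "siderophore_synthesis", "entE dhbE"),
    e("COG1535", "siderophore_synthesis", "entB"),
    e("COG1819", "siderophore_synthesis", "iroB"),
    e("COG3486", "siderophore_synthesis", "entF pchE irp2"),
    e("COG7001", "siderophore_synthesis", "alcA"),
    e("COG7002", "siderophore_synthesis", "mbtA"),
    e("COG7003", "siderophore_synthesis", "mxcE"),
    e("COG7004", "siderophore_synthesis", "asbA"),
    e("COG7005", "siderophore_synthesis", "sfnaB"),
    e("COG7006", "siderophore_synthesis", "sbnC"),
    e("COG7007", "siderophore_synthesis", "pchA"),
    e("COG7008", "siderophore_synthesis", "pvdJ"),
    e("COG7009", "siderophore_synthesis", "irp1"),
    e("COG7010", "siderophore_synthesis", "sfnaD sbnE"),
    e("COG7011", "siderophore_synthesis", "amphA"),
    e("COG7012", "siderophore_synthesis", "amphB")
  )
}

#' Bundled siderophore pathway definitions (synthetic fixture)
#'
#' Twelve pathways whose structure exercises every branch of the presence
#' classifier against the bundled genomes: eight recoverable as PRESENT
#' (each with at least one unique, unambiguous signature COG), and four as
#' ABSENT (one required gene missing from every genome; the amphibactin-like
#' case misses exactly one gene). Genes shared between pathways (an
#' entE-like ligase carried by two COGs, a promiscuous NRPS COG) reproduce
#' the multi-map structure that makes naive presence calling unreliable.
#'
#' @return Edge tibble with `pathway_id`, `gene_id`, `cog_id`, `ambiguous`,
#'   suitable for [pathway_network()].
#' @export
default_pathway_edges <- function() {
  p <- function(pathway, gene, cog, amb = FALSE) {
    tibble::tibble(pathway_id = pathway, gene_id = gene, cog_id = cog,
                   ambiguous = amb)
  }
  dplyr::bind_rows(
    p("enterobactin", "entB", "COG1535"),
    p("enterobactin", "entE", "COG0318", amb = TRUE),
    p("enterobactin", "entE", "COG1021"),
    p("enterobactin", "entF", "COG3486"),
    p("salmochelin", "iroB", "COG1819"),
    p("salmochelin", "entE", "COG0318", amb = TRUE),
    p("salmochelin", "entE", "COG1021"),
    p("salmochelin", "iroC", "COG3486"),
    p("alcaligin", "alcA", "COG7001"),
    p("alcaligin", "alcB", "COG3486"),
    p("mycobactin", "mbtA", "COG7002"),
    p("mycobactin", "mbtB", "COG3486"),
    p("myxochelin", "mxcE", "COG7003"),
    p("myxochelin", "mxcF", "COG3486"),
    p("petrobactin", "asbA", "COG7004"),
    p("petrobactin", "asbC", "COG0318", amb = TRUE),
    p("staphyloferrin_A", "sfnaB", "COG7005"),
    p("staphyloferrin_A", "sfnaD", "COG7010"),
    p("staphyloferrin_B", "sbnC", "COG7006"),
    p("staphyloferrin_B", "sbnE", "COG7010"),
    p("pyochelin", "pchA", "COG7007"),
    p("pyochelin", "pchE", "COG3486"),
    p("pyoverdin", "pvdL", "COG0318", amb = TRUE),
    p("pyoverdin", "pvdJ", "COG7008"),
    p("yersiniabactin", "irp1", "COG7009"),
    p("yersiniabactin", "irp2", "COG3486"),
    p("amphibactin", "amphA", "COG7011"),
    p("amphibactin", "amphB", "COG7012")
  )
}

#' Bundled genome models for the synthetic community
#'
#' Gene complements (integer copies per genome) for the six focal genera.
#' Every genome carries the ten marker COGs at exactly one copy. The
#' gammaproteobacterial clade is the designated siderophore producer (all
#' signature COGs of the eight recoverable pathways, plus the present
#' amphibactin gene); the blooming Bacteroidetes clade is the designated
#' cheater: no synthesis genes at all, but TonB-dependent outer-membrane
#' ferric-siderophore transporters, including a single-copy fhuA-like
#' receptor whose per-genome copy number anchors the recovery checks. The
#' pelagibacterale carries no TonB-dependent transporters and only a generic
#' ambiguous ligase from the synthesis table.
#'
#' @return List with `complements` (tibble `taxon_id`, `cog_id`, `copies`)
#'   and `roles` (tibble `taxon_id`, `role` in producer/cheater/neither).
#' @export
default_genomes <- function() {
  g <- function(taxon, cog, copies = 1L) {
    tibble::tibble(taxon_id = taxon, cog_id = cog, copies = as.integer(copies))
  }
  markers <- default_markers()
  marker_rows <- purrr::map(
    c("Polaribacter", "Pelagibacter", "Thioglobus", "Nitrosopumilus",
      "Actinomarina", "Luteolibacter"),
    function(t) g(t, markers, 1L)
  )
  producer_synthesis <- c("COG1535", "COG0318", "COG1021", "COG3486",
                          "COG1819", "COG7001", "COG7002", "COG7003",
                          "COG7004", "COG7005", "COG7006", "COG7010",
                          "COG7011")
  complements <- dplyr::bind_rows(
    marker_rows,
    # cheater: transporters only, 1-copy fhuA-like receptor
    g("Polaribacter", "COG1629", 1L),
    g("Polaribacter", "COG4771", 3L),
    g("Polaribacter", "COG0370", 2L),
    g("Polaribacter", "COG0609", 1L),
    g("Polaribacter", "COG1121", 1L),
    g("Polaribacter", "COG4772", 1L),
    g("Polaribacter", "COG0735", 2L),
    g("Polaribacter", "COG0783", 1L),
    # streamlined alphaproteobacterium: no TonB-dependent transporters
    g("Pelagibacter", "COG0609", 1L),
    g("Pelagibacter", "COG0614", 1L),
    g("Pelagibacter", "COG1121", 1L),
    g("Pelagibacter", "COG0735", 1L),
    g("Pelagibacter", "COG0318", 1L),
    # producer gammaproteobacterium
    g("Thioglobus", producer_synthesis, 1L),
    g("Thioglobus", "COG1629", 1L),
    g("Thioglobus", "COG4771", 1L),
    g("Thioglobus", "COG0609", 1L),
    g("Thioglobus", "COG0614", 1L),
    g("Thioglobus", "COG0370", 1L),
    g("Thioglobus", "COG4772", 1L),
    g("Thioglobus", "COG4558", 1L),
    g("Thioglobus", "COG1528", 1L),
    g("Thioglobus", "COG0735", 2L),
    g("Thioglobus", "COG1321", 1L),
    # declining thaumarchaeon
    g("Nitrosopumilus", "COG1121", 2L),
    g("Nitrosopumilus", "COG0803", 1L),
    g("Nitrosopumilus", "COG1528", 1L),
    g("Nitrosopumilus", "COG0735", 1L),
    # minor lineages
    g("Actinomarina", "COG2822", 1L),
    g("Actinomarina", "COG0370", 1L),
    g("Actinomarina", "COG4558", 1L),
    g("Actinomarina", "COG0735", 1L),
    g("Luteolibacter", "COG1121", 1L),
    g("Luteolibacter", "COG0370", 1L),
    g("Luteolibacter", "COG0735", 1L)
  )
  roles <- tibble::tibble(
    taxon_id = c("Polaribacter", "Pelagibacter", "Thioglobus",
                 "Nitrosopumilus", "Actinomarina", "Luteolibacter"),
    role = c("cheater", "neither", "producer", "neither", "neither", "neither")
  )
  list(complements = complements, roles = roles)
}

#' Default community scenario: a 13-sample spring bloom
#'
#' The bundled study conditions: thirteen chronological samples over which
#' the Bacteroidetes flavobacterium blooms from a 9% to a 55% read fraction
#' (logistic trajectory), the alphaproteobacterium recedes from 36% to 21%,
#' the gammaproteobacterial producer stays near one fifth, the thaumarchaeon
#' all but disappears, and two minor phyla decline. Fractions are
#' renormalized to sum to one at each time point.
#'
#' @param n_samples Number of time points (chronological), at least 2.
#' @param reads_per_sample Mapped reads per sample for the multinomial
#'   read-count draw; `Inf` gives exact expected counts.
#' @param noise_cv Coefficient of variation of the lognormal per-ORF
#'   coverage noise; 0 disables noise.
#' @param base_depth Community-wide coverage scale (depth of a single-copy
#'   gene in a genome at fraction 1).
#' @param seed Integer seed; every random draw in the simulator derives from
#'   it.
#' @return A `community_scenario` object.
#' @export
default_scenario <- function(n_samples = 13, reads_per_sample = 1e5,
                             noise_cv = 0.1, base_depth = 100, seed = 1) {
  taxa <- tibble::tibble(
    taxon_id = c("Polaribacter", "Pelagibacter", "Thioglobus",
                 "Nitrosopumilus", "Actinomarina", "Luteolibacter"),
    initial_fraction = c(0.09, 0.36, 0.20, 0.12, 0.04, 0.025),
    final_fraction   = c(0.55, 0.21, 0.18, 0.005, 0.02, 0.005),
    trajectory = c("logistic", "linear", "linear", "linear", "linear", "linear")
  )
  community_scenario(taxa, n_samples = n_samples,
                     reads_per_sample = reads_per_sample,
                     noise_cv = noise_cv, base_depth = base_depth, seed = seed)
}
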