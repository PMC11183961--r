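#' Define a synthetic community scenario
#'
#' A scenario fixes everything the simulator needs: the focal taxa with their
#' initial and final community fractions and trajectory shapes, the number of
#' chronological samples, sequencing effort, coverage noise, and the seed.
#' Given the same scenario and seed the simulator is byte-deterministic.
#'
#' @param taxa Tibble with `taxon_id`, `initial_fraction`, `final_fraction`
#'   (each in `[0, 1]`), `trajectory` (`"linear"` or `"logistic"`).
#' @param n_samples Number of time points, at least 2.
#' @param reads_per_sample Mapped reads per sample (multinomial over
#'   contigs); `Inf` yields exact expected counts.
#' @param noise_cv Coefficient of variation of lognormal per-ORF coverage
#'   noise (mean preserved); 0 disables noise.
#' @param base_depth Coverage of a single-copy gene in a genome at community
#'   fraction 1.
#' @param seed Integer seed.
#' @return A `community_scenario` object.
#' @export
community_scenario <- function(taxa, n_samples = 13, reads_per_sample = 1e5,
                               noise_cv = 0.1, base_depth = 100, seed = 1) {
  taxa <- tibble::as_tibble(taxa)
  required <- c("taxon_id", "initial_fraction", "final_fraction", "trajectory")
  stopifnot(all(required %in% names(taxa)))
  stopifnot(
    n_samples >= 2,
    noise_cv >= 0, base_depth > 0,
    all(taxa$initial_fraction >= 0), all(taxa$initial_fraction <= 1),
    all(taxa$final_fraction >= 0), all(taxa$final_fraction <= 1),
    all(taxa$trajectory %in% c("linear", "logistic"))
  )
  if (sum(taxa$initial_fraction) <= 0 || sum(taxa$final_fraction) <= 0) {
    stop("community fractions sum to 0 at an endpoint")
  }
  structure(
    list(taxa = taxa, n_samples = as.integer(n_samples),
         reads_per_sample = reads_per_sample, noise_cv = noise_cv,
         base_depth = base_depth, seed = as.integer(seed)),
    class = "community_scenario"
  )
}

#' @export
print.community_scenario <- function(x, ...) {
  cat("<community_scenario> ", nrow(x$taxa), " taxa x ", x$n_samples,
      " samples; reads/sample ", format(x$reads_per_sample),
      "; noise cv ", x$noise_cv, "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Ground-truth community trajectories
#'
#' Interpolates each taxon's fraction from its initial to its final value
#' across the time series (linearly, or along a logistic sigmoid for bloom
#' dynamics) and renormalizes fractions to sum to one at every time point.
#' Purely deterministic.
#'
#' @param scenario A [community_scenario()] object.
#' @return Tibble with `sample_id` (chronological `s01`, `s02`, ...),
#'   `taxon_id`, `fraction` (renormalized) and `raw_fraction` (before
#'   renormalization).
#' @export
simulate_community <- function(scenario) {
  stopifnot(inherits(scenario, "community_scenario"))
  n <- scenario$n_samples
  x <- (seq_len(n) - 1) / (n - 1)
  logistic01 <- function(x, k = 8) {
    s <- stats::plogis(k * (x - 0.5))
    (s - s[1]) / (s[length(s)] - s[1])
  }
  shape <- list(linear = x, logistic = logistic01(x))
  out <- purrr::pmap(scenario$taxa, function(taxon_id, initial_fraction,
                                             final_fraction, trajectory, ...) {
    tibble::tibble(
      sample_id = sprintf("s%02d", seq_len(n)),
      taxon_id = taxon_id,
      raw_fraction = initial_fraction +
        (final_fraction - initial_fraction) * shape[[trajectory]]
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(fraction = .data$raw_fraction / sum(.data$raw_fraction)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$sample_id, .data$taxon_id)
  totals <- tapply(out$raw_fraction, out$sample_id, sum)
  if (any(totals <= 0)) stop("community fractions sum to 0 at a time point")
  dplyr::select(out, "sample_id", "taxon_id", "fraction", "raw_fraction")
}

# expand genome complements into one ORF per gene copy, plus unannotated
# background ORFs, and chunk each genome's ORFs into contigs
build_orf_layout <- function(genomes, n_background = 8, orfs_per_contig = 8) {
  comp <- tibble::as_tibble(genomes$complements)
  orfs <- comp[rep(seq_len(nrow(comp)), comp$copies), c("taxon_id", "cog_id")]
  bg <- tibble::tibble(
    taxon_id = rep(unique(comp$taxon_id), each = n_background),
    cog_id = NA_character_
  )
  orfs <- dplyr::bind_rows(orfs, bg) |> dplyr::arrange(.data$taxon_id)
  orfs <- orfs |>
    dplyr::group_by(.data$taxon_id) |>
    dplyr::mutate(orf_id = sprintf("%s_orf%03d", .data$taxon_id,
                                   dplyr::row_number()),
                  contig_id = sprintf("%s_ctg%02d", .data$taxon_id,
                                      (dplyr::row_number() - 1) %/%
                                        orfs_per_contig + 1)) |>
    dplyr::ungroup()
  orfs[c("orf_id", "contig_id", "taxon_id", "cog_id")]
}

#' Simulate the observable tables for one sample
#'
#' From a time point's true taxon fractions, emits what the assembly and
#' mapping stages of a real study would hand downstream: a homology hit
#' table, a per-ORF coverage table, per-contig mapped-read counts, and the
#' ORF-to-contig map. Coverage of each ORF is `base_depth x taxon fraction`
#' (one ORF per gene copy) perturbed by mean-preserving lognormal noise.
#' Hit tables are constructed so the LCA classifier recovers each ORF's true
#' genus: true hits point at the species below the true genus with
#' identities drawn between the genus and species floors, decoy hits point
#' at a sister genus with bitscores below the 80% window.
#'
#' @param fractions Tibble with `taxon_id`, `fraction` for one sample.
#' @param genomes Genome models as from [default_genomes()].
#' @param scenario A [community_scenario()] object (noise, depth, reads,
#'   seed).
#' @param tax A [taxonomy()] object containing every scenario taxon.
#' @param sample_index Integer; offsets the seed so samples differ.
#' @return List with tibbles `hits`, `coverage` (`orf_id`, `coverage`),
#'   `read_counts` (`contig_id`, `reads`), `contig_map` (`orf_id`,
#'   `contig_id`) and `orf_truth` (`orf_id`, `taxon_id`, `cog_id`).
#' @export
simulate_sample_tables <- function(fractions, genomes, scenario, tax,
                                   sample_index = 1L) {
  stopifnot(inherits(scenario, "community_scenario"), inherits(tax, "taxonomy"))
  fractions <- tibble::as_tibble(fractions)
  missing <- setdiff(fractions$taxon_id, genomes$complements$taxon_id)
  if (length(missing)) {
    stop("no genome model for taxon: ", paste(missing, collapse = ", "))
  }
  set.seed((scenario$seed %% 100000L) * 10000L + 7L * as.integer(sample_index))

  layout <- build_orf_layout(genomes)
  layout <- layout[layout$taxon_id %in% fractions$taxon_id, ]
  frac <- stats::setNames(fractions$fraction, fractions$taxon_id)
  n_orf <- nrow(layout)

  noise <- if (scenario$noise_cv > 0) {
    sdlog <- sqrt(log(1 + scenario$noise_cv^2))
    stats::rlnorm(n_orf, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else rep(1, n_orf)
  coverage <- tibble::tibble(
    orf_id = layout$orf_id,
    coverage = scenario$base_depth * frac[layout$taxon_id] * noise
  )

  # species below each true genus, and a sister genus's species for decoys
  genus_species <- species_under_genus(tax)
  true_species <- genus_species$species[match(layout$taxon_id,
                                              genus_species$genus)]
  sister_species <- genus_species$sister_species[match(layout$taxon_id,
                                                       genus_species$genus)]
  n_true <- 4L
  n_decoy <- 2L
  per_orf <- n_true + n_decoy
  best_bit <- 200
  true_bits <- matrix(stats::runif(n_orf * n_true, 0.85 * best_bit, best_bit),
                      n_orf)
  true_idents <- matrix(stats::runif(n_orf * n_true, 61, 84), n_orf)
  decoy_bits <- matrix(stats::runif(n_orf * n_decoy, 0.4 * best_bit,
                                    0.6 * best_bit), n_orf)
  decoy_idents <- matrix(stats::runif(n_orf * n_decoy, 40, 60), n_orf)
  hits <- tibble::tibble(
    query_id = rep(layout$orf_id, each = per_orf),
    subject_id = paste0("ref_", rep(seq_len(n_orf), each = per_orf), "_",
                        rep(seq_len(per_orf), n_orf)),
    percent_identity = as.vector(rbind(t(true_idents), t(decoy_idents))),
    alignment_length = 250L,
    bitscore = as.vector(rbind(t(true_bits), t(decoy_bits))),
    evalue = 1e-80,
    subject_taxon = as.vector(rbind(
      matrix(rep(true_species, each = n_true), nrow = n_true),
      matrix(rep(sister_species, each = n_decoy), nrow = n_decoy)
    )),
    subject_cog = as.vector(rbind(
      matrix(rep(layout$cog_id, each = n_true), nrow = n_true),
      matrix(NA_character_, nrow = n_decoy, ncol = n_orf)
    ))
  )

  # a taxon's total read mass is proportional to its community fraction
  # (fractions are defined on reads); within a taxon, reads spread over its
  # contigs proportionally to contig size
  contig_sizes <- dplyr::count(layout, .data$contig_id, .data$taxon_id,
                               name = "n_orfs")
  contig_sizes <- contig_sizes |>
    dplyr::group_by(.data$taxon_id) |>
    dplyr::mutate(within = .data$n_orfs / sum(.data$n_orfs)) |>
    dplyr::ungroup()
  probs <- frac[contig_sizes$taxon_id] * contig_sizes$within
  probs <- probs / sum(probs)
  reads <- if (is.finite(scenario$reads_per_sample)) {
    as.numeric(stats::rmultinom(1, scenario$reads_per_sample, probs))
  } else {
    probs
  }
  list(
    hits = hits,
    coverage = coverage,
    read_counts = tibble::tibble(contig_id = contig_sizes$contig_id,
                                 reads = reads),
    contig_map = layout[c("orf_id", "contig_id")],
    orf_truth = layout[c("orf_id", "taxon_id", "cog_id")]
  )
}

# for each genus in the tree: one species under it (hit subjects) and a
# species under a sister genus of the same family (decoy subjects)
species_under_genus <- function(tax) {
  lin <- tax$lineage
  sp <- lin[!is.na(lin$species) & lin$taxon_id == lin$species, ]
  genus <- sp$genus
  family <- sp$family
  sister <- vapply(seq_len(nrow(sp)), function(i) {
    others <- sp$species[sp$family == family[i] & sp$genus != genus[i]]
    if (length(others)) others[1] else sp$species[i]
  }, character(1))
  tibble::tibble(genus = genus, species = sp$species, sister_species = sister)
}

#' Simulate a complete multi-sample study
#'
#' Runs [simulate_community()] and [simulate_sample_tables()] for every time
#' point of the scenario.
#'
#' @param scenario A [community_scenario()] object.
#' @param genomes Genome models (default [default_genomes()]).
#' @param tax A [taxonomy()] object (default [default_taxonomy()]).
#' @return List with `community` (truth fractions), `samples` (named list of
#'   per-sample table sets), `scenario`, `genomes`, `tax`.
#' @export
simulate_study <- function(scenario = default_scenario(),
                           genomes = default_genomes(),
                           tax = default_taxonomy()) {
  community <- simulate_community(scenario)
  sample_ids <- unique(community$sample_id)
  samples <- purrr::map(seq_along(sample_ids), function(i) {
    fr <- community[community$sample_id == sample_ids[i], ]
    simulate_sample_tables(fr, genomes, scenario, tax, sample_index = i)
  })
  names(samples) <- sample_ids
  list(community = community, samples = samples, scenario = scenario,
       genomes = genomes, tax = tax)
}

#' Export the study's ground truth
#'
#' The tables recovery tests compare pipeline output against: true taxon
#' fractions per sample (with phylum roll-up), true community-average copy
#' numbers per COG (`sum over taxa of fraction x copies`, since the marker
#' median normalizes to one genome), and true pathway statuses implied by
#' the union of all genome complements.
#'
#' @param scenario A [community_scenario()] object.
#' @param genomes Genome models.
#' @param tax A [taxonomy()] object.
#' @param network Optional [pathway_network()] for truth statuses.
#' @return List of tibbles: `fractions` (per sample, with `phylum`),
#'   `copy_numbers` (`sample_id`, `cog_id`, `copy_number`), and, when a
#'   network is given, `pathway_status` (`pathway_id`, `status`).
#' @export
export_ground_truth <- function(scenario, genomes, tax = default_taxonomy(),
                                network = NULL) {
  community <- simulate_community(scenario)
  community$phylum <- lineage_at_rank(tax, community$taxon_id, "phylum")
  comp <- tibble::as_tibble(genomes$complements)
  cns <- dplyr::inner_join(community, comp, by = "taxon_id",
                           relationship = "many-to-many") |>
    dplyr::group_by(.data$sample_id, .data$cog_id) |>
    dplyr::summarise(copy_number = sum(.data$fraction * .data$copies),
                     .groups = "drop")
  out <- list(fractions = community, copy_numbers = cns)
  if (!is.null(network)) {
    present <- unique(comp$cog_id[comp$copies > 0])
    out$pathway_status <- purrr::map(names(network$pathways),
                                     classify_pathway, network = network,
                                     present_cogs = present) |>
      dplyr::bind_rows() |>
      dplyr::select("pathway_id", "status")
  }
  out
}
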