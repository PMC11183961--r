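#' Consensus taxonomy for contigs from their ORF annotations
#'
#' Walks the rank ladder from superkingdom downward. At each rank the
#' candidate taxa are those consistent with the taxon chosen at the previous
#' rank; a candidate is accepted when it is claimed by at least
#' `min_fraction_all` of all the contig's ORFs (annotated or not) and at
#' least `min_fraction_annotated` of the ORFs annotated at that rank. The
#' consensus is the taxon at the deepest rank reached before the rule first
#' fails; a contig failing already at superkingdom is unclassified.
#' Unclassified ORFs count toward the total but never toward the annotated
#' denominator.
#'
#' @param orf_taxonomies Tibble from [classify_orfs()] (`orf_id`,
#'   `assigned_taxon`, ...).
#' @param contig_map Tibble mapping `orf_id` to `contig_id`.
#' @param tax A [taxonomy()] object.
#' @param params A [consensus_params()] object.
#' @return Tibble with one row per contig: `contig_id`, `assigned_taxon`
#'   (`NA` when unclassified), `assigned_rank`, `n_orfs`.
#' @export
consensus_taxonomy <- function(orf_taxonomies, contig_map, tax,
                               params = consensus_params()) {
  stopifnot(inherits(tax, "taxonomy"), inherits(params, "consensus_params"))
  df <- dplyr::inner_join(tibble::as_tibble(contig_map),
                          tibble::as_tibble(orf_taxonomies),
                          by = "orf_id")
  contigs <- unique(df$contig_id)
  ranks <- tax_ranks()
  lin <- tax$lineage
  idx <- match(df$assigned_taxon, lin$taxon_id)
  anc <- lapply(ranks, function(r) lin[[r]][idx])
  names(anc) <- ranks

  out <- purrr::map(split(seq_len(nrow(df)), df$contig_id), function(rows) {
    total <- length(rows)
    chosen <- NA_character_
    chosen_rank <- NA_character_
    for (r in ranks) {
      at_rank <- anc[[r]][rows]
      annotated <- sum(!is.na(at_rank))
      if (annotated == 0) break
      counts <- table(at_rank)
      if (!is.na(chosen)) {
        # parent consistency: candidate's ancestor at the previous rank must
        # be the taxon already chosen there
        prev <- ranks[match(r, ranks) - 1L]
        parents <- lin[[prev]][match(names(counts), lin$taxon_id)]
        counts <- counts[!is.na(parents) & parents == chosen]
      }
      if (!length(counts)) break
      ok <- frac_ge(counts, total, params$min_fraction_all) &
        frac_ge(counts, annotated, params$min_fraction_annotated)
      if (!any(ok)) break
      counts <- counts[ok]
      chosen <- names(counts)[order(-counts, names(counts))][1]
      chosen_rank <- r
    }
    tibble::tibble(assigned_taxon = chosen, assigned_rank = chosen_rank,
                   n_orfs = total)
  })
  res <- dplyr::bind_rows(out, .id = "contig_id")
  res[match(contigs, res$contig_id), ]
}

#' Consensus taxonomy for a single contig
#'
#' Convenience wrapper over [consensus_taxonomy()] for the ORFs of one
#' contig.
#'
#' @param orf_taxonomies Tibble of ORF taxonomies for one contig (nonempty).
#' @param tax A [taxonomy()] object.
#' @param params A [consensus_params()] object.
#' @return One-row tibble (`contig_id` set to `"contig"`).
#' @export
consensus_contig_taxonomy <- function(orf_taxonomies, tax,
                                      params = consensus_params()) {
  orf_taxonomies <- tibble::as_tibble(orf_taxonomies)
  stopifnot(nrow(orf_taxonomies) > 0)
  cm <- tibble::tibble(orf_id = orf_taxonomies$orf_id, contig_id = "contig")
  consensus_taxonomy(orf_taxonomies, cm, tax, params)
}

#' Per-taxon read fractions at a target rank
#'
#' Rolls each contig's consensus taxon up to its lineage ancestor at the
#' target rank and sums mapped reads per taxon. Contigs that are
#' unclassified, or whose lineage does not pass through the target rank, fall
#' into an explicit `"unclassified"` bucket. Fractions sum to 1.
#'
#' @param contig_taxa Tibble with `contig_id`, `assigned_taxon`.
#' @param read_counts Tibble with `contig_id`, `reads` (mapped-read counts).
#' @param tax A [taxonomy()] object.
#' @param rank Target rank from [tax_ranks()].
#' @return Tibble with `taxon` (taxon id at `rank`, or `"unclassified"`) and
#'   `fraction`, sorted by decreasing fraction.
#' @export
taxon_read_fractions <- function(contig_taxa, read_counts, tax, rank = "phylum") {
  stopifnot(inherits(tax, "taxonomy"), rank %in% tax_ranks())
  df <- dplyr::inner_join(tibble::as_tibble(read_counts),
                          tibble::as_tibble(contig_taxa),
                          by = "contig_id")
  total <- sum(df$reads)
  if (total <= 0) stop("total mapped reads is zero; fractions undefined")
  df$taxon <- lineage_at_rank(tax, df$assigned_taxon, rank)
  df$taxon[is.na(df$taxon)] <- "unclassified"
  df |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(fraction = sum(.data$reads) / total, .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$fraction))
}
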