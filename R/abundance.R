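#' Aggregate per-ORF coverage by COG
#'
#' @param coverage Tibble with `orf_id`, `coverage` (mean aligned depth per
#'   base).
#' @param orf_functions Tibble with `orf_id`, `cog_id`.
#' @param agg `"sum"` (default) adds the coverages of all ORFs annotated to a
#'   COG; `"mean"` averages them.
#' @return Tibble with `cog_id`, `coverage`, one row per annotated COG.
#' @export
cog_coverage <- function(coverage, orf_functions, agg = c("sum", "mean")) {
  agg <- match.arg(agg)
  f <- if (agg == "sum") sum else mean
  dplyr::inner_join(tibble::as_tibble(coverage),
                    tibble::as_tibble(orf_functions), by = "orf_id") |>
    dplyr::filter(!is.na(.data$cog_id)) |>
    dplyr::group_by(.data$cog_id) |>
    dplyr::summarise(coverage = f(.data$coverage), .groups = "drop")
}

#' Median coverage of the universal single-copy marker genes
#'
#' The per-genome normalization denominator: every marker COG's aggregate
#' coverage is computed (markers with no annotated ORF contribute 0) and the
#' median over the marker set is returned; with an even count the mean of the
#' two central values. Because the markers occur once per genome in
#' essentially all prokaryotes, this median estimates "genomes sequenced per
#' sample" on the coverage scale.
#'
#' @param coverage Tibble with `orf_id`, `coverage`.
#' @param orf_functions Tibble with `orf_id`, `cog_id`.
#' @param markers Character vector of marker COG ids (ten in the standard
#'   configuration).
#' @param agg Aggregation of multiple ORFs hitting the same marker COG;
#'   `"sum"` by default.
#' @return The median marker coverage (positive scalar).
#' @export
marker_median <- function(coverage, orf_functions, markers,
                          agg = c("sum", "mean")) {
  stopifnot(length(markers) >= 1)
  agg <- match.arg(agg)
  cogs <- cog_coverage(coverage, orf_functions, agg)
  aggregates <- stats::setNames(rep(0, length(markers)), markers)
  found <- intersect(markers, cogs$cog_id)
  aggregates[found] <- cogs$coverage[match(found, cogs$cog_id)]
  med <- stats::median(aggregates)
  if (med <= 0) {
    stop("marker median coverage is 0; the profile cannot be normalized ",
         "(markers with evidence: ", sum(aggregates > 0), "/", length(markers), ")")
  }
  med
}

#' Coverage-to-copy-number conversion
#'
#' Average gene copies per genome: a feature's aggregate coverage divided by
#' the median coverage of the universal single-copy markers. Dimensionless;
#' invariant under global rescaling of coverages within a sample.
#'
#' @param target_coverage Aggregate coverage of a COG, category, or ORF set
#'   (vectorized).
#' @param marker_median Positive marker median from [marker_median()].
#' @return `target_coverage / marker_median`.
#' @export
copy_number <- function(target_coverage, marker_median) {
  if (!is.numeric(marker_median) || length(marker_median) != 1 ||
      marker_median <= 0) {
    stop("marker_median must be a positive scalar")
  }
  target_coverage / marker_median
}

#' Build a normalized abundance profile for one sample
#'
#' Bundles the per-sample quantities the downstream stages consume: per-COG
#' aggregate coverages, the marker median, and copy numbers per COG and per
#' iron-function category (category copy number is the sum of its member
#' COGs' copy numbers).
#'
#' @param coverage Tibble with `orf_id`, `coverage` for one sample.
#' @param orf_functions Tibble with `orf_id`, `cog_id`.
#' @param markers Character vector of marker COG ids.
#' @param catalog Catalog tibble from [load_iron_catalog()].
#' @param sample_id Optional sample label.
#' @return An `abundance_profile` object: list with `sample_id`,
#'   `marker_median`, `cov_by_cog`, `cn_by_cog` (tibbles with `cog_id`,
#'   `coverage`, `copy_number`), and `cn_by_category` (tibble with
#'   `category`, `coverage`, `copy_number` over the catalog categories).
#' @export
abundance_profile <- function(coverage, orf_functions, markers, catalog,
                              sample_id = NA_character_) {
  catalog <- validate_iron_catalog(catalog)
  cov_cog <- cog_coverage(coverage, orf_functions)
  med <- marker_median(coverage, orf_functions, markers)
  cn_cog <- dplyr::mutate(cov_cog, copy_number = copy_number(.data$coverage, med))
  by_cat <- cn_cog |>
    dplyr::inner_join(catalog[c("cog_id", "category")], by = "cog_id") |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(coverage = sum(.data$coverage),
                     copy_number = sum(.data$copy_number), .groups = "drop")
  all_cat <- tibble::tibble(category = iron_categories())
  by_cat <- dplyr::left_join(all_cat, by_cat, by = "category") |>
    tidyr::replace_na(list(coverage = 0, copy_number = 0))
  structure(
    list(sample_id = sample_id, marker_median = med,
         cov_by_cog = cov_cog, cn_by_cog = cn_cog, cn_by_category = by_cat),
    class = "abundance_profile"
  )
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat("<abundance_profile> sample ", x$sample_id,
      "; marker median ", signif(x$marker_median, 4),
      "; ", nrow(x$cn_by_cog), " COGs\n", sep = "")
  invisible(x)
}

#' Taxonomic breakdown of a functional category's coverage
#'
#' Shares of a category's total coverage attributed to each taxon at a target
#' rank, using the per-ORF taxonomies (functions are attributed by ORF, not
#' contig). ORFs unclassified at the target rank fall into an
#' `"unclassified"` bucket. Shares sum to 1; an empty or zero-coverage
#' category yields an empty table.
#'
#' @param category_orfs Character vector of ORF ids in the category.
#' @param orf_taxonomies Tibble from [classify_orfs()].
#' @param coverage Tibble with `orf_id`, `coverage`.
#' @param tax A [taxonomy()] object.
#' @param rank Target rank from [tax_ranks()].
#' @return Tibble with `taxon`, `coverage`, `fraction`, sorted by decreasing
#'   share.
#' @export
category_breakdown <- function(category_orfs, orf_taxonomies, coverage, tax,
                               rank = "phylum") {
  stopifnot(inherits(tax, "taxonomy"), rank %in% tax_ranks())
  empty <- tibble::tibble(taxon = character(), coverage = numeric(),
                          fraction = numeric())
  if (length(category_orfs) == 0) return(empty)
  df <- tibble::as_tibble(coverage) |>
    dplyr::filter(.data$orf_id %in% category_orfs) |>
    dplyr::left_join(tibble::as_tibble(orf_taxonomies)[c("orf_id", "assigned_taxon")],
                     by = "orf_id")
  total <- sum(df$coverage)
  if (!nrow(df) || total <= 0) return(empty)
  df$taxon <- lineage_at_rank(tax, df$assigned_taxon, rank)
  df$taxon[is.na(df$taxon)] <- "unclassified"
  df |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(coverage = sum(.data$coverage), .groups = "drop") |>
    dplyr::mutate(fraction = .data$coverage / total) |>
    dplyr::arrange(dplyr::desc(.data$fraction))
}
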