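#' Best-hit COG assignment for every ORF in a hit table
#'
#' Each query is annotated with the COG of its best hit (maximum bitscore
#' among hits with e-value at or below the cutoff; ties broken by lower
#' e-value, then higher identity, then input order). Queries with no
#' qualifying hit, or whose best hit carries no COG label, come back `NA`.
#'
#' @param hits Hit tibble with `subject_cog` labels.
#' @param evalue_cutoff Maximum e-value for a hit to qualify.
#' @return Tibble with `orf_id` and `cog_id` (`NA` when unannotated), one row
#'   per query in first-appearance order.
#' @export
annotate_cogs <- function(hits, evalue_cutoff = 1e-3) {
  hits <- tibble::as_tibble(hits)
  all_queries <- unique(hits$query_id)
  if (nrow(hits) == 0) {
    return(tibble::tibble(orf_id = character(), cog_id = character()))
  }
  hits$.row <- seq_len(nrow(hits))
  best <- hits |>
    dplyr::filter(.data$evalue <= evalue_cutoff + 1e-300) |>
    dplyr::arrange(.data$query_id, dplyr::desc(.data$bitscore), .data$evalue,
                   dplyr::desc(.data$percent_identity), .data$.row) |>
    dplyr::distinct(.data$query_id, .keep_all = TRUE)
  out <- tibble::tibble(
    orf_id = all_queries,
    cog_id = best$subject_cog[match(all_queries, best$query_id)]
  )
  out
}

#' COG assignment for a single ORF
#'
#' @param hits Hit tibble for one query.
#' @param evalue_cutoff Maximum e-value for a hit to qualify.
#' @return The best hit's COG id, or `NA_character_` when no hit qualifies.
#' @export
assign_cog <- function(hits, evalue_cutoff = 1e-3) {
  hits <- tibble::as_tibble(hits)
  if (nrow(hits) == 0) return(NA_character_)
  if (length(unique(hits$query_id)) != 1L) {
    stop("assign_cog expects hits for exactly one query")
  }
  annotate_cogs(hits, evalue_cutoff)$cog_id[1]
}

#' Load a catalog of iron-related COGs
#'
#' Reads a TSV with columns `cog_id`, `category`, `gene_examples`,
#' `ambiguous_synthesis`. Categories must come from the closed vocabulary of
#' [iron_categories()]; each COG belongs to exactly one category. The
#' `ambiguous_synthesis` flag marks synthesis COGs that conflate siderophore
#' and non-siderophore enzymes: they count toward pathway-gene presence but
#' are excluded from synthesis quantitation.
#'
#' @param path Path to the catalog TSV.
#' @return Tibble with those four columns (`ambiguous_synthesis` logical).
#' @export
load_iron_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  df <- readr::read_tsv(path,
                        col_types = readr::cols(.default = readr::col_character()),
                        na = c("", "."), progress = FALSE)
  validate_iron_catalog(df)
}

validate_iron_catalog <- function(df) {
  df <- tibble::as_tibble(df)
  required <- c("cog_id", "category")
  if (!all(required %in% names(df))) {
    stop("catalog needs columns: ", paste(required, collapse = ", "))
  }
  if (!"gene_examples" %in% names(df)) df$gene_examples <- NA_character_
  if (!"ambiguous_synthesis" %in% names(df)) df$ambiguous_synthesis <- FALSE
  if (is.character(df$ambiguous_synthesis)) {
    df$ambiguous_synthesis <- tolower(df$ambiguous_synthesis) %in%
      c("true", "t", "1", "yes")
  }
  df$ambiguous_synthesis[is.na(df$ambiguous_synthesis)] <- FALSE
  bad <- setdiff(unique(df$category), iron_categories())
  if (length(bad)) {
    stop("unknown iron category: ", paste(bad, collapse = ", "),
         " (allowed: ", paste(iron_categories(), collapse = ", "), ")")
  }
  if (anyDuplicated(df$cog_id)) {
    stop("duplicate cog_id in catalog: ",
         paste(unique(df$cog_id[duplicated(df$cog_id)]), collapse = ", "))
  }
  df[c("cog_id", "category", "gene_examples", "ambiguous_synthesis")]
}

#' Partition ORFs into iron-function categories
#'
#' Joins per-ORF COG assignments against the catalog. ORFs whose COG is
#' absent from the catalog (or who have no COG) fall into the implicit
#' `"non_iron"` pool, so every ORF lands in exactly one category and the
#' category sizes partition the input.
#'
#' @param orf_functions Tibble with `orf_id`, `cog_id` from [annotate_cogs()].
#' @param catalog Catalog tibble from [load_iron_catalog()].
#' @return Tibble with `orf_id`, `cog_id`, `category` (`"non_iron"` for
#'   uncataloged ORFs).
#' @export
categorize_orfs <- function(orf_functions, catalog) {
  orf_functions <- tibble::as_tibble(orf_functions)
  catalog <- validate_iron_catalog(catalog)
  out <- dplyr::left_join(orf_functions[c("orf_id", "cog_id")],
                          catalog[c("cog_id", "category")], by = "cog_id")
  out$category[is.na(out$category)] <- "non_iron"
  out
}
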