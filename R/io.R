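#' Read a 12-column tabular protein-homology hit file
#'
#' Parses the de facto tabular alignment layout (one row per query-subject
#' alignment: query, subject, percent identity, alignment length, mismatches,
#' gap opens, qstart, qend, sstart, send, e-value, bitscore) and joins
#' per-subject taxon and COG labels from a lookup table. Subjects absent from
#' the lookup are kept with empty labels, never dropped; downstream modules
#' decide how unlabeled hits are treated.
#'
#' @param path Path to the tab-separated hit file (no header).
#' @param subject_map Optional data frame with column `subject_id` and any of
#'   `taxon_id`, `cog_id` giving per-subject labels. `NULL` leaves all labels
#'   `NA`.
#' @return Tibble of hit records in file order with columns `query_id`,
#'   `subject_id`, `percent_identity`, `alignment_length`, `bitscore`,
#'   `evalue`, `subject_taxon`, `subject_cog`. An empty file yields a
#'   zero-row tibble.
#' @export
read_alignment_table <- function(path, subject_map = NULL) {
  if (!file.exists(path)) stop("hit file not found: ", path)
  cols <- c("query_id", "subject_id", "pident", "length", "mismatches",
            "gapopens", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  raw <- suppressWarnings(
    readr::read_tsv(path, col_names = cols,
                    col_types = readr::cols(.default = readr::col_character()),
                    na = character(), progress = FALSE)
  )
  if (nrow(raw) == 0) return(empty_hit_table())
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stop("malformed hit file ", path, ": wrong column count at line ",
         paste(unique(probs$row), collapse = ", "))
  }
  for (col in c("pident", "evalue", "bitscore", "length")) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(val))
    if (length(bad)) {
      stop("malformed hit file ", path, ": non-numeric ", col, " ('",
           raw[[col]][bad[1]], "') at line ", bad[1])
    }
    raw[[col]] <- val
  }
  if (any(raw$query_id == "")) {
    stop("malformed hit file ", path, ": empty query_id at line ",
         which(raw$query_id == "")[1])
  }
  if (any(raw$pident < 0 | raw$pident > 100)) {
    stop("malformed hit file ", path, ": percent identity outside [0,100] at line ",
         which(raw$pident < 0 | raw$pident > 100)[1])
  }
  if (any(raw$evalue < 0) || any(raw$bitscore < 0)) {
    stop("malformed hit file ", path, ": negative e-value or bitscore")
  }
  hits <- tibble::tibble(
    query_id = raw$query_id,
    subject_id = raw$subject_id,
    percent_identity = raw$pident,
    alignment_length = as.integer(raw$length),
    bitscore = raw$bitscore,
    evalue = raw$evalue
  )
  join_subject_labels(hits, subject_map)
}

empty_hit_table <- function() {
  tibble::tibble(
    query_id = character(), subject_id = character(),
    percent_identity = numeric(), alignment_length = integer(),
    bitscore = numeric(), evalue = numeric(),
    subject_taxon = character(), subject_cog = character()
  )
}

join_subject_labels <- function(hits, subject_map) {
  hits$subject_taxon <- NA_character_
  hits$subject_cog <- NA_character_
  if (is.null(subject_map)) return(hits)
  subject_map <- tibble::as_tibble(subject_map)
  stopifnot("subject_id" %in% names(subject_map))
  idx <- match(hits$subject_id, subject_map$subject_id)
  if ("taxon_id" %in% names(subject_map)) {
    hits$subject_taxon <- as.character(subject_map$taxon_id)[idx]
  }
  if ("cog_id" %in% names(subject_map)) {
    hits$subject_cog <- as.character(subject_map$cog_id)[idx]
  }
  hits$subject_taxon[hits$subject_taxon %in% c("", ".")] <- NA_character_
  hits$subject_cog[hits$subject_cog %in% c("", ".")] <- NA_character_
  hits
}

#' Read a ranked taxonomy table
#'
#' Expects a TSV with header columns `taxon_id`, `parent_id`, `rank`, `name`.
#' The root row carries `NA`, `""` or `"."` as its parent. Ranks outside the
#' ladder are stored as `"norank"`. Structural defects (missing parent, two
#' roots, cycles) are errors.
#'
#' @param path Path to the taxonomy TSV.
#' @return A [taxonomy()] object.
#' @export
read_taxonomy_table <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  nodes <- readr::read_tsv(path,
                           col_types = readr::cols(.default = readr::col_character()),
                           na = c("", "."), progress = FALSE)
  taxonomy(nodes)
}

#' Read a siderophore pathway definition table
#'
#' Expects a TSV with header columns `pathway_id`, `gene_id`, `cog_id` and an
#' optional logical column `ambiguous` flagging COGs that conflate siderophore
#' biosynthesis with unrelated functions (curation input; not recomputable
#' here). A gene may map to several COGs (alternative signatures of the same
#' gene) and a COG may serve several pathways; pathway-level uniqueness flags
#' are always derived from the table, never read from it.
#'
#' @param path Path to the pathway TSV.
#' @return A [pathway_network()] object.
#' @export
read_pathway_table <- function(path) {
  if (!file.exists(path)) stop("pathway file not found: ", path)
  df <- readr::read_tsv(path,
                        col_types = readr::cols(.default = readr::col_character()),
                        na = c("", "."), progress = FALSE)
  if (nrow(df) == 0) stop("pathway table is empty (no pathways defined)")
  if ("ambiguous" %in% names(df)) {
    df$ambiguous <- tolower(df$ambiguous) %in% c("true", "t", "1", "yes")
  }
  pathway_network(df)
}

#' Write a pipeline output table as TSV
#'
#' All pipeline outputs are plain TSV with a header line and `"."` for
#' missing values, so they diff cleanly and read back identically.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @return `x`, invisibly (pipe-friendly).
#' @export
write_iron_tsv <- function(x, path) {
  readr::write_tsv(x, path, na = ".", progress = FALSE)
  invisible(x)
}

#' Read a pipeline output table back
#'
#' Inverse of [write_iron_tsv()]: TSV with header, `"."` as missing.
#'
#' @param path Path to the TSV.
#' @param col_types Optional readr column specification.
#' @return Tibble.
#' @export
read_iron_tsv <- function(path, col_types = NULL) {
  readr::read_tsv(path, na = ".", col_types = col_types, progress = FALSE,
                  show_col_types = FALSE)
}
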