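#' Build a ranked taxonomy tree
#'
#' Validates a node table (one row per taxon) into a `taxonomy` object: the
#' substrate for LCA and consensus calls. The tree must have exactly one root
#' (a row whose `parent_id` is `NA`, `""` or `"."`), acyclic parent links, and
#' every parent present in the table. Ranks outside the seven-level ladder of
#' [tax_ranks()] are kept but coerced to `"norank"`; such nodes pass lineages
#' through but never receive direct rank assignments.
#'
#' @param nodes Data frame with columns `taxon_id`, `parent_id`, `rank`,
#'   `name` (`name` optional; defaults to `taxon_id`).
#' @return A `taxonomy` object: list with `nodes` (validated tibble) and
#'   `lineage` (one row per taxon, one column per rank holding the
#'   ancestor-or-self taxon at that rank, `NA` where the lineage has none).
#' @examples
#' tax <- taxonomy(data.frame(
#'   taxon_id  = c("root", "p1", "g1"),
#'   parent_id = c(NA, "root", "p1"),
#'   rank      = c("norank", "phylum", "genus"),
#'   name      = c("root", "PhylumOne", "GenusOne")
#' ))
#' lineage_at_rank(tax, "g1", "phylum")
#' @export
taxonomy <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)
  required <- c("taxon_id", "parent_id", "rank")
  if (!all(required %in% names(nodes))) {
    stop("taxonomy nodes need columns: ", paste(required, collapse = ", "))
  }
  if (!"name" %in% names(nodes)) nodes$name <- nodes$taxon_id
  nodes <- dplyr::mutate(
    nodes,
    taxon_id  = as.character(.data$taxon_id),
    parent_id = as.character(.data$parent_id),
    rank      = as.character(.data$rank),
    name      = as.character(.data$name)
  )
  if (anyDuplicated(nodes$taxon_id)) {
    stop("duplicate taxon_id: ",
         paste(unique(nodes$taxon_id[duplicated(nodes$taxon_id)]), collapse = ", "))
  }
  root_marker <- is.na(nodes$parent_id) | nodes$parent_id %in% c("", ".")
  if (sum(root_marker) != 1L) {
    stop("taxonomy must have exactly one root, found ", sum(root_marker))
  }
  if (any(!root_marker & nodes$parent_id == nodes$taxon_id)) {
    bad <- nodes$taxon_id[!root_marker & nodes$parent_id == nodes$taxon_id]
    stop("cycle: taxon is its own parent: ", paste(bad, collapse = ", "))
  }
  missing_parent <- !root_marker & !(nodes$parent_id %in% nodes$taxon_id)
  if (any(missing_parent)) {
    stop("parent_id not in table: ",
         paste(unique(nodes$parent_id[missing_parent]), collapse = ", "))
  }
  nodes$rank[!nodes$rank %in% tax_ranks()] <- "norank"

  parent <- stats::setNames(nodes$parent_id, nodes$taxon_id)
  parent[root_marker[match(names(parent), nodes$taxon_id)]] <- NA_character_
  rank_of <- stats::setNames(nodes$rank, nodes$taxon_id)

  n <- nrow(nodes)
  lineage <- matrix(NA_character_, nrow = n, ncol = length(tax_ranks()),
                    dimnames = list(NULL, tax_ranks()))
  for (i in seq_len(n)) {
    cur <- nodes$taxon_id[i]
    steps <- 0L
    while (!is.na(cur)) {
      r <- rank_of[[cur]]
      if (r != "norank") lineage[i, r] <- cur
      cur <- parent[[cur]]
      steps <- steps + 1L
      if (steps > n) {
        stop("cycle detected in taxonomy at taxon ", nodes$taxon_id[i])
      }
    }
  }
  lineage <- tibble::as_tibble(lineage)
  lineage$taxon_id <- nodes$taxon_id

  structure(
    list(nodes = nodes,
         lineage = dplyr::relocate(lineage, "taxon_id")),
    class = "taxonomy"
  )
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("<taxonomy> ", nrow(x$nodes), " taxa; ranks: ",
      paste(intersect(tax_ranks(), unique(x$nodes$rank)), collapse = " > "),
      "\n", sep = "")
  invisible(x)
}

#' Ancestor of a taxon at a given rank
#'
#' @param tax A [taxonomy()] object.
#' @param taxon_id Character vector of taxon identifiers (vectorized).
#' @param rank One rank from [tax_ranks()].
#' @return Character vector of ancestor-or-self taxon ids at `rank`, `NA`
#'   where the lineage does not pass through that rank.
#' @export
lineage_at_rank <- function(tax, taxon_id, rank) {
  stopifnot(inherits(tax, "taxonomy"), rank %in% tax_ranks())
  idx <- match(taxon_id, tax$lineage$taxon_id)
  if (anyNA(idx) && any(!is.na(taxon_id[is.na(idx)]))) {
    bad <- unique(taxon_id[is.na(idx) & !is.na(taxon_id)])
    stop("taxon not in taxonomy: ", paste(bad, collapse = ", "))
  }
  tax$lineage[[rank]][idx]
}

#' Human-readable lineage string for a taxon
#'
#' @param tax A [taxonomy()] object.
#' @param taxon_id Character vector of taxon ids.
#' @param sep Separator between rank names.
#' @return Character vector like `"Bacteria;Bacteroidetes;...;Polaribacter"`,
#'   using node names at the ranked levels present in each lineage.
#' @export
lineage_string <- function(tax, taxon_id, sep = ";") {
  stopifnot(inherits(tax, "taxonomy"))
  name_of <- stats::setNames(tax$nodes$name, tax$nodes$taxon_id)
  idx <- match(taxon_id, tax$lineage$taxon_id)
  vapply(seq_along(taxon_id), function(i) {
    if (is.na(idx[i])) return(NA_character_)
    ids <- unlist(tax$lineage[idx[i], tax_ranks()])
    ids <- ids[!is.na(ids)]
    if (!length(ids)) return(name_of[[taxon_id[i]]])
    paste(name_of[ids], collapse = sep)
  }, character(1))
}

#' Rank of each taxon
#' @param tax A [taxonomy()] object.
#' @param taxon_id Character vector of taxon ids.
#' @return Character vector of ranks (`"norank"` for unranked nodes).
#' @export
taxon_rank <- function(tax, taxon_id) {
  stats::setNames(tax$nodes$rank, tax$nodes$taxon_id)[taxon_id]
}
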