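#' Build a siderophore pathway-gene-COG network
#'
#' A bipartite multi-map: each pathway lists its genes, each gene one or more
#' COG signatures (for instance a dhbE-like gene carried by both an
#' AMP-dependent-ligase COG and a dedicated ligase COG). From the edge table
#' the network derives the COGs occurring in exactly one pathway, and
#' subtracts the curation-flagged ambiguous COGs (shared with
#' non-siderophore functions) to get `unique_cogs`, the signatures able to
#' upgrade a pathway call from MAYBE to PRESENT.
#'
#' @param edges Data frame with columns `pathway_id`, `gene_id`, `cog_id`,
#'   optional logical `ambiguous`.
#' @return A `pathway_network` object: list with `edges`, `pathways`
#'   (pathway to gene sets), `gene_cogs` (per pathway-gene COG sets),
#'   `ambiguous_cogs`, `unique_cogs`.
#' @export
pathway_network <- function(edges) {
  edges <- tibble::as_tibble(edges)
  required <- c("pathway_id", "gene_id", "cog_id")
  if (!all(required %in% names(edges))) {
    stop("pathway edges need columns: ", paste(required, collapse = ", "))
  }
  if (nrow(edges) == 0) stop("pathway network has no pathways")
  if (!"ambiguous" %in% names(edges)) edges$ambiguous <- FALSE
  edges$ambiguous[is.na(edges$ambiguous)] <- FALSE
  for (col in required) {
    if (any(is.na(edges[[col]]) | edges[[col]] == "")) {
      stop("empty ", col, " in pathway table")
    }
  }
  key <- paste(edges$pathway_id, edges$gene_id, edges$cog_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (pathway, gene, cog) triple: ",
         gsub("\r", " / ", key[duplicated(key)][1]))
  }
  ambiguous_cogs <- unique(edges$cog_id[edges$ambiguous])
  # a COG flagged ambiguous anywhere is ambiguous everywhere
  edges$ambiguous <- edges$cog_id %in% ambiguous_cogs
  per_path <- split(edges$gene_id, edges$pathway_id)
  pathways <- lapply(per_path, unique)
  gene_cogs <- split(edges$cog_id, paste(edges$pathway_id, edges$gene_id, sep = "\r"))
  n_paths <- edges |>
    dplyr::distinct(.data$pathway_id, .data$cog_id) |>
    dplyr::count(.data$cog_id, name = "n_pathways")
  unique_cogs <- setdiff(n_paths$cog_id[n_paths$n_pathways == 1L], ambiguous_cogs)
  structure(
    list(edges = edges, pathways = pathways, gene_cogs = gene_cogs,
         ambiguous_cogs = ambiguous_cogs, unique_cogs = unique_cogs),
    class = "pathway_network"
  )
}

#' @export
print.pathway_network <- function(x, ...) {
  cat("<pathway_network> ", length(x$pathways), " pathways, ",
      length(unique(x$edges$gene_id)), " genes, ",
      length(unique(x$edges$cog_id)), " COGs (",
      length(x$unique_cogs), " unique, ",
      length(x$ambiguous_cogs), " ambiguous)\n", sep = "")
  invisible(x)
}

#' COGs detected in a sample
#'
#' The detection predicate feeding the pathway presence criteria: a COG is
#' detected when its aggregate coverage strictly exceeds the floor (default
#' 0, i.e. any evidence counts).
#'
#' @param profile An [abundance_profile()] or a tibble with `cog_id`,
#'   `coverage`.
#' @param min_coverage Detection floor (strict inequality).
#' @return Character vector of detected COG ids.
#' @export
detected_cogs <- function(profile, min_coverage = 0) {
  stopifnot(min_coverage >= 0)
  cov <- if (inherits(profile, "abundance_profile")) profile$cov_by_cog
         else tibble::as_tibble(profile)
  cov$cog_id[cov$coverage > min_coverage]
}

#' Presence call for one siderophore pathway
#'
#' The three-rule classifier. A gene is present when at least one of its COG
#' signatures is detected (ambiguous COGs do count here). Then:
#' ABSENT when at least one gene of the pathway is missing; PRESENT when all
#' genes are present and at least one detected COG is unique to this pathway
#' (and unambiguous); MAYBE when all genes are present but every signature is
#' shared, so presence cannot be asserted with certainty.
#'
#' @param pathway_id Pathway to classify.
#' @param network A [pathway_network()] object.
#' @param present_cogs Character vector of detected COG ids.
#' @return One-row tibble: `pathway_id`, `status` (`"PRESENT"`, `"MAYBE"`,
#'   `"ABSENT"`), list-columns `missing_genes` and `supporting_unique_cogs`.
#' @export
classify_pathway <- function(pathway_id, network, present_cogs) {
  stopifnot(inherits(network, "pathway_network"))
  if (!pathway_id %in% names(network$pathways)) {
    stop("unknown pathway: ", pathway_id)
  }
  genes <- network$pathways[[pathway_id]]
  gene_present <- vapply(genes, function(g) {
    cogs <- network$gene_cogs[[paste(pathway_id, g, sep = "\r")]]
    any(cogs %in% present_cogs)
  }, logical(1))
  missing <- genes[!gene_present]
  path_cogs <- unique(network$edges$cog_id[network$edges$pathway_id == pathway_id])
  supporting <- intersect(intersect(present_cogs, network$unique_cogs), path_cogs)
  status <- if (length(missing)) "ABSENT"
            else if (length(supporting)) "PRESENT"
            else "MAYBE"
  tibble::tibble(
    pathway_id = pathway_id,
    status = status,
    missing_genes = list(missing),
    supporting_unique_cogs = list(supporting)
  )
}

#' Pathway presence calls across samples
#'
#' Classifies every pathway in every sample and derives a study-level status
#' per pathway as the best status observed across samples
#' (PRESENT > MAYBE > ABSENT), covering both the per-sample and the pooled
#' reading of presence.
#'
#' @param network A [pathway_network()] object.
#' @param profiles Named list of [abundance_profile()] objects (or tibbles
#'   with `cog_id`, `coverage`), one per sample.
#' @param min_coverage Detection floor passed to [detected_cogs()].
#' @return List of class `pathway_calls`: `per_sample` (tibble `sample_id`,
#'   `pathway_id`, `status`, `missing_genes`, `supporting_unique_cogs`) and
#'   `study` (tibble `pathway_id`, `status`).
#' @export
call_all_pathways <- function(network, profiles, min_coverage = 0) {
  stopifnot(inherits(network, "pathway_network"))
  if (length(profiles) == 0) {
    return(structure(
      list(per_sample = tibble::tibble(sample_id = character(),
                                       pathway_id = character(),
                                       status = character()),
           study = tibble::tibble(pathway_id = character(),
                                  status = character())),
      class = "pathway_calls"
    ))
  }
  if (is.null(names(profiles))) names(profiles) <- as.character(seq_along(profiles))
  per_sample <- purrr::imap(profiles, function(p, sid) {
    present <- detected_cogs(p, min_coverage)
    purrr::map(names(network$pathways),
               classify_pathway, network = network, present_cogs = present) |>
      dplyr::bind_rows() |>
      dplyr::mutate(sample_id = sid, .before = 1)
  }) |>
    dplyr::bind_rows()
  rank <- c(ABSENT = 1L, MAYBE = 2L, PRESENT = 3L)
  study <- per_sample |>
    dplyr::group_by(.data$pathway_id) |>
    dplyr::summarise(status = names(rank)[max(rank[.data$status])],
                     .groups = "drop")
  structure(list(per_sample = per_sample, study = study),
            class = "pathway_calls")
}

#' @export
print.pathway_calls <- function(x, ...) {
  tab <- table(factor(x$study$status, c("PRESENT", "MAYBE", "ABSENT")))
  cat("<pathway_calls> ", length(unique(x$per_sample$sample_id)), " samples; ",
      "study-level: ", paste(names(tab), tab, sep = "=", collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Copy number of unambiguous siderophore-synthesis genes
#'
#' Quantifies the synthesis category while excluding every COG flagged
#' ambiguous (in the catalog or the network): reads on such COGs may belong
#' to unrelated metabolic routes, so they count for pathway presence but not
#' here. The returned copy number is therefore a deliberate underestimate of
#' total siderophore-synthesis capacity.
#'
#' @param profile An [abundance_profile()] object.
#' @param network A [pathway_network()] object (its `ambiguous_cogs` add to
#'   the catalog flags); may be `NULL`.
#' @param catalog Catalog tibble from [load_iron_catalog()].
#' @return Copy number (non-negative scalar).
#' @export
quantify_synthesis <- function(profile, network = NULL, catalog) {
  stopifnot(inherits(profile, "abundance_profile"))
  catalog <- validate_iron_catalog(catalog)
  synth <- catalog[catalog$category == "siderophore_synthesis", ]
  excluded <- synth$cog_id[synth$ambiguous_synthesis]
  if (!is.null(network)) {
    stopifnot(inherits(network, "pathway_network"))
    excluded <- union(excluded, network$ambiguous_cogs)
  }
  keep <- setdiff(synth$cog_id, excluded)
  cov <- profile$cov_by_cog
  copy_number(sum(cov$coverage[cov$cog_id %in% keep]), profile$marker_median)
}
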