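#' Select the valid hits for LCA classification
#'
#' Applies the three hit filters: e-value at most `evalue_cutoff`; bitscore at
#' least `bitscore_fraction` of the best hit's bitscore; and percent identity
#' within the identity window of the best hit (relative by default: at least
#' `identity_fraction` times the best hit's identity). The best hit is the
#' maximal-bitscore hit after e-value filtering, with ties broken by lower
#' e-value, then higher identity, then input order; it is always retained.
#' Works on a table holding one query or many (filters apply per query).
#'
#' @param hits Hit tibble as returned by [read_alignment_table()].
#' @param params An [lca_params()] object.
#' @return Tibble of valid hits, input order preserved within each query,
#'   with helper columns `best_bitscore` and `best_identity` (the best hit's
#'   values for that query).
#' @export
select_valid_hits <- function(hits, params = lca_params()) {
  stopifnot(inherits(params, "lca_params"))
  hits <- tibble::as_tibble(hits)
  if (nrow(hits) == 0) {
    out <- hits
    out$best_bitscore <- numeric(0)
    out$best_identity <- numeric(0)
    return(out)
  }
  hits$.row <- seq_len(nrow(hits))
  kept <- dplyr::filter(hits, .data$evalue <= params$evalue_cutoff + 1e-300)
  if (nrow(kept) == 0) {
    out <- hits[0, ]
    out$.row <- NULL
    out$best_bitscore <- numeric(0)
    out$best_identity <- numeric(0)
    return(out)
  }
  best <- kept |>
    dplyr::arrange(.data$query_id, dplyr::desc(.data$bitscore), .data$evalue,
                   dplyr::desc(.data$percent_identity), .data$.row) |>
    dplyr::distinct(.data$query_id, .keep_all = TRUE) |>
    dplyr::select("query_id",
                  best_bitscore = "bitscore",
                  best_identity = "percent_identity")
  kept <- dplyr::left_join(kept, best, by = "query_id")
  ident_floor <- if (params$identity_mode == "relative") {
    params$identity_fraction * kept$best_identity
  } else {
    kept$best_identity - 100 * params$identity_fraction
  }
  valid <- kept[kept$bitscore >= params$bitscore_fraction * kept$best_bitscore - 1e-9 &
                  kept$percent_identity >= ident_floor - 1e-9, ]
  valid <- dplyr::arrange(valid, .data$.row)
  valid$.row <- NULL
  valid
}

#' Classify every ORF in a hit table by thresholded LCA
#'
#' For each query, valid hits are selected with [select_valid_hits()]; then,
#' walking ranks from species up to superkingdom, the classifier looks for a
#' taxon at each rank shared by at least `support_fraction` of the valid hits
#' (hits with no taxon label count in the denominator but support nothing).
#' The candidate assignment is the deepest supported rank; the reported rank
#' is then capped by the minimum-identity floors, moving up the lineage until
#' the best valid hit's identity meets the floor. Queries with no valid hits,
#' no supported taxon, or identity below the superkingdom floor come back
#' unclassified.
#'
#' @param hits Hit tibble (any number of queries) with `subject_taxon` labels.
#' @param tax A [taxonomy()] object covering every labeled subject taxon.
#' @param params An [lca_params()] object.
#' @return Tibble with one row per query: `orf_id`, `assigned_taxon` (`NA`
#'   when unclassified), `assigned_rank` (`NA` when unclassified),
#'   `best_identity`, `n_valid_hits`.
#' @export
classify_orfs <- function(hits, tax, params = lca_params()) {
  stopifnot(inherits(tax, "taxonomy"), inherits(params, "lca_params"))
  hits <- tibble::as_tibble(hits)
  all_queries <- unique(hits$query_id)
  unclassified <- tibble::tibble(
    orf_id = all_queries,
    assigned_taxon = NA_character_,
    assigned_rank = NA_character_,
    best_identity = NA_real_,
    n_valid_hits = 0L
  )
  if (nrow(hits) == 0) return(unclassified)

  labeled <- hits$subject_taxon[!is.na(hits$subject_taxon)]
  unknown <- setdiff(labeled, tax$lineage$taxon_id)
  if (length(unknown)) {
    stop("hit taxon not in taxonomy: ", paste(unknown, collapse = ", "))
  }

  valid <- select_valid_hits(hits, params)
  if (nrow(valid) == 0) return(unclassified)

  per_query <- valid |>
    dplyr::group_by(.data$query_id) |>
    dplyr::summarise(
      n_valid_hits = dplyr::n(),
      best_identity = if (params$floor_identity == "best") {
        .data$best_identity[1]
      } else {
        stats::median(.data$percent_identity)
      },
      .groups = "drop"
    )

  ranks <- tax_ranks()
  lin <- tax$lineage
  idx <- match(valid$subject_taxon, lin$taxon_id)
  anc <- lapply(ranks, function(r) lin[[r]][idx])
  names(anc) <- ranks
  long <- tibble::tibble(
    query_id = rep(valid$query_id, times = length(ranks)),
    rank = rep(ranks, each = nrow(valid)),
    taxon = unlist(anc, use.names = FALSE)
  )
  support <- long |>
    dplyr::filter(!is.na(.data$taxon)) |>
    dplyr::count(.data$query_id, .data$rank, .data$taxon, name = "n_agree") |>
    dplyr::left_join(per_query, by = "query_id") |>
    dplyr::filter(frac_ge(.data$n_agree, .data$n_valid_hits,
                          params$support_fraction))
  # deepest supported rank per query; within a rank keep the best-supported
  # taxon (unique whenever support_fraction > 0.5)
  depth <- stats::setNames(seq_along(ranks), ranks)
  candidate <- support |>
    dplyr::mutate(depth = depth[.data$rank]) |>
    dplyr::arrange(.data$query_id, dplyr::desc(.data$depth),
                   dplyr::desc(.data$n_agree), .data$taxon) |>
    dplyr::distinct(.data$query_id, .keep_all = TRUE)

  res <- per_query |>
    dplyr::left_join(dplyr::select(candidate, "query_id", "taxon", "depth"),
                     by = "query_id")
  floors <- params$rank_floors[ranks]
  # deepest rank whose identity floor the query meets (floors non-increasing
  # toward superkingdom, so the qualifying ranks form a shallow prefix)
  qual <- vapply(res$best_identity, function(id) {
    ok <- which(id >= floors - 1e-9)
    if (length(ok)) max(ok) else 0L
  }, integer(1))
  final_depth <- pmin(res$depth, qual)
  final_depth[is.na(res$depth)] <- NA_integer_
  final_depth[!is.na(final_depth) & final_depth == 0L] <- NA_integer_

  cand_idx <- match(res$taxon, lin$taxon_id)
  assigned <- rep(NA_character_, nrow(res))
  assigned_rank <- rep(NA_character_, nrow(res))
  for (i in which(!is.na(final_depth))) {
    # if the candidate's lineage skips the capped rank, keep walking up
    for (d in seq(final_depth[i], 1L)) {
      a <- lin[[ranks[d]]][cand_idx[i]]
      if (!is.na(a)) {
        assigned[i] <- a
        assigned_rank[i] <- ranks[d]
        break
      }
    }
  }
  out <- tibble::tibble(
    orf_id = res$query_id,
    assigned_taxon = assigned,
    assigned_rank = assigned_rank,
    best_identity = res$best_identity,
    n_valid_hits = as.integer(res$n_valid_hits)
  )
  # queries whose hits were all filtered out still get a row
  missing <- setdiff(all_queries, out$orf_id)
  if (length(missing)) {
    out <- dplyr::bind_rows(out, unclassified[unclassified$orf_id %in% missing, ])
  }
  out[match(all_queries, out$orf_id), ]
}

#' LCA assignment for a single ORF
#'
#' Convenience wrapper over [classify_orfs()] for a hit table holding one
#' query.
#'
#' @param valid_hits Hit tibble for one query (filtering is applied
#'   internally; pre-filtered input is fine since the filters are idempotent).
#' @param tax A [taxonomy()] object.
#' @param params An [lca_params()] object.
#' @return One-row tibble as in [classify_orfs()].
#' @export
assign_orf_lca <- function(valid_hits, tax, params = lca_params()) {
  valid_hits <- tibble::as_tibble(valid_hits)
  if (nrow(valid_hits) > 0 && length(unique(valid_hits$query_id)) != 1L) {
    stop("assign_orf_lca expects hits for exactly one query")
  }
  classify_orfs(valid_hits, tax, params)
}
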