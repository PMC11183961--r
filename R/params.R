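#' Taxonomic rank ladder
#'
#' The seven ranked levels used throughout the package, ordered from the
#' shallowest (superkingdom) to the deepest (species). Nodes at other levels
#' are carried as `"norank"` and never receive direct assignments.
#'
#' @return Character vector of rank names, shallow to deep.
#' @export
tax_ranks <- function() {
  c("superkingdom", "phylum", "class", "order", "family", "genus", "species")
}

#' The closed vocabulary of iron-function categories
#'
#' Functional categories for iron transport and siderophore synthesis genes:
#' ferrous iron ABC transporters (`Fe(II)`), TonB-dependent outer-membrane
#' ferric-siderophore transporters (`Fe(III)-OM`), cell-membrane ferric
#' siderophore ABC transporters (`Fe(III)-CM`), divalent cation ABC
#' transporters, dicitrate-bound iron transport, heme transport, ferritin-like
#' storage, regulators of iron metabolism, and siderophore synthesis.
#'
#' @return Character vector of category names.
#' @export
iron_categories <- function() {
  c("Fe(II)", "Fe(III)-OM", "Fe(III)-CM", "divalent_cation", "dicitrate",
    "heme", "storage", "regulators", "siderophore_synthesis")
}

#' Parameters for thresholded LCA classification of ORFs
#'
#' Controls hit filtering and the support/identity rules of the LCA
#' classifier. Defaults follow the published protocol: hits with e-value
#' above 1e-3 are discarded; "valid hits" must reach at least 80% of the best
#' hit's bitscore and at least 10% of the best hit's percent identity; a taxon
#' is reported when at least 90% of the valid hits support it; and the
#' assignment rank is capped by minimum-identity floors of 85/60/55/50/46/42/40
#' percent for species through superkingdom.
#'
#' @param evalue_cutoff Maximum e-value for a hit to be considered at all.
#' @param bitscore_fraction Valid hits need `bitscore >= bitscore_fraction *
#'   best bitscore`. In `(0, 1]`.
#' @param identity_fraction Identity window relative to the best hit. With
#'   `identity_mode = "relative"` (the literal reading of the protocol) valid
#'   hits need `pident >= identity_fraction * best pident`; with
#'   `identity_mode = "absolute"` they need
#'   `pident >= best pident - 100 * identity_fraction` percentage points.
#' @param support_fraction Fraction of valid hits that must agree on a taxon
#'   for it to be reported. In `(0, 1]`.
#' @param rank_floors Named numeric vector of minimum percent identities per
#'   rank, non-increasing from species to superkingdom.
#' @param identity_mode `"relative"` (default) or `"absolute"`; see
#'   `identity_fraction`.
#' @param floor_identity `"best"` (default) compares the best valid hit's
#'   identity against the rank floors; `"median"` uses the median identity of
#'   the valid hits.
#'
#' @return An object of class `lca_params`.
#' @export
lca_params <- function(evalue_cutoff = 1e-3,
                       bitscore_fraction = 0.80,
                       identity_fraction = 0.10,
                       support_fraction = 0.90,
                       rank_floors = c(species = 85, genus = 60, family = 55,
                                       order = 50, class = 46, phylum = 42,
                                       superkingdom = 40),
                       identity_mode = c("relative", "absolute"),
                       floor_identity = c("best", "median")) {
  identity_mode <- match.arg(identity_mode)
  floor_identity <- match.arg(floor_identity)
  stopifnot(
    is.numeric(evalue_cutoff), evalue_cutoff >= 0,
    bitscore_fraction > 0, bitscore_fraction <= 1,
    identity_fraction > 0, identity_fraction <= 1,
    support_fraction > 0, support_fraction <= 1
  )
  if (!all(tax_ranks() %in% names(rank_floors))) {
    stop("rank_floors must name all ranks: ", paste(tax_ranks(), collapse = ", "))
  }
  floors <- rank_floors[tax_ranks()]
  if (any(diff(floors) < 0)) {
    stop("rank_floors must be non-increasing from species to superkingdom")
  }
  structure(
    list(evalue_cutoff = evalue_cutoff,
         bitscore_fraction = bitscore_fraction,
         identity_fraction = identity_fraction,
         support_fraction = support_fraction,
         rank_floors = floors,
         identity_mode = identity_mode,
         floor_identity = floor_identity),
    class = "lca_params"
  )
}

#' Parameters for consensus contig taxonomy
#'
#' A contig is assigned to the deepest taxon claimed by at least
#' `min_fraction_all` of all its ORFs (annotated or not) and at least
#' `min_fraction_annotated` of the ORFs annotated at that rank, walking the
#' rank ladder top-down with parent consistency. Defaults are the published
#' 50% / 70% rule.
#'
#' @param min_fraction_all Fraction of all ORFs on the contig, in `(0, 1]`.
#' @param min_fraction_annotated Fraction of rank-annotated ORFs, in `(0, 1]`.
#' @return An object of class `consensus_params`.
#' @export
consensus_params <- function(min_fraction_all = 0.50,
                             min_fraction_annotated = 0.70) {
  stopifnot(
    min_fraction_all > 0, min_fraction_all <= 1,
    min_fraction_annotated > 0, min_fraction_annotated <= 1
  )
  structure(
    list(min_fraction_all = min_fraction_all,
         min_fraction_annotated = min_fraction_annotated),
    class = "consensus_params"
  )
}

# threshold comparison with a tiny epsilon so that exact rational boundaries
# (9/10 >= 0.9) pass regardless of binary representation
frac_ge <- function(count, total, frac) {
  count >= frac * total - 1e-9
}
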