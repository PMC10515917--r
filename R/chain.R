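#' The catarrhine-to-human lineage chain
#'
#' The pipeline assigns every single-event change (substitution or motif
#' gain/loss) to one of five named lineages. A lineage is the branch between
#' two consecutive nodes on the ordered root-to-tip path
#' Catarrhine ancestor -> Ape ancestor -> Great Ape ancestor ->
#' African Great Ape ancestor -> Hominin ancestor -> Human tip.
#' The catarrhine ancestor is required as the outgroup-polarised reference
#' state so that changes on the Ape stem branch itself are assignable; Old and
#' New World monkeys serve only to reconstruct it.
#'
#' @return A tibble with one row per chain node, deepest first, with columns
#'   `node` (node identifier) and `lineage` (the lineage label of the branch
#'   leading *into* the node from its parent chain node; `NA` for the deepest
#'   node).
#' @examples
#' lineage_chain()
#' @export
lineage_chain <- function() {
  tibble::tibble(
    node = c("Catarrhine", "Ape", "GreatApe", "AfricanGreatApe",
             "Hominin", "Human"),
    lineage = c(NA_character_, "Ape", "GreatApe", "AfricanGreatApe",
                "Hominin", "Human")
  )
}

#' Names of the five lineages, deepest first
#' @return Character vector `c("Ape", "GreatApe", "AfricanGreatApe",
#'   "Hominin", "Human")`.
#' @export
lineage_names <- function() lineage_chain()$lineage[-1]

#' Default lineage branch lengths in million years
#'
#' Lower-bound divergence-time estimates used to normalise substitution counts
#' per unit of evolutionary time: Human 6, Hominin 2, African Great Ape 8,
#' Great Ape 4, Ape 13 MY.
#'
#' @return Named numeric vector over the five lineages.
#' @export
default_branch_my <- function() {
  c(Human = 6, Hominin = 2, AfricanGreatApe = 8, GreatApe = 4, Ape = 13)
}

# Chain node ids ordered deepest -> shallowest.
chain_nodes <- function() lineage_chain()$node
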