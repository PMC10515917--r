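# Guide-tree construction for the synthetic catarrhine study.

# Node ages (million years) implied by the five lineage branch times, walking
# up the chain from the human tip.
chain_node_ages <- function(branch_my) {
  cumsum(branch_my[c("Human", "Hominin", "AfricanGreatApe", "GreatApe", "Ape")])
}

# Sequentially ladderised newick subtree over `tips` with crown age
# `crown_age`; internal nodes labelled `<prefix>_j`. Returns the subtree
# string WITHOUT a trailing branch length.
ladder_newick <- function(tips, crown_age, prefix) {
  k <- length(tips)
  if (k == 1L) return(sprintf("%s:%s", tips, format(crown_age)))
  ages <- crown_age * seq_len(k - 1L) / (k - 1L)
  cur <- sprintf("%s:%s", tips[1], format(ages[1]))
  cur_age <- ages[1]
  for (j in 2:k) {
    age <- ages[j - 1L]
    cur <- sprintf("(%s,%s:%s)%s_%d", cur, tips[j], format(age), prefix, j - 1L)
    if (j < k) {
      cur <- sprintf("%s:%s", cur, format(ages[j] - age))
      cur_age <- ages[j]
    }
  }
  cur
}

#' Build the catarrhine guide tree for simulation and reconstruction
#'
#' Constructs the rooted binary phylogeny the generator evolves sequences on
#' and the reconstruction consumes: the five ape tips ladderised as
#' (((human, chimp) gorilla) orangutan) gibbon, Old World monkeys as the
#' sister clade of the apes, New World monkeys as the outgroup. Internal nodes
#' on the ape path are labelled with the chain node ids (`Hominin`,
#' `AfricanGreatApe`, `GreatApe`, `Ape`, `Catarrhine`) so that the branch into
#' each labelled node is exactly the correspondingly named lineage. Branch
#' lengths are the configured million-year times scaled by
#' `background_sub_rate` into expected substitutions per site.
#'
#' @param config A [sim_config()].
#' @return An `ape::phylo` with `node.label` set; attribute `"my_scale"`
#'   holds the substitutions/site per MY scaling used.
#' @examples
#' tr <- build_guide_tree(sim_config())
#' tr$node.label
#' @export
build_guide_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  bl <- config$branch_lengths_my
  ages <- chain_node_ages(bl)  # Hominin, AGA, GA, Ape, Catarrhine node ages
  ape_tips <- config$taxa$ape
  a <- function(x) format(x)

  ape_clade <- sprintf(
    "((((%s:%s,%s:%s)Hominin:%s,%s:%s)AfricanGreatApe:%s,%s:%s)GreatApe:%s,%s:%s)Ape:%s",
    ape_tips[1], a(ages[1]), ape_tips[2], a(ages[1]), a(bl[["Hominin"]]),
    ape_tips[3], a(ages[2]), a(bl[["AfricanGreatApe"]]),
    ape_tips[4], a(ages[3]), a(bl[["GreatApe"]]),
    ape_tips[5], a(ages[4]), a(bl[["Ape"]])
  )

  catarrhine_age <- ages[5]
  owm_crown <- min(15, 0.75 * catarrhine_age)
  owm <- ladder_newick(config$taxa$owm, owm_crown, "OWM")
  owm <- sprintf("%s:%s", owm, a(catarrhine_age - owm_crown))
  root_age <- catarrhine_age + 10
  nwm_crown <- min(20, 0.75 * root_age)
  nwm <- ladder_newick(config$taxa$nwm, nwm_crown, "NWM")
  nwm <- sprintf("%s:%s", nwm, a(root_age - nwm_crown))

  nwk <- sprintf("((%s,%s)Catarrhine:%s,%s)Root;",
                 ape_clade, owm, a(root_age - catarrhine_age), nwm)
  tr <- ape::read.tree(text = nwk)
  tr$edge.length <- tr$edge.length * config$background_sub_rate
  attr(tr, "my_scale") <- config$background_sub_rate
  tr
}

# --- small phylo helpers used by simulator and reconstruction ---------------

# label of every node (tips then internals), length Ntip + Nnode
node_labels <- function(tree) {
  c(tree$tip.label,
    tree$node.label %||% rep(NA_character_, tree$Nnode))
}

# node index of a labelled node (tip or internal)
node_id <- function(tree, label) {
  idx <- match(label, node_labels(tree))
  if (is.na(idx)) abort(sprintf("node '%s' not found in tree", label))
  idx
}

# indices of the six chain nodes, deepest first; `human` is the tip name
chain_node_ids <- function(tree, human = "human") {
  labs <- c("Catarrhine", "Ape", "GreatApe", "AfricanGreatApe", "Hominin",
            human)
  vapply(labs, function(l) node_id(tree, l), integer(1))
}

# all node indices in the clade below `node` (including `node`);
# tree edges as given
clade_nodes <- function(tree, node) {
  edge <- tree$edge
  out <- node
  frontier <- node
  repeat {
    kids <- edge[edge[, 1] %in% frontier, 2]
    if (!length(kids)) break
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

# the child node of the branch named by a lineage: the chain node the
# lineage leads into (Human lineage -> human tip, Ape lineage -> Ape node)
lineage_child_node <- function(tree, lineage, human = "human") {
  lab <- if (lineage == "Human") human else lineage
  node_id(tree, lab)
}
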