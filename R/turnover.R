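# Wagner (linear-cost) parsimony reconstruction of ancestral gene-family
# counts on a rooted binary tree, per-branch gain/loss event counts, and
# per-branch turnover rates.

.check_rooted_binary <- function(tree) {
  if (!inherits(tree, "phylo")) abort("tree must be a phylo object")
  if (!ape::is.rooted(tree)) abort("root required: supply a rooted tree")
  tab <- table(tree$edge[, 1])
  if (any(tab != 2)) abort("tree must be binary (every internal node with 2 children)")
}

#' Wagner-parsimony ancestral gene-family counts
#'
#' Farris's interval algorithm for integer character states under linear
#' cost: a bottom-up pass computes per-node optimal count intervals (the
#' intersection of the two child intervals when non-empty, else the gap
#' between them), then a top-down pass assigns each node the value in its
#' interval closest to its parent's value. The root takes its interval's
#' minimum — gains are counted from the minimum number of family members at
#' ancestral nodes. The total absolute change over branches is minimal.
#'
#' @param tree Rooted binary `phylo` whose tips are genomes.
#' @param leaf_counts Families x genomes matrix of non-negative integer
#'   counts (e.g. a pan-matrix); columns must cover all tip labels.
#' @return An integer matrix families x nodes, with columns ordered tips
#'   first then internal nodes (root first among internal), named with tip
#'   and node labels.
#' @export
wagner_ancestral_counts <- function(tree, leaf_counts) {
  .check_rooted_binary(tree)
  if (is.vector(leaf_counts)) leaf_counts <- matrix(leaf_counts, nrow = 1,
    dimnames = list("f1", names(leaf_counts)))
  if (any(leaf_counts < 0)) abort("negative count")
  if (!all(tree$tip.label %in% colnames(leaf_counts))) {
    abort("leaf_counts must have a column for every tip label")
  }
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  nfam <- nrow(leaf_counts)
  lo <- hi <- matrix(NA_real_, nfam, ntip + nnode)
  lo[, 1:ntip] <- hi[, 1:ntip] <- leaf_counts[, tree$tip.label, drop = FALSE]

  post <- ape::reorder.phylo(tree, "postorder")$edge
  internal <- unique(post[, 1])  # parents in postorder: children done first
  children_of <- split(tree$edge[, 2], tree$edge[, 1])
  for (nd in internal) {
    ch <- children_of[[as.character(nd)]]
    l1 <- lo[, ch[1]]; h1 <- hi[, ch[1]]
    l2 <- lo[, ch[2]]; h2 <- hi[, ch[2]]
    # Farris: intersection when it exists, else the gap between intervals
    lo[, nd] <- pmin(pmax(l1, l2), pmin(h1, h2))
    hi[, nd] <- pmax(pmin(h1, h2), pmax(l1, l2))
  }

  val <- matrix(NA_real_, nfam, ntip + nnode)
  val[, 1:ntip] <- lo[, 1:ntip]
  root <- ntip + 1L
  val[, root] <- lo[, root]  # root tie-break: interval minimum
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  for (i in seq_len(nrow(pre))) {
    parent <- pre[i, 1]; child <- pre[i, 2]
    if (child <= ntip) next
    val[, child] <- pmin(pmax(val[, parent], lo[, child]), hi[, child])
  }
  if (is.null(tree$node.label)) tree$node.label <- sprintf("n%02d", seq_len(nnode))
  colnames(val) <- c(tree$tip.label, tree$node.label)
  rownames(val) <- rownames(leaf_counts)
  storage.mode(val) <- "integer"
  val
}

#' Per-branch gain and loss counts
#'
#' Given a full node-by-family count assignment, sums over families, per
#' branch, the positive differences (gains) and negative differences
#' (losses) from parent to child.
#'
#' @param tree Rooted binary `phylo`.
#' @param node_counts Families x nodes matrix from
#'   [wagner_ancestral_counts()].
#' @return A tibble: `parent_label`, `child_label`, `branch_length`, `gains`,
#'   `losses`.
#' @export
branch_gain_loss <- function(tree, node_counts) {
  .check_rooted_binary(tree)
  ntip <- length(tree$tip.label)
  labels <- c(tree$tip.label,
              if (is.null(tree$node.label)) sprintf("n%02d", seq_len(tree$Nnode))
              else tree$node.label)
  purrr::map_dfr(seq_len(nrow(tree$edge)), function(i) {
    parent <- tree$edge[i, 1]; child <- tree$edge[i, 2]
    diff <- node_counts[, labels[child]] - node_counts[, labels[parent]]
    tibble(parent_label = labels[parent], child_label = labels[child],
           branch_length = if (is.null(tree$edge.length)) NA_real_
                           else tree$edge.length[i],
           gains = sum(pmax(diff, 0)), losses = sum(pmax(-diff, 0)))
  })
}

#' Per-branch turnover rates
#'
#' Divides per-branch gains and losses by branch length, the free-rates view
#' in which every branch has its own turnover rate. Zero-length branches get
#' the undefined sentinel `NA` (with a warning when they carry events).
#'
#' @param branch_events Tibble from [branch_gain_loss()].
#' @param tree Optional; unused if `branch_events` already carries
#'   `branch_length`.
#' @return The input with `gain_rate` and `loss_rate` columns.
#' @export
branch_turnover_rates <- function(branch_events, tree = NULL) {
  len <- branch_events$branch_length
  zero <- !is.na(len) & len == 0
  if (any(zero & (branch_events$gains > 0 | branch_events$losses > 0))) {
    warn("zero-length branch carries events; its rates are undefined (NA)")
  }
  branch_events %>%
    mutate(gain_rate = ifelse(zero | is.na(len), NA_real_, .data$gains / len),
           loss_rate = ifelse(zero | is.na(len), NA_real_, .data$losses / len))
}

#' Full gene-turnover analysis
#'
#' Runs [wagner_ancestral_counts()], [branch_gain_loss()] and
#' [branch_turnover_rates()] on a pan-matrix and rooted reference tree.
#'
#' @param tree Rooted binary `phylo` (the reference phylogenomic tree).
#' @param pan_matrix Families x genomes count matrix.
#' @return A list of class `turnover_result`: `node_counts` (tibble:
#'   `node_label`, `total_genes` — summed over families), `family_counts`
#'   (full families x nodes matrix), `branches` (per-branch events + rates),
#'   `total_changes`.
#' @export
gene_turnover <- function(tree, pan_matrix) {
  counts <- wagner_ancestral_counts(tree, pan_matrix)
  branches <- branch_turnover_rates(branch_gain_loss(tree, counts))
  structure(list(
    node_counts = tibble(node_label = colnames(counts),
                         total_genes = colSums(counts)),
    family_counts = counts,
    branches = branches,
    total_changes = sum(branches$gains) + sum(branches$losses)),
    class = "turnover_result")
}

#' @export
print.turnover_result <- function(x, ...) {
  cat(sprintf("Gene turnover: %d total changes (%d gains, %d losses) over %d branches\n",
              x$total_changes, sum(x$branches$gains), sum(x$branches$losses),
              nrow(x$branches)))
  invisible(x)
}

#' @method tidy turnover_result
#' @export
tidy.turnover_result <- function(x, ...) x$branches

#' @method glance turnover_result
#' @export
glance.turnover_result <- function(x, ...) {
  # the root is the first internal node: tips come first in node_counts
  n_nodes <- nrow(x$node_counts)
  n_tips <- (n_nodes + 1) %/% 2
  tibble(total_changes = x$total_changes,
         total_gains = sum(x$branches$gains),
         total_losses = sum(x$branches$losses),
         root_genes = unname(x$node_counts$total_genes[n_tips + 1]))
}
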