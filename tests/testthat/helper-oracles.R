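# Independent oracles and small utilities shared across the suite.
# Everything here is deliberately brute-force / closed-form and independent
# of the package's own code paths.

# Adjusted Rand index between two labellings of the same items.
adj_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_a <- b * cc / n2
  (a - exp_a) / (0.5 * (b + cc) - exp_a)
}

# Brute-force minimum total linear-cost change for integer counts on a
# rooted tree: exhaustively enumerates all ancestral assignments
# (vectorized over the assignment grid).
wagner_brute_min <- function(tree, leaf_counts) {
  ntip <- length(tree$tip.label)
  vals <- 0:max(leaf_counts)
  A <- as.matrix(expand.grid(rep(list(vals), tree$Nnode)))
  node_vals <- function(node) {
    if (node <= ntip) rep(leaf_counts[[tree$tip.label[node]]], nrow(A))
    else A[, node - ntip]
  }
  cost <- rep(0, nrow(A))
  for (e in seq_len(nrow(tree$edge))) {
    cost <- cost + abs(node_vals(tree$edge[e, 2]) - node_vals(tree$edge[e, 1]))
  }
  min(cost)
}

# K2P closed form (transitions P, transversions Q).
k2p_dist <- function(P, Q) {
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

# JC69 closed form for total difference proportion D.
jc69_dist <- function(D) -0.75 * log(1 - 4 / 3 * D)

# Numerical TN93 transition matrix via matrix exponential (Matrix::expm),
# same parameterization as the simulator but an independent code path.
tn93_expm <- function(t, base_freqs, kappa1, kappa2, beta = 1) {
  p <- unname(as.numeric(base_freqs))
  a1 <- kappa1 * beta; a2 <- kappa2 * beta
  Q <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    rate <- beta
    if ((i == 1 && j == 3) || (i == 3 && j == 1)) rate <- a1
    if ((i == 2 && j == 4) || (i == 4 && j == 2)) rate <- a2
    Q[i, j] <- rate * p[j]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(p * diag(Q))
  as.matrix(Matrix::expm(Q / mu * t))
}

# Random rooted binary tree with exponential branch lengths (independent of
# the package's simulator); returns phylo.
random_blen_tree <- function(n, rate = 1) {
  tr <- ape::rtree(n, rooted = TRUE)
  tr$edge.length <- stats::rexp(nrow(tr$edge), rate) + 0.05
  tr
}

# Random i.i.d. sequences
random_dna <- function(n, freqs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freqs),
        collapse = "")
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# Mutate a DNA string at exactly k positions (uniform different base).
mutate_dna <- function(seq, k) {
  v <- strsplit(seq, "")[[1]]
  idx <- sample(length(v), k)
  v[idx] <- vapply(v[idx], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  paste(v, collapse = "")
}

# Sequence tibble constructor for fixtures.
seq_tbl <- function(ids, seqs, alphabet = "nucleotide") {
  tibble::tibble(id = ids, desc = "", seq = seqs, alphabet = alphabet)
}
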