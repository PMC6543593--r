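# Synthetic clade generator: a known tree, a gene gain/loss history over it,
# a TN93-evolved marker alignment, and per-genome proteomes whose
# within-family identity decays with tree distance. Every downstream stage
# of the pipeline can be checked against the returned truth.

#' Simulation configuration
#'
#' Bundles all parameters of the synthetic clade generator. Defaults describe
#' a small acid-mine-drainage-style clade: ten genomes, an open pan-genome
#' (gains outpace losses), a 1,500 bp 16S-like marker evolved under a
#' transition-biased TN93 process with rRNA-like base frequencies, and
#' proteins long enough (120 aa) for percent identity to be stable.
#'
#' @param n_genomes Number of extant genomes (>= 3).
#' @param tree_mode `"random_yule"` (default) or `"fixed_newick"`.
#' @param fixed_tree A `phylo` or Newick string, used when
#'   `tree_mode = "fixed_newick"`.
#' @param tree_height Root-to-tip height the simulated tree is rescaled to.
#' @param root_family_count Gene families present in the clade ancestor.
#' @param gain_rate Expected new families gained per unit branch length
#'   (Poisson).
#' @param loss_rate Per-family loss rate per unit branch length; a family
#'   survives a branch of length `l` with probability `exp(-loss_rate * l)`.
#' @param marker_length Marker gene length in bp (default 1,500, a full-length
#'   16S rRNA gene).
#' @param marker_scale Expected substitutions/site per unit branch length for
#'   the marker (default 0.05, keeping 16S divergence realistic and
#'   unsaturated).
#' @param base_freqs Named or ordered numeric of stationary frequencies
#'   (A, C, G, T); must sum to 1. Default is rRNA-like.
#' @param kappa1,kappa2 TN93 transition rate factors for A<->G and C<->T
#'   relative to the transversion rate.
#' @param beta Transversion rate factor (usually 1; only ratios matter after
#'   normalization).
#' @param protein_identity_decay Per-site substitution rate of proteins per
#'   unit branch length (probability `1 - exp(-decay * l)` per branch).
#' @param protein_length Protein length in residues.
#' @param mge_fraction Fraction of genes labelled with mobile-genetic-element
#'   product strings (transposase/integrase/phage) for `flag_mge()` testing.
#' @param seed Integer seed; recorded in all outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genomes = 10,
                       tree_mode = c("random_yule", "fixed_newick"),
                       fixed_tree = NULL,
                       tree_height = 1,
                       root_family_count = 120,
                       gain_rate = 30,
                       loss_rate = 0.1,
                       marker_length = 1500,
                       marker_scale = 0.05,
                       base_freqs = c(A = 0.254, C = 0.229, G = 0.313, T = 0.204),
                       kappa1 = 2,
                       kappa2 = 4,
                       beta = 1,
                       protein_identity_decay = 0.15,
                       protein_length = 120,
                       mge_fraction = 0.05,
                       seed = 1L) {
  tree_mode <- match.arg(tree_mode)
  stopifnot(n_genomes >= 3, root_family_count >= 1,
            gain_rate >= 0, loss_rate >= 0,
            marker_length >= 100, marker_scale > 0,
            kappa1 >= 0, kappa2 >= 0, beta > 0,
            protein_identity_decay >= 0, protein_length >= 10,
            mge_fraction >= 0, mge_fraction <= 1)
  base_freqs <- unname(as.numeric(base_freqs))
  if (length(base_freqs) != 4 || abs(sum(base_freqs) - 1) > 1e-9 ||
      any(base_freqs <= 0)) {
    abort("base_freqs must be four positive values summing to 1 (within 1e-9)")
  }
  if (tree_mode == "fixed_newick" && is.null(fixed_tree)) {
    abort("fixed_newick mode requires `fixed_tree`")
  }
  structure(list(n_genomes = as.integer(n_genomes), tree_mode = tree_mode,
                 fixed_tree = fixed_tree, tree_height = tree_height,
                 root_family_count = as.integer(root_family_count),
                 gain_rate = gain_rate, loss_rate = loss_rate,
                 marker_length = as.integer(marker_length),
                 marker_scale = marker_scale,
                 base_freqs = stats::setNames(base_freqs, c("A", "C", "G", "T")),
                 kappa1 = kappa1, kappa2 = kappa2, beta = beta,
                 protein_identity_decay = protein_identity_decay,
                 protein_length = as.integer(protein_length),
                 mge_fraction = mge_fraction, seed = as.integer(seed)),
            class = "sim_config")
}

# Label helper: name of a node (tip label or internal node label).
.node_label <- function(tree, node) {
  ntip <- length(tree$tip.label)
  ifelse(node <= ntip, tree$tip.label[node], tree$node.label[node - ntip])
}

#' Simulate the clade tree
#'
#' A rooted binary tree with `n_genomes` leaves. In `random_yule` mode a
#' pure-birth tree is drawn and rescaled so the root-to-tip height equals
#' `tree_height`; in `fixed_newick` mode the supplied tree is returned
#' unchanged (apart from internal node labels, added if absent).
#'
#' @param config A [sim_config()].
#' @return A rooted [ape::phylo] with unique tip labels `g01, g02, ...` (Yule
#'   mode) and internal node labels.
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$tree_mode == "fixed_newick") {
    tr <- config$fixed_tree
    if (is.character(tr)) tr <- ape::read.tree(text = tr)
    stopifnot(inherits(tr, "phylo"))
  } else {
    set.seed(config$seed)
    tr <- ape::rphylo(config$n_genomes, birth = 1, death = 0)
    tr$tip.label <- sprintf("g%02d", seq_len(config$n_genomes))
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * config$tree_height / depth
  }
  if (is.null(tr$node.label) || any(!nzchar(tr$node.label))) {
    tr$node.label <- sprintf("n%02d", seq_len(tr$Nnode))
  }
  tr
}

#' Simulate gene-family gain and loss along a tree
#'
#' Each branch loses each currently present family independently with
#' probability `1 - exp(-loss_rate * l)` and gains `Poisson(gain_rate * l)`
#' brand-new families (infinite-alleles: a lost family is never re-gained,
#' keeping the parsimony ground truth well defined).
#'
#' @param tree Rooted binary `phylo` with node labels.
#' @param config A [sim_config()].
#' @return A list with `pan` (binary presence matrix, families x genomes,
#'   restricted to families seen in >= 1 extant genome) and `truth`, itself a
#'   list: `tree`, `events` (tibble: `child_label`, `gains`, `losses`),
#'   `membership` (tibble: `family_id`, `genome_id`, `gene_id`),
#'   `origin` (tibble: `family_id`, `origin_label` — node where the family
#'   first exists), and `seed`.
#' @export
simulate_gene_content <- function(tree, config) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nfam_total <- config$root_family_count
  fam_name <- function(i) sprintf("fam%05d", i)
  root_fams <- fam_name(seq_len(nfam_total))
  presence <- vector("list", ntip + tree$Nnode)
  presence[[root]] <- root_fams
  origin <- stats::setNames(rep(.node_label(tree, root), nfam_total), root_fams)

  edges <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
  # preorder: parents before children
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  ev_gain <- ev_loss <- numeric(nrow(pre))
  child_labels <- character(nrow(pre))
  for (i in seq_len(nrow(pre))) {
    parent <- pre[i, 1]; child <- pre[i, 2]
    len <- tree$edge.length[which(tree$edge[, 1] == parent &
                                  tree$edge[, 2] == child)]
    fams <- presence[[parent]]
    p_loss <- 1 - exp(-config$loss_rate * len)
    lost <- if (length(fams)) fams[stats::runif(length(fams)) < p_loss] else character()
    kept <- setdiff(fams, lost)
    n_gain <- stats::rpois(1, config$gain_rate * len)
    gained <- character()
    if (n_gain > 0) {
      gained <- fam_name(nfam_total + seq_len(n_gain))
      nfam_total <- nfam_total + n_gain
      origin[gained] <- .node_label(tree, child)
    }
    presence[[child]] <- c(kept, gained)
    ev_gain[i] <- n_gain
    ev_loss[i] <- length(lost)
    child_labels[i] <- .node_label(tree, child)
  }

  membership <- purrr::map_dfr(seq_len(ntip), function(tip) {
    fams <- presence[[tip]]
    g <- tree$tip.label[tip]
    tibble(family_id = fams, genome_id = g,
           gene_id = sprintf("%s_%s", g, fams))
  })
  fams_seen <- sort(unique(membership$family_id))
  pan <- matrix(0L, nrow = length(fams_seen), ncol = ntip,
                dimnames = list(fams_seen, tree$tip.label))
  pan[cbind(match(membership$family_id, fams_seen),
            match(membership$genome_id, tree$tip.label))] <- 1L

  list(pan = pan,
       truth = list(tree = tree,
                    events = tibble(child_label = child_labels,
                                    gains = as.integer(ev_gain),
                                    losses = as.integer(ev_loss)),
                    membership = membership,
                    origin = tibble(family_id = names(origin),
                                    origin_label = unname(origin)),
                    node_presence = presence,
                    seed = config$seed))
}

# TN93 machinery -------------------------------------------------------------

# Normalized TN93 rate matrix (rows = from, cols = to, order A,C,G,T),
# scaled so the expected substitution rate at stationarity is 1.
.tn93_rate_matrix <- function(base_freqs, kappa1, kappa2, beta = 1) {
  p <- base_freqs
  a1 <- kappa1 * beta; a2 <- kappa2 * beta
  Q <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    rate <- beta
    if ((i == 1 && j == 3) || (i == 3 && j == 1)) rate <- a1  # A<->G
    if ((i == 2 && j == 4) || (i == 4 && j == 2)) rate <- a2  # C<->T
    Q[i, j] <- rate * p[j]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(p * diag(Q))
  Q / mu
}

#' TN93 transition probabilities
#'
#' Closed-form transition probability matrix `P(t)` of the Tamura-Nei (1993)
#' substitution model, with the rate matrix normalized so `t` is measured in
#' expected substitutions per site.
#'
#' @param t Branch length (expected substitutions/site).
#' @param base_freqs Stationary frequencies (A, C, G, T).
#' @param kappa1,kappa2,beta Rate factors as in [sim_config()].
#' @return A 4x4 row-stochastic matrix over (A, C, G, T).
#' @export
tn93_transition_probs <- function(t, base_freqs, kappa1, kappa2, beta = 1) {
  p <- unname(as.numeric(base_freqs))
  pA <- p[1]; pC <- p[2]; pG <- p[3]; pT <- p[4]
  pR <- pA + pG; pY <- pC + pT
  a1 <- kappa1 * beta; a2 <- kappa2 * beta; b <- beta
  # normalization to 1 expected substitution per unit t
  mu <- 2 * (pA * pG * a1 + pC * pT * a2 + pR * pY * b)
  a1 <- a1 / mu; a2 <- a2 / mu; b <- b / mu
  e2 <- exp(-b * t)
  e3 <- exp(-(pR * a1 + pY * b) * t)
  e4 <- exp(-(pY * a2 + pR * b) * t)
  P <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  # purines
  P["A", "A"] <- pA + pA * pY / pR * e2 + pG / pR * e3
  P["A", "G"] <- pG + pG * pY / pR * e2 - pG / pR * e3
  P["G", "G"] <- pG + pG * pY / pR * e2 + pA / pR * e3
  P["G", "A"] <- pA + pA * pY / pR * e2 - pA / pR * e3
  # pyrimidines
  P["C", "C"] <- pC + pC * pR / pY * e2 + pT / pY * e4
  P["C", "T"] <- pT + pT * pR / pY * e2 - pT / pY * e4
  P["T", "T"] <- pT + pT * pR / pY * e2 + pC / pY * e4
  P["T", "C"] <- pC + pC * pR / pY * e2 - pC / pY * e4
  # transversions
  P["A", "C"] <- P["G", "C"] <- pC * (1 - e2)
  P["A", "T"] <- P["G", "T"] <- pT * (1 - e2)
  P["C", "A"] <- P["T", "A"] <- pA * (1 - e2)
  P["C", "G"] <- P["T", "G"] <- pG * (1 - e2)
  # guard against tiny negative round-off at t ~ 0
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate a marker-gene alignment under TN93
#'
#' Draws a root sequence from the stationary base frequencies and evolves it
#' along every branch under the TN93 transition probabilities, giving a
#' gapless alignment with one sequence per genome (one marker copy per
#' genome; no intragenomic heterogeneity).
#'
#' @param tree Rooted `phylo`.
#' @param config A [sim_config()]; branch lengths are multiplied by
#'   `marker_scale` to obtain substitutions/site.
#' @return A sequence tibble (see [read_fasta()]) of aligned nucleotide
#'   sequences, one per tip, in tip-label order.
#' @export
simulate_marker_alignment <- function(tree, config) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  L <- config$marker_length
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  states <- vector("list", ntip + tree$Nnode)
  states[[root]] <- sample.int(4, L, replace = TRUE, prob = config$base_freqs)
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (i in seq_len(nrow(pre))) {
    parent <- pre[i, 1]; child <- pre[i, 2]
    t <- lens[i] * config$marker_scale
    P <- tn93_transition_probs(t, config$base_freqs,
                               config$kappa1, config$kappa2, config$beta)
    s <- states[[parent]]
    out <- integer(L)
    for (st in 1:4) {
      idx <- which(s == st)
      if (length(idx)) out[idx] <- sample.int(4, length(idx), replace = TRUE,
                                              prob = P[st, ])
    }
    states[[child]] <- out
  }
  bases <- c("A", "C", "G", "T")
  tibble(id = tree$tip.label,
         desc = sprintf("simulated 16S-like marker (seed %d)", config$seed),
         seq = vapply(seq_len(ntip),
                      function(i) paste(bases[states[[i]]], collapse = ""),
                      character(1)),
         alphabet = "nucleotide")
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.mutate_protein <- function(aa_vec, p_sub) {
  hit <- which(stats::runif(length(aa_vec)) < p_sub)
  if (length(hit)) {
    # substitute to a uniformly chosen *different* residue
    cur <- aa_vec[hit]
    new <- .AA20[sample.int(20, length(hit), replace = TRUE)]
    same <- new == cur
    while (any(same)) {
      new[same] <- .AA20[sample.int(20, sum(same), replace = TRUE)]
      same <- new == cur
    }
    aa_vec[hit] <- new
  }
  aa_vec
}

.MGE_PRODUCTS <- c("IS3 family transposase", "phage integrase",
                   "prophage terminase large subunit",
                   "site-specific recombinase", "insertion sequence protein")
.HK_PRODUCTS <- c("carbonic anhydrase", "ribosomal protein L2",
                  "sulfur oxidation protein SoxB", "RuBisCO large subunit",
                  "ATP synthase subunit beta", "elongation factor Tu",
                  "hypothetical protein", "outer membrane porin",
                  "nitrogenase iron protein", "cytochrome c oxidase subunit I")

#' Simulate proteomes consistent with a gene-content history
#'
#' Every family receives a random ancestral protein at its origin node, which
#' is then evolved down the tree by i.i.d. site substitution (no indels), so
#' within-family percent identity decays analytically with tree distance. A
#' seeded fraction of genes receives mobile-genetic-element product strings.
#'
#' @param tree Rooted `phylo`.
#' @param content Result of [simulate_gene_content()].
#' @param config A [sim_config()].
#' @return A list: `proteomes` (named list of sequence tibbles, one per
#'   genome), `annotations` (tibble: `genome_id`, `gene_id`, `product`,
#'   `start`, `end`, `strand`), `mge_genes` (gene ids carrying MGE products).
#' @export
simulate_proteomes <- function(tree, content, config) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  node_presence <- content$truth$node_presence
  L <- config$protein_length
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  lens <- ape::reorder.phylo(tree, "cladewise")$edge.length

  # seqs[[node]]: named list family -> integer vector over 1..20
  seqs <- vector("list", ntip + tree$Nnode)
  new_ancestor <- function(fams) {
    stats::setNames(lapply(fams, function(f) {
      .AA20[sample.int(20, L, replace = TRUE)]
    }), fams)
  }
  seqs[[root]] <- new_ancestor(node_presence[[root]])
  for (i in seq_len(nrow(pre))) {
    parent <- pre[i, 1]; child <- pre[i, 2]
    p_sub <- 1 - exp(-config$protein_identity_decay * lens[i])
    fams_child <- node_presence[[child]]
    inherited <- intersect(fams_child, names(seqs[[parent]]))
    evolved <- stats::setNames(lapply(seqs[[parent]][inherited],
                                      .mutate_protein, p_sub = p_sub),
                               inherited)
    gained <- setdiff(fams_child, inherited)
    seqs[[child]] <- c(evolved, new_ancestor(gained))
  }

  proteomes <- stats::setNames(lapply(seq_len(ntip), function(tip) {
    g <- tree$tip.label[tip]
    fams <- names(seqs[[tip]])
    tibble(id = sprintf("%s_%s", g, fams),
           desc = "",
           seq = vapply(seqs[[tip]], paste, character(1), collapse = ""),
           alphabet = "protein")
  }), tree$tip.label)

  ann <- purrr::map_dfr(tree$tip.label, function(g) {
    pr <- proteomes[[g]]
    n <- nrow(pr)
    starts <- cumsum(c(1, rep(3 * L + 200, max(0, n - 1))))
    tibble(genome_id = g, gene_id = pr$id,
           product = sample(.HK_PRODUCTS, n, replace = TRUE),
           start = starts, end = starts + 3 * L - 1,
           strand = sample(c("+", "-"), n, replace = TRUE))
  })
  n_mge <- round(config$mge_fraction * nrow(ann))
  mge_idx <- if (n_mge > 0) sample.int(nrow(ann), n_mge) else integer()
  ann$product[mge_idx] <- sample(.MGE_PRODUCTS, n_mge, replace = TRUE)
  list(proteomes = proteomes, annotations = ann,
       mge_genes = ann$gene_id[mge_idx])
}

#' Simulate a full synthetic clade
#'
#' Convenience wrapper running [simulate_tree()], [simulate_gene_content()],
#' [simulate_marker_alignment()] and [simulate_proteomes()] under one config.
#'
#' @param config A [sim_config()].
#' @return A list: `tree`, `pan`, `truth`, `marker`, `proteomes`,
#'   `annotations`, `mge_genes`, `config`.
#' @export
simulate_clade <- function(config = sim_config()) {
  tree <- simulate_tree(config)
  content <- simulate_gene_content(tree, config)
  marker <- simulate_marker_alignment(tree, config)
  prot <- simulate_proteomes(tree, content, config)
  list(tree = tree, pan = content$pan, truth = content$truth,
       marker = marker, proteomes = prot$proteomes,
       annotations = prot$annotations, mge_genes = prot$mge_genes,
       config = config)
}
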