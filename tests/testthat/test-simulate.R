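test_that("tree simulation is deterministic, sized correctly and respects fixed trees", {
  cfg <- sim_config(n_genomes = 28, seed = 4)
  t1 <- simulate_tree(cfg)
  t2 <- simulate_tree(cfg)
  expect_identical(t1, t2)
  expect_length(t1$tip.label, 28)
  expect_equal(t1$Nnode, 27)
  expect_true(ape::is.rooted(t1))
  expect_equal(max(ape::node.depth.edgelength(t1)), 1, tolerance = 1e-12)

  fixed <- ape::read.tree(text = "((a:1,b:1):0.5,(c:0.7,d:0.8):0.7);")
  cfgf <- sim_config(n_genomes = 4, tree_mode = "fixed_newick",
                     fixed_tree = fixed, seed = 1)
  tf <- simulate_tree(cfgf)
  expect_equal(tf$edge, fixed$edge)
  expect_equal(tf$edge.length, fixed$edge.length)
})

test_that("identical config and seed give byte-identical clades", {
  cfg <- sim_config(n_genomes = 5, seed = 99)
  a <- simulate_clade(cfg)
  b <- simulate_clade(cfg)
  expect_identical(a$pan, b$pan)
  expect_identical(a$marker, b$marker)
  expect_identical(a$proteomes, b$proteomes)
  expect_identical(a$annotations, b$annotations)
})

test_that("gene content respects the zero-rate and zero-loss regimes", {
  cfg0 <- sim_config(n_genomes = 5, gain_rate = 0, loss_rate = 0,
                     root_family_count = 40, seed = 2)
  tr <- simulate_tree(cfg0)
  gc0 <- simulate_gene_content(tr, cfg0)
  expect_equal(dim(gc0$pan), c(40, 5))
  expect_true(all(gc0$pan == 1))  # all-core

  # loss_rate = 0: each family occupies exactly the clade below its origin
  cfg1 <- sim_config(n_genomes = 6, gain_rate = 20, loss_rate = 0, seed = 3)
  tr1 <- simulate_tree(cfg1)
  gc1 <- simulate_gene_content(tr1, cfg1)
  labels <- c(tr1$tip.label, tr1$node.label)
  for (f in sample(rownames(gc1$pan), 25)) {
    org <- gc1$truth$origin$origin_label[gc1$truth$origin$family_id == f]
    node <- which(labels == org)
    below <- if (node <= length(tr1$tip.label)) tr1$tip.label[node]
             else ape::extract.clade(tr1, node)$tip.label
    expect_setequal(colnames(gc1$pan)[gc1$pan[f, ] == 1], below)
  }
  # and the core equals exactly the root families
  part <- partition_pangenome(gc1$pan)
  expect_length(part$core, cfg1$root_family_count)
})

test_that("per-branch event counts match their Poisson/Binomial means", {
  cfg <- sim_config(n_genomes = 4, gain_rate = 8, loss_rate = 0.3,
                    root_family_count = 60, tree_mode = "fixed_newick",
                    fixed_tree = ape::read.tree(
                      text = "((a:0.4,b:0.4):0.6,(c:0.5,d:0.5):0.5);"),
                    seed = 1)
  tr <- simulate_tree(cfg)
  nrep <- 200
  gains1 <- losses1 <- numeric(nrep)
  for (r in seq_len(nrep)) {
    cfg_r <- cfg; cfg_r$seed <- 1000L + r
    gc <- simulate_gene_content(tr, cfg_r)
    # first preorder branch leaves the root, so its parent pool is known
    gains1[r] <- gc$truth$events$gains[1]
    losses1[r] <- gc$truth$events$losses[1]
  }
  pre <- ape::reorder.phylo(tr, "cladewise")
  len1 <- pre$edge.length[1]
  lam <- cfg$gain_rate * len1
  expect_lt(abs(mean(gains1) - lam), 3 * sqrt(lam / nrep))
  p_loss <- 1 - exp(-cfg$loss_rate * len1)
  mu <- 60 * p_loss
  expect_lt(abs(mean(losses1) - mu), 3 * sqrt(60 * p_loss * (1 - p_loss) / nrep))
})

test_that("marker evolution matches the TN93 matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  # two leaves separated by total path 0.5 substitutions/site at 10 kb
  fixed <- ape::read.tree(text = "(a:2.5,b:2.5);")
  cfg <- sim_config(n_genomes = 3, tree_mode = "fixed_newick",
                    fixed_tree = fixed, marker_length = 10000,
                    marker_scale = 0.1, kappa1 = 1, kappa2 = 1, beta = 1,
                    base_freqs = c(0.3, 0.2, 0.2, 0.3), seed = 8)
  aln <- simulate_marker_alignment(fixed, cfg)
  sp <- substitution_proportions(aln$seq[1], aln$seq[2])
  P <- tn93_expm(0.5, cfg$base_freqs, 1, 1, 1)
  p <- cfg$base_freqs
  exp_P1 <- p[["A"]] * P["A", "G"] + p[["G"]] * P["G", "A"]
  exp_P2 <- p[["C"]] * P["C", "T"] + p[["T"]] * P["T", "C"]
  exp_Q <- sum(vapply(c("A", "G"), function(i) {
    p[[i]] * (P[i, "C"] + P[i, "T"])
  }, numeric(1))) + sum(vapply(c("C", "T"), function(i) {
    p[[i]] * (P[i, "A"] + P[i, "G"])
  }, numeric(1)))
  se <- function(pr) sqrt(pr * (1 - pr) / 10000)
  expect_lt(abs(sp$P1 - exp_P1), 3 * se(exp_P1))
  expect_lt(abs(sp$P2 - exp_P2), 3 * se(exp_P2))
  expect_lt(abs(sp$Q - exp_Q), 3 * se(exp_Q))

  # zero branch lengths: all sequences identical
  flat <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  cfg0 <- sim_config(n_genomes = 3, tree_mode = "fixed_newick",
                     fixed_tree = flat, marker_length = 500, seed = 2)
  aln0 <- simulate_marker_alignment(flat, cfg0)
  expect_length(unique(aln0$seq), 1)
})

test_that("closed-form TN93 transition probabilities agree with expm", {
  skip_if_not_installed("Matrix")
  for (t in c(0.01, 0.1, 0.5, 2)) {
    P1 <- tn93_transition_probs(t, c(0.254, 0.229, 0.313, 0.204), 2, 4, 1)
    P2 <- tn93_expm(t, c(0.254, 0.229, 0.313, 0.204), 2, 4, 1)
    expect_equal(P1, P2, tolerance = 1e-10)
    expect_equal(unname(rowSums(P1)), rep(1, 4), tolerance = 1e-12)
  }
})

test_that("proteomes conserve the truth families and obey the decay knob", {
  cfg <- sim_config(n_genomes = 5, seed = 6, protein_identity_decay = 0)
  cl <- simulate_clade(cfg)
  all_genes <- unlist(lapply(cl$proteomes, function(p) p$id))
  expect_setequal(all_genes, cl$truth$membership$gene_id)
  expect_equal(anyDuplicated(all_genes), 0)

  # decay 0: within-family sequences identical across genomes
  seqs <- dplyr::bind_rows(cl$proteomes)
  fam_of <- sub("^g\\d+_", "", seqs$id)
  n_distinct <- tapply(seqs$seq, fam_of, function(x) length(unique(x)))
  expect_true(all(n_distinct == 1))

  # nonzero decay: identity decreases but families stay recognizable
  cfg2 <- sim_config(n_genomes = 5, seed = 6, protein_identity_decay = 0.15)
  cl2 <- simulate_clade(cfg2)
  fam <- cl2$truth$membership$family_id[1]
  members <- cl2$truth$membership[cl2$truth$membership$family_id == fam, ]
  if (nrow(members) >= 2) {
    s1 <- dplyr::bind_rows(cl2$proteomes)
    a <- s1$seq[s1$id == members$gene_id[1]]
    b <- s1$seq[s1$id == members$gene_id[2]]
    id <- pairwise_identity(a, b)$identity
    expect_gt(id, 50)
    expect_lt(id, 100)
  }
})

test_that("the MGE fraction labels exactly the flagged subset", {
  cfg <- sim_config(n_genomes = 5, seed = 12, mge_fraction = 0.1)
  cl <- simulate_clade(cfg)
  n_genes <- nrow(cl$annotations)
  expect_equal(length(cl$mge_genes), round(0.1 * n_genes))
  expect_setequal(flag_mge(cl$annotations), cl$mge_genes)
})
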