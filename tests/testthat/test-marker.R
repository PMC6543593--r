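test_that("marker filtering applies the inclusive length window and dedup", {
  recs <- seq_tbl(c("a", "b", "c", "d"),
                  vapply(c(1250, 1300, 1550, 1600), function(n) strrep("A", n),
                         character(1)))
  out <- filter_marker_sequences(recs, 1300, 1550)
  expect_equal(out$id, c("b", "c"))
  counts <- attr(out, "filter_counts")
  expect_equal(counts$n[counts$reason == "length_out_of_window"], 2)

  dup <- seq_tbl(c("x", "y"), rep(strrep("ACGT", 350), 2))
  expect_equal(filter_marker_sequences(dup)$id, "x")

  empty <- filter_marker_sequences(seq_tbl(character(), character()))
  expect_equal(nrow(empty), 0)
  expect_equal(sum(attr(empty, "filter_counts")$n), 0)

  expect_error(filter_marker_sequences(recs, 1550, 1300), "min_len")
})

test_that("substitution proportions count the three difference classes", {
  sp0 <- substitution_proportions("ACGT", "ACGT")
  expect_equal(c(sp0$P1, sp0$P2, sp0$Q), c(0, 0, 0))

  sp1 <- substitution_proportions("AG", "GG")
  expect_equal(sp1$P1, 0.5)
  expect_equal(sp1$P2, 0)
  expect_equal(sp1$Q, 0)

  # planted 1000-site fixture: 30 A<->G, 20 C<->T, 10 transversions
  set.seed(21)
  a <- rep(c("A", "C", "G", "T"), 250)
  b <- a
  b[1:30] <- "G"        # sites are A at 1,5,9,... pattern: pick A sites
  a_sites <- which(a == "A")[1:30]
  c_sites <- which(a == "C")[1:20]
  g_sites <- which(a == "G")[1:10]
  b <- a
  b[a_sites] <- "G"
  b[c_sites] <- "T"
  b[g_sites] <- "C"
  sp2 <- substitution_proportions(paste(a, collapse = ""), paste(b, collapse = ""))
  expect_equal(c(sp2$P1, sp2$P2, sp2$Q), c(0.03, 0.02, 0.01))
  expect_equal(sp2$sites_used, 1000)

  # pairwise deletion of gaps and ambiguity
  sp3 <- substitution_proportions("A-GN", "AAGA")
  expect_equal(sp3$sites_used, 2)
  expect_error(substitution_proportions("--", "AA"), "no comparable sites")
  expect_error(substitution_proportions("A", "AA"), "aligned")
})

test_that("TN93 distance matches K2P and JC69 closed forms in their limits", {
  eq <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  mk <- function(P1, P2, Q) list(P1 = P1, P2 = P2, Q = Q, base_freqs = eq,
                                 sites_used = 1000)
  expect_equal(tn93_distance(mk(0, 0, 0)), 0)

  for (P in c(0.02, 0.06, 0.10, 0.16)) {
    for (Q in c(0.01, 0.05, 0.09)) {
      expect_equal(tn93_distance(mk(P / 2, P / 2, Q)), k2p_dist(P, Q),
                   tolerance = 1e-12)
    }
  }
  # JC69: all six unordered difference classes equally likely
  for (D in c(0.03, 0.12, 0.3)) {
    expect_equal(tn93_distance(mk(D / 6, D / 6, 4 * D / 6)), jc69_dist(D),
                 tolerance = 1e-12)
  }
  # saturation of the estimator returns the NA sentinel with a reason
  sat <- tn93_distance(mk(0.55, 0, 0.1))
  expect_true(is.na(sat))
  expect_match(attr(sat, "reason"), "saturated")
})

test_that("TN93 distances agree with an independent implementation", {
  cfg <- sim_config(n_genomes = 6, seed = 31, marker_length = 2000)
  cl <- simulate_clade(cfg)
  m <- tn93_distance_matrix(cl$marker)
  chars <- do.call(rbind, strsplit(tolower(cl$marker$seq), ""))
  rownames(chars) <- cl$marker$id
  bin <- ape::as.DNAbin(chars)
  m_ape <- as.matrix(ape::dist.dna(bin, model = "TN93"))
  expect_equal(m[lower.tri(m)], m_ape[rownames(m), rownames(m)][lower.tri(m)],
               tolerance = 1e-3)
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) == 0))
})

test_that("estimated TN93 distance is consistent for long markers", {
  # true path length 0.1 substitutions/site, 20 kb marker (scaled-down
  # consistency check, 5% tolerance)
  fixed <- ape::read.tree(text = "(a:1,b:1);")
  cfg <- sim_config(n_genomes = 3, tree_mode = "fixed_newick",
                    fixed_tree = fixed, marker_length = 20000,
                    marker_scale = 0.05, seed = 17)
  aln <- simulate_marker_alignment(fixed, cfg)
  d <- tn93_distance(substitution_proportions(aln$seq[1], aln$seq[2]))
  expect_lt(abs(d - 0.1) / 0.1, 0.05)
})

test_that("saturation assessment separates fresh from randomized alignments", {
  # transition-biased, low-divergence: unsaturated
  cfg <- sim_config(n_genomes = 6, seed = 13)
  cl <- simulate_clade(cfg)
  rep_lo <- saturation_assessment(cl$marker)
  expect_equal(rep_lo$verdict, "not_saturated")
  expect_equal(nrow(rep_lo$pairs), choose(6, 2))

  # i.i.d. random sequences (stationarity): transversions dominate
  set.seed(14)
  rnd <- seq_tbl(paste0("r", 1:4),
                 vapply(rep(10000, 4), random_dna, character(1)))
  rep_hi <- saturation_assessment(rnd)
  expect_equal(rep_hi$verdict, "saturated")
  expect_true(all(rep_hi$pairs$v > rep_hi$pairs$s))

  # identical pair counts as not saturated under the v >= s tie rule
  same <- seq_tbl(c("a", "b"), rep("ACGTACGT", 2))
  rep_same <- saturation_assessment(same)
  expect_false(rep_same$pairs$saturated[1])
  expect_error(saturation_assessment(same[1, ]), ">= 2")
})

test_that("neighbor joining solves three taxa exactly and recovers additive matrices", {
  m3 <- matrix(c(0, 3, 8, 3, 0, 9, 8, 9, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- nj_tree(m3)
  # pendant lengths solve the three-point equations: a=1, b=2, c=7
  got <- setNames(tr3$edge.length[match(1:3, tr3$edge[, 2])],
                  tr3$tip.label)
  expect_equal(got[c("A", "B", "C")], c(A = 1, B = 2, C = 7))

  set.seed(41)
  for (i in 1:20) {
    t0 <- random_blen_tree(8)
    D <- ape::cophenetic.phylo(t0)
    est <- nj_tree(D)
    expect_equal(phangorn::RF.dist(ape::unroot(t0), est), 0)
    expect_equal(max(abs(ape::cophenetic.phylo(est)[rownames(D), colnames(D)] - D)),
                 0, tolerance = 1e-9)
  }

  # degenerate all-equal distances: deterministic output
  meq <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(meq) <- 0
  expect_identical(ape::write.tree(nj_tree(meq)), ape::write.tree(nj_tree(meq)))

  mna <- m3; mna[1, 2] <- mna[2, 1] <- NA
  expect_error(nj_tree(mna), "drop taxa")
})

test_that("outgroup rooting splits the outgroup edge at its midpoint", {
  tr <- ape::read.tree(text = "((A:1,B:1):0.5,(C:1,D:2):0.5);")
  un <- ape::unroot(tr)
  rt <- root_by_outgroup(un, "D")
  expect_true(ape::is.rooted(rt))
  # D is sister to everything else
  ntip <- length(rt$tip.label)
  root_children <- rt$edge[rt$edge[, 1] == ntip + 1, 2]
  d_tip <- which(rt$tip.label == "D")
  expect_true(d_tip %in% root_children)
  # the two root edges each carry half of D's pendant edge
  root_lens <- rt$edge.length[rt$edge[, 1] == ntip + 1]
  expect_equal(root_lens[1], root_lens[2])
  # rooting then unrooting returns the original topology and total length
  expect_equal(phangorn::RF.dist(ape::unroot(rt), un), 0)
  expect_equal(sum(rt$edge.length), sum(un$edge.length))

  expect_error(root_by_outgroup(un, "Z"), "not a leaf")
})
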