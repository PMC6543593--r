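test_that("Wagner reconstruction matches hand-worked small cases", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  counts <- matrix(c(2, 0, 0), 1, 3, dimnames = list("f1", c("A", "B", "C")))
  v <- wagner_ancestral_counts(tr, counts)
  expect_equal(unname(v["f1", c("A", "B", "C")]), c(2, 0, 0))
  ntip <- 3
  root_lab <- colnames(v)[ntip + 1]
  expect_equal(unname(v["f1", root_lab]), 0L)
  ev <- branch_gain_loss(tr, v)
  expect_equal(sum(ev$gains) + sum(ev$losses), 2)  # one gain of 2 on A's branch
  expect_equal(ev$gains[ev$child_label == "A"], 2)

  tr4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  c4 <- matrix(c(1, 1, 0, 0), 1, 4,
               dimnames = list("f1", c("A", "B", "C", "D")))
  v4 <- wagner_ancestral_counts(tr4, c4)
  labs <- colnames(v4)
  # internal nodes: AB ancestor 1, CD ancestor 0, root 0 (interval {0,1},
  # minimum tie-break)
  expect_equal(unname(v4["f1", labs[5]]), 0L)  # root
  ev4 <- branch_gain_loss(tr4, v4)
  expect_equal(sum(ev4$gains) + sum(ev4$losses), 1)

  # all leaves equal k: ancestors all k, zero events
  ck <- matrix(3, 1, 4, dimnames = list("f1", c("A", "B", "C", "D")))
  vk <- wagner_ancestral_counts(tr4, ck)
  expect_true(all(vk == 3))
  evk <- branch_gain_loss(tr4, vk)
  expect_true(all(evk$gains == 0 & evk$losses == 0))
})

test_that("input validation rejects unrooted trees and negative counts", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  un <- ape::unroot(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"))
  cm <- matrix(1, 1, 4, dimnames = list("f1", c("A", "B", "C", "D")))
  expect_error(wagner_ancestral_counts(un, cm), "root")
  bad <- matrix(c(1, -1, 0), 1, 3, dimnames = list("f1", c("A", "B", "C")))
  expect_error(wagner_ancestral_counts(tr, bad), "negative")
})

test_that("per-branch events and rates follow their definitions", {
  tr <- ape::read.tree(text = "((A:2,B:1):1,C:1);")
  counts <- matrix(c(5, 3, 1, 2, 0, 1), 2, 3, byrow = TRUE,
                   dimnames = list(c("f1", "f2"), c("A", "B", "C")))
  v <- wagner_ancestral_counts(tr, counts)
  ev <- branch_gain_loss(tr, v)
  # definition check on one branch: gains/losses are summed family diffs
  a_edge <- ev[ev$child_label == "A", ]
  parent_vals <- v[, a_edge$parent_label]
  diffs <- counts[, "A"] - parent_vals
  expect_equal(a_edge$gains, sum(pmax(diffs, 0)))
  expect_equal(a_edge$losses, sum(pmax(-diffs, 0)))

  rates <- branch_turnover_rates(ev)
  expect_equal(rates$gain_rate, rates$gains / rates$branch_length)
  # doubling branch lengths halves all defined rates
  ev2 <- ev
  ev2$branch_length <- ev2$branch_length * 2
  rates2 <- branch_turnover_rates(ev2)
  expect_equal(rates2$gain_rate, rates$gain_rate / 2)
  expect_equal(rates2$loss_rate, rates$loss_rate / 2)

  # zero-length branch with events: NA rate and a warning
  ev0 <- ev
  ev0$branch_length[1] <- 0
  if (ev0$gains[1] + ev0$losses[1] == 0) ev0$gains[1] <- 1
  expect_warning(r0 <- branch_turnover_rates(ev0), "zero-length")
  expect_true(is.na(r0$gain_rate[1]))
})

test_that("Wagner total change equals the brute-force minimum on random instances", {
  set.seed(81)
  for (i in 1:50) {
    n <- sample(3:6, 1)
    tr <- random_blen_tree(n)
    counts <- matrix(sample(0:4, n, replace = TRUE), 1, n,
                     dimnames = list("f1", tr$tip.label))
    v <- wagner_ancestral_counts(tr, counts)
    ev <- branch_gain_loss(tr, v)
    total <- sum(ev$gains) + sum(ev$losses)
    oracle <- wagner_brute_min(tr, setNames(counts[1, ], colnames(counts)))
    expect_equal(total, oracle)
    # leaves keep their input counts
    expect_equal(unname(v[1, tr$tip.label]), unname(counts[1, tr$tip.label]))
  }
})

test_that("turnover reconstruction recovers zero-loss histories exactly", {
  cfg <- sim_config(n_genomes = 7, gain_rate = 15, loss_rate = 0, seed = 82)
  tr <- simulate_tree(cfg)
  gc <- simulate_gene_content(tr, cfg)
  res <- gene_turnover(tr, gc$pan)
  expect_true(all(res$branches$losses == 0))
  truth <- gc$truth$events
  j <- dplyr::left_join(res$branches, truth, by = "child_label",
                        suffix = c("_rec", "_true"))
  expect_equal(j$gains_rec, j$gains_true)
  g <- glance(res)
  expect_equal(g$root_genes, cfg$root_family_count)
})

test_that("parsimony under-counts but tracks dense histories", {
  set.seed(83)
  rec_tot <- true_tot <- numeric(0)
  for (r in 1:50) {
    cfg <- sim_config(n_genomes = 6, root_family_count = 40, gain_rate = 4,
                      loss_rate = 0.1, seed = 4000 + r)
    tr <- simulate_tree(cfg)
    gc <- simulate_gene_content(tr, cfg)
    res <- gene_turnover(tr, gc$pan)
    j <- dplyr::left_join(res$branches, gc$truth$events, by = "child_label",
                          suffix = c("_rec", "_true"))
    rec_tot <- c(rec_tot, j$gains_rec + j$losses_rec)
    true_tot <- c(true_tot, j$gains_true + j$losses_true)
    # parsimony never infers more change than actually happened
    expect_lte(sum(j$gains_rec + j$losses_rec),
               sum(j$gains_true + j$losses_true))
  }
  expect_gte(cor(rec_tot, true_tot, method = "spearman"), 0.8)
})
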