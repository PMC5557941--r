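test_that("NJ recovers additive distances exactly", {
  withr::local_seed(3)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    true <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    d <- ape::cophenetic.phylo(true)
    ids <- rownames(d)
    got <- nj_tree(make_dist(d, ids = ids))
    # same unrooted topology, and the full path-length matrix is restored
    expect_equal(ape::dist.topo(ape::unroot(true), ape::unroot(got)), 0,
                 ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(got)[ids, ids], d, tolerance = 1e-8)
  }
})

test_that("three taxa solve the three-point formulas", {
  d <- matrix(c(0, 0.2, 0.5,
                0.2, 0, 0.4,
                0.5, 0.4, 0), 3, 3)
  tr <- nj_tree(make_dist(d, ids = c("a", "b", "c")))
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(len["a"]), (0.2 + 0.5 - 0.4) / 2, tolerance = 1e-12)
  expect_equal(unname(len["b"]), (0.2 + 0.4 - 0.5) / 2, tolerance = 1e-12)
  expect_equal(unname(len["c"]), (0.5 + 0.4 - 0.2) / 2, tolerance = 1e-12)
  expect_error(nj_tree(make_dist(matrix(0, 2, 2))), class = "bg_error_size")
})

test_that("equal distances give a deterministic tree", {
  d <- matrix(0.1, 4, 4); diag(d) <- 0
  t1 <- nj_tree(make_dist(d))
  t2 <- nj_tree(make_dist(d))
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("monophyly classifies clusters on a rooted tree", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  p <- as_partition(c(a = "X", b = "X", c = "Y", d = "Y"))
  rep1 <- monophyly(tr, p)
  expect_equal(rep1$status, c("monophyletic", "monophyletic"))

  p2 <- as_partition(c(a = "X", c = "X", b = "Y", d = "Y"))
  rep2 <- monophyly(tr, p2)
  expect_true(all(rep2$status == "non-monophyletic"))

  # singleton clusters are trivial; absent leaves make a cluster unresolvable
  p3 <- as_partition(c(a = "X", b = "Y", c = "Y", d = "Y", e = "Z"))
  rep3 <- monophyly(tr, p3)
  expect_equal(rep3$status[rep3$group == "X"], "trivial")
  expect_equal(rep3$status[rep3$group == "Z"], "unresolvable")

  # unrooted trees need an outgroup
  un <- ape::unroot(ape::read.tree(text = "((a,b),(c,d),(e,f));"))
  expect_error(monophyly(un, p), class = "bg_error_rooting")
  rooted <- monophyly(un, as_partition(c(a = "X", b = "X", c = "Y", d = "Y")),
                      outgroup = c("e", "f"))
  expect_equal(rooted$status, c("monophyletic", "monophyletic"))
})

test_that("monophyly is invariant to leaf input order", {
  tr <- ape::read.tree(text = "(((a,b),c),(d,e));")
  base <- c(a = "X", b = "X", c = "X", d = "Y", e = "Y")
  r1 <- monophyly(tr, as_partition(base))
  r2 <- monophyly(tr, as_partition(base[c(4, 2, 5, 1, 3)]))
  expect_equal(dplyr::arrange(r1, group)$status,
               dplyr::arrange(r2, group)$status)
})

test_that("bootstrap is seeded, bounded, and finds planted structure", {
  sim <- simulate_dataset(n_species = 2, n_individuals = 8, seq_length = 300,
                          inter_divergence = c(0.15, 0.2), seed = 5)
  b1 <- bootstrap_support(sim$alignment, replicates = 50, seed = 99)
  b2 <- bootstrap_support(sim$alignment, replicates = 50, seed = 99)
  expect_identical(b1$support, b2$support)
  expect_true(all(b1$support$support >= 0 & b1$support$support <= 1))

  # the two planted species are separated with high support
  tru <- split(sim$truth$partition$specimen_id, sim$truth$partition$group)
  mono <- monophyly(b1$tree, sim$truth$partition, outgroup = tru[[1]],
                    boot_trees = NULL)
  expect_true(all(mono$status == "monophyletic"))
  sup <- monophyly(ape::root(b1$tree, outgroup = tru[[1]],
                             resolve.root = TRUE),
                   sim$truth$partition, boot_trees = replicate(
                     20, nj_tree(distance_matrix(sim$alignment)),
                     simplify = FALSE))
  expect_true(all(sup$support == 1))

  b3 <- bootstrap_support(sim$alignment, replicates = 1, seed = 1)
  expect_true(all(b3$support$support %in% c(0, 1)))
  expect_error(bootstrap_support(sim$alignment, replicates = 0),
               class = "bg_error_parameter")
})

test_that("planted clusters reach high bootstrap support", {
  sim <- simulate_dataset(n_species = 2, n_individuals = 10, seq_length = 400,
                          intra_divergence = 0.01,
                          inter_divergence = c(0.15, 0.2), seed = 21)
  b <- bootstrap_support(sim$alignment, replicates = 100, seed = 7)
  tru <- split(sim$truth$partition$specimen_id, sim$truth$partition$group)
  # support of the species bipartition, counted over the bootstrap trees
  boots <- withr::with_seed(7, replicate(100, {
    cols <- sample.int(400, 400, replace = TRUE)
    nj_tree(distance_matrix(aligned_matrix(unclass(sim$alignment)[, cols])))
  }, simplify = FALSE))
  frac <- mean(vapply(boots, barcogeo:::is_split_of, logical(1),
                      tipset = tru[[1]]))
  expect_gte(frac, 0.95)
})
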