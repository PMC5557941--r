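test_that("gap detection follows its worked examples", {
  # no positive gap at all
  expect_true(is.na(find_gap_threshold(c(0, 0, 0), prior = 0.01)))
  # clear gap after three low ranks: midpoint of [0.007, 0.10]
  expect_equal(find_gap_threshold(c(0.005, 0.006, 0.007, 0.10, 0.11),
                                  prior = 0.01), 0.0535)
  # uniform ladder: every gap equals the local reference, strict test fails
  expect_true(is.na(find_gap_threshold(seq(0.01, 0.10, by = 0.01),
                                       prior = 0.005)))
  expect_error(find_gap_threshold(numeric(0), prior = 0.01),
               class = "bg_error_empty")
})

test_that("threshold partitioning is connectivity clustering", {
  d <- matrix(c(0, 0.01, 0.05,
                0.01, 0, 0.01,
                0.05, 0.01, 0), 3, 3)
  dm <- make_dist(d, ids = c("a", "b", "c"))
  # chaining: a-b and b-c linked, so one group despite d(a,c) > t
  p <- partition_at_threshold(dm, 0.02)
  expect_equal(partition_k(p), 1L)
  # t >= max distance: one group; t below min positive distance: singletons
  expect_equal(partition_k(partition_at_threshold(dm, 1)), 1L)
  expect_equal(partition_k(partition_at_threshold(dm, 0.001)), 3L)
  expect_error(partition_at_threshold(dm, -1), class = "bg_error_parameter")
})

test_that("threshold partitioning equals brute-force transitive closure", {
  withr::local_seed(23)
  for (rep in 1:8) {
    n <- sample(4:10, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0, 0.2)
    d <- d + t(d)
    dm <- make_dist(d)
    t <- runif(1, 0, 0.2)
    got <- partition_at_threshold(dm, t)
    want <- oracle_components(d, t)
    expect_equal(adjusted_rand(got, as_partition(
      setNames(paste0("C", want), dm$ids))), 1)
  }
})

test_that("partitions are nested in the threshold", {
  withr::local_seed(9)
  n <- 12
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0, 0.2)
  d <- d + t(d)
  dm <- make_dist(d)
  ts <- sort(runif(6, 0, 0.25))
  parts <- lapply(ts, function(t) partition_at_threshold(dm, t))
  for (i in seq_len(length(ts) - 1)) {
    expect_true(is_refinement(parts[[i]], parts[[i + 1]]))
  }
})

test_that("primary partition recovers a planted two-cluster gap", {
  dm <- block_dist(c(4, 5), wd = 0.008, bd = 0.12)
  p <- primary_partition(dm, prior = 0.02)
  expect_equal(partition_k(p), 2L)
  expect_false(attr(p, "fallback"))
  # identical sequences: one group at every prior (threshold falls back to P)
  dm0 <- make_dist(matrix(0, 4, 4))
  for (P in c(0.001, 0.01, 0.1)) {
    expect_equal(partition_k(primary_partition(dm0, P)), 1L)
  }
})

test_that("recursion refines the primary partition and finds nested gaps", {
  # two outer blocks; the first splits again at a mid-level gap
  n <- 9
  grp <- c(1, 1, 1, 2, 2, 2, 3, 3, 3) # 1+2 form the outer left block
  d <- matrix(0.15, n, n)
  for (g in 1:3) d[grp == g, grp == g] <- 0.005
  left <- grp %in% c(1, 2)
  d[left, left][d[left, left] == 0.15] <- 0.04
  diag(d) <- 0
  dm <- make_dist(d)
  prim <- primary_partition(dm, prior = 0.01)
  expect_equal(partition_k(prim), 2L)
  rec <- recursive_partition(dm, prior = 0.01)
  expect_equal(partition_k(rec), 3L)
  expect_true(is_refinement(rec, prim))

  # all-singletons primary is a fixed point of recursion
  dms <- block_dist(rep(1, 5), wd = 0, bd = 0.1)
  prim2 <- primary_partition(dms, prior = 0.001)
  expect_equal(partition_k(prim2), 5L)
  expect_equal(partition_k(recursive_partition(dms, prior = 0.001)), 5L)
})

test_that("recursive partitions refine primary ones at every prior", {
  withr::local_seed(31)
  sim <- simulate_dataset(n_species = 6, n_individuals = 30, seq_length = 300)
  dm <- distance_matrix(sim$alignment)
  ps <- prior_scan(dm, n_priors = 8)
  for (i in seq_len(nrow(ps$scan))) {
    expect_true(is_refinement(ps$partitions$recursive[[i]],
                              ps$partitions$primary[[i]]))
    expect_gte(ps$scan$recursive_k[i], ps$scan$primary_k[i])
  }
  # plateaus are disjoint and cover the grid
  expect_equal(sum(ps$plateaus$width), nrow(ps$scan))
  expect_equal(ps$plateaus$start[-1], ps$plateaus$end[-nrow(ps$plateaus)] + 1L)
})

test_that("plateau selection picks the widest run, ties to larger priors", {
  pl <- barcogeo:::plateau_table(c(5L, 5L, 5L, 3L, 3L))
  expect_equal(pl$k[barcogeo:::select_widest_plateau(pl)], 5L)
  pl2 <- barcogeo:::plateau_table(c(7L, 7L, 2L, 2L))
  expect_equal(barcogeo:::select_widest_plateau(pl2), 2L) # tie -> later run
  pl3 <- barcogeo:::plateau_table(c(1L, 1L, 1L))
  expect_equal(nrow(pl3), 1L)
})

test_that("the prior scan recovers a planted eight-species truth", {
  sim <- simulate_dataset(n_species = 8, n_individuals = 40, seq_length = 400,
                          intra_divergence = 0.02,
                          inter_divergence = c(0.12, 0.20), seed = 101)
  dm <- distance_matrix(sim$alignment)
  ps <- prior_scan(dm)
  expect_equal(partition_k(ps$selected), 8L)
  expect_equal(adjusted_rand(ps$selected, sim$truth$partition), 1)
})
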