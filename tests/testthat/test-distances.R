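test_that("pairwise K2P matches its closed forms", {
  expect_equal(k2p_distance("AAAA", "AAAA")$distance, 0)
  expect_equal(k2p_distance("AAAA", "AAAA")$sites, 4L)

  # one transition among four sites: p_ts = 1/4, d = -log(1/2)/2
  r <- k2p_distance("AAAA", "AGAA")
  expect_equal(r$distance, -0.5 * log(0.5), tolerance = 1e-12)
  expect_equal(r$p_ts, 0.25)

  # pairwise deletion drops the gapped column
  r <- k2p_distance("A-AA", "AGAA")
  expect_equal(r$sites, 3L)
  expect_equal(r$distance, 0)

  # a single transition over a 658-site barcode
  a <- strrep("A", 658)
  b <- paste0("G", strrep("A", 657))
  expect_equal(k2p_distance(a, b)$distance, -0.5 * log(1 - 2 / 658),
               tolerance = 1e-12)

  expect_error(k2p_distance("AAA", "AAAA"), class = "bg_error_shape")
  expect_error(k2p_distance("NNN-", "AAAA"), class = "bg_error_incomparable")
  expect_error(k2p_distance("AAAA", "GGGG"), class = "bg_error_saturation")
})

test_that("K2P is symmetric and invariant to appending identical columns", {
  withr::local_seed(11)
  for (rep in 1:10) {
    a <- paste(sample(c("A", "C", "G", "T", "-", "N"), 30, replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T", "-"), 30, replace = TRUE),
               collapse = "")
    ra <- try(k2p_distance(a, b), silent = TRUE)
    rb <- try(k2p_distance(b, a), silent = TRUE)
    if (inherits(ra, "try-error")) {
      expect_true(inherits(rb, "try-error"))
      next
    }
    expect_equal(ra$distance, rb$distance)
    # appending the same extra column to both leaves nothing changed except
    # one more comparable (identical) site
    r2 <- k2p_distance(paste0(a, "C"), paste0(b, "C"))
    expect_equal(r2$sites, ra$sites + 1L)
    expect_true(r2$distance <= ra$distance + 1e-12)
  }
})

test_that("distance_matrix equals brute-force per-pair recomputation", {
  withr::local_seed(42)
  aln <- random_alignment(10, 50)
  dm <- distance_matrix(aln)
  expect_equal(dm$d, t(dm$d))
  expect_true(all(diag(dm$d) == 0))
  for (i in 1:9) {
    for (j in (i + 1):10) {
      o <- oracle_k2p(paste(aln[i, ], collapse = ""),
                      paste(aln[j, ], collapse = ""))
      expect_equal(dm$d[i, j], o$d, tolerance = 1e-12)
      expect_equal(unname(dm$sites[i, j]), o$sites)
    }
  }
})

test_that("distance_matrix agrees with an independent K80 implementation", {
  withr::local_seed(7)
  aln <- random_alignment(8, 200)
  dm <- distance_matrix(aln)
  ref <- ape::dist.dna(ape::as.DNAbin(unclass(aln)), model = "K80",
                       pairwise.deletion = TRUE, as.matrix = TRUE)
  ref <- ref[dm$ids, dm$ids]
  # our container flags saturated/incomparable pairs as NA where ape emits
  # non-finite values; compare the defined entries and the flag pattern
  expect_equal(is.na(dm$d), !is.finite(ref), ignore_attr = TRUE)
  ok <- !is.na(dm$d)
  expect_equal(unname(dm$d[ok]), unname(ref[ok]), tolerance = 1e-10)
})

test_that("saturated and incomparable pairs are reported, not fatal", {
  aln <- aligned_matrix(c(a = "AAAAAA", b = "GGGGGG", c = "AAAAAA",
                          d = "NNNNNN"))
  dm <- distance_matrix(aln)
  expect_true(is.na(dm$d["a", "b"]))
  expect_true(any(dm$diagnostics$type == "saturated"))
  expect_true(any(dm$diagnostics$type == "incomparable"))
  capped <- suppressMessages(cap_saturated(dm))
  expect_false(is.na(capped$d["a", "b"]))
})

test_that("distance summaries pool pairs within and between groups", {
  d <- matrix(c(0, 0.01, 0.10,
                0.01, 0, 0.12,
                0.10, 0.12, 0), 3, 3)
  dm <- make_dist(d, ids = c("a", "b", "c"))
  p <- as_partition(c(a = "g1", b = "g1", c = "g2"))
  s <- summarize_distances(dm, p)
  expect_equal(s$mean[s$type == "intra"], 0.01)
  expect_equal(s$mean[s$type == "inter"], 0.11)
  expect_equal(s$n_pairs, c(1L, 2L))
  expect_equal(attr(s, "per_group_max")$max, 0.01)

  # all singletons: no intra pairs
  s2 <- summarize_distances(dm, as_partition(c(a = "x", b = "y", c = "z")))
  expect_false(s2$defined[s2$type == "intra"])
  # one group: no inter pairs
  s3 <- summarize_distances(dm, as_partition(c(a = "x", b = "x", c = "x")))
  expect_false(s3$defined[s3$type == "inter"])
  expect_equal(sum(s3$n_pairs), 3L)

  expect_error(summarize_distances(dm, as_partition(c(a = "x", b = "y"))),
               class = "bg_error_integrity")
})

test_that("distance histograms conserve the pair count", {
  dm <- make_dist(matrix(0, 3, 3))
  h <- distance_histogram(dm)
  expect_equal(sum(h$count), 3L)
  expect_equal(h$count[1], 3L)

  withr::local_seed(5)
  for (n in c(5, 9)) {
    d <- matrix(0, n, n)
    v <- runif(n * (n - 1) / 2, 0, 0.3)
    d[upper.tri(d)] <- v
    d <- d + t(d)
    h <- distance_histogram(make_dist(d), bins = 7)
    expect_equal(sum(h$count), n * (n - 1) / 2)
    expect_equal(nrow(h), 7L)
  }
  expect_error(distance_histogram(dm, bins = 0), class = "bg_error_parameter")
})
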