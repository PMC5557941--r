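test_that("partition meet is the common refinement", {
  p1 <- as_partition(c(a = "g1", b = "g1", c = "g2"))
  p2 <- as_partition(c(a = "h1", b = "h2", c = "h2"))
  m <- partition_meet(p1, p2)
  expect_equal(partition_k(m), 3L) # {a},{b},{c}
  # idempotence and the all-singletons absorbing element
  expect_equal(adjusted_rand(partition_meet(p1, p1), p1), 1)
  singl <- as_partition(c(a = "x", b = "y", c = "z"))
  expect_equal(adjusted_rand(partition_meet(p1, singl), singl), 1)
  expect_error(partition_meet(p1, as_partition(c(a = "x", d = "y"))),
               class = "bg_error_integrity")
})

test_that("meet is commutative, associative, and refines its inputs", {
  withr::local_seed(17)
  ids <- paste0("s", 1:12)
  for (rep in 1:6) {
    p1 <- random_partition(ids, 3)
    p2 <- random_partition(ids, 4)
    p3 <- random_partition(ids, 2)
    m12 <- partition_meet(p1, p2)
    expect_equal(adjusted_rand(m12, partition_meet(p2, p1)), 1)
    expect_equal(adjusted_rand(partition_meet(m12, p3),
                               partition_meet(p1, partition_meet(p2, p3))), 1)
    expect_true(is_refinement(m12, p1))
    expect_true(is_refinement(m12, p2))
    expect_gte(partition_k(m12), max(partition_k(p1), partition_k(p2)))
  }
})

test_that("adjusted Rand matches both an oracle and mclust", {
  p1 <- as_partition(c(a = "x", b = "x", c = "y", d = "y"))
  expect_equal(adjusted_rand(p1, p1), 1)
  # all-singletons vs one-group on n = 4: chance-level agreement
  expect_equal(adjusted_rand(as_partition(c(a = 1, b = 2, c = 3, d = 4) |>
                                            sapply(as.character)),
                             as_partition(c(a = "g", b = "g", c = "g", d = "g"))),
               0)
  skip_if_not_installed("mclust")
  withr::local_seed(29)
  ids <- paste0("s", 1:15)
  for (rep in 1:8) {
    pa <- random_partition(ids, sample(2:5, 1))
    pb <- random_partition(ids, sample(2:5, 1))
    got <- adjusted_rand(pa, pb)
    expect_equal(got, oracle_ari(pa, pb), tolerance = 1e-12)
    expect_equal(got,
                 mclust::adjustedRandIndex(
                   setNames(pa$group, pa$specimen_id)[ids],
                   setNames(pb$group, pb$specimen_id)[ids]),
                 tolerance = 1e-12)
  }
})

test_that("cluster-wise congruence flags exactly the disagreeing clusters", {
  ref <- as_partition(c(a = "g1", b = "g1", c = "g1"))
  other <- as_partition(c(a = "h1", b = "h1", c = "h2"))
  rep1 <- clusterwise_congruence(ref, list(split = other))
  expect_false(rep1$clusters$congruent)
  expect_equal(rep1$clusters$disagrees_with, "split")
  expect_equal(rep1$n_congruent, 0L)

  # others identical to the reference: everything congruent
  rep2 <- clusterwise_congruence(other, list(other, other))
  expect_true(all(rep2$clusters$congruent))
  expect_equal(rep2$n_congruent, 2L)
  expect_equal(unname(rep2$ari[1, 2]), 1)

  # order of "others" never changes the congruent count
  p3 <- as_partition(c(a = "z1", b = "z2", c = "z2"))
  c1 <- clusterwise_congruence(ref, list(other, p3))$n_congruent
  c2 <- clusterwise_congruence(ref, list(p3, other))$n_congruent
  expect_equal(c1, c2)
})

test_that("character reports exclude deformed specimens and find stasis", {
  meta <- tibble::tibble(
    specimen_id = paste0("s", 1:7),
    site_id = "x", latitude = 0, longitude = 0,
    morphospecies = "M", deformed = c(rep(FALSE, 6), TRUE),
    characters = c(
      list(c(pso = "A", th2 = "1")), list(c(pso = "A", th2 = "2")),
      list(c(pso = "B", th2 = "1")), list(c(pso = "B", th2 = "2")),
      list(c(pso = "C", th2 = "1")), list(c(pso = "C", th2 = "1")),
      list(c(pso = "WEIRD", th2 = "9")) # deformed: must not count
    )
  )
  p <- as_partition(setNames(c("g1", "g1", "g2", "g2", "g3", "g3", "g3"),
                             meta$specimen_id))
  cr <- character_report(meta, p)
  stab <- cr$stability
  expect_true(all(stab$stability[stab$character == "pso"] == 1))
  # th2 varies inside g1 and g2 but not g3
  expect_equal(stab$stability[stab$group == "g1" & stab$character == "th2"], 0.5)
  expect_equal(stab$stability[stab$group == "g3" & stab$character == "th2"], 1)
  # pso is diagnostic for every pair; th2 for none
  dg <- cr$diagnosability
  expect_true(all(dg$diagnosable[dg$character == "pso"]))
  expect_false(any(dg$diagnosable[dg$character == "th2"]))

  # removing the deformed specimen changes nothing
  cr2 <- character_report(meta[1:6, ], as_partition(
    setNames(c("g1", "g1", "g2", "g2", "g3", "g3"), meta$specimen_id[1:6])))
  expect_equal(cr$stability, cr2$stability)

  # two clusters with identical value sets: morphological stasis
  stasis_meta <- meta[1:4, ]
  stasis_meta$characters <- rep(list(c(pso = "Z")), 4)
  crs <- character_report(stasis_meta, as_partition(
    setNames(c("g1", "g1", "g2", "g2"), stasis_meta$specimen_id)))
  expect_false(any(crs$diagnosability$diagnosable))
})

test_that("species validation applies the three-criterion rule table", {
  ids <- paste0("s", 1:6)
  cand <- as_partition(setNames(rep(c("c1", "c2", "c3"), each = 2), ids))
  meta <- tibble::tibble(
    specimen_id = ids, site_id = "x", latitude = 0, longitude = 0,
    morphospecies = "M", deformed = FALSE,
    # clusters 1 and 2 mutually undiagnosable; cluster 3 distinct
    characters = c(rep(list(c(pso = "same")), 4), rep(list(c(pso = "own")), 2))
  )
  tr <- ape::read.tree(text = "(((s1,s2),(s3,s4)),(s5,s6));")
  mono <- monophyly(tr, cand)
  cong <- clusterwise_congruence(cand, list(geo = cand))
  chars <- character_report(meta, cand)
  v <- validate_species(cand, mono, cong, chars)
  expect_equal(v$status, c("cryptic_species", "cryptic_species",
                           "validated_species"))
  expect_equal(glance(v)$n_cryptic, 2L)

  # a non-monophyletic cluster is unresolved whatever the other flags
  bad <- as_partition(setNames(c("c1", "c2", "c1", "c2", "c3", "c3"), ids))
  mono_b <- monophyly(tr, bad)
  v2 <- validate_species(bad, mono_b,
                         clusterwise_congruence(bad, list(bad)),
                         character_report(meta, bad))
  expect_true(all(v2$status[v2$group %in% c("c1", "c2")] == "unresolved"))

  # all three criteria met everywhere: all validated
  meta_ok <- meta
  meta_ok$characters <- lapply(seq_along(ids), function(i) {
    c(pso = c("a", "a", "b", "b", "c", "c")[i])
  })
  v3 <- validate_species(cand, mono, cong, character_report(meta_ok, cand))
  expect_true(all(v3$status == "validated_species"))

  other_labels <- as_partition(setNames(rep(c("d1", "d2"), 3), ids))
  expect_error(validate_species(other_labels, mono, cong, chars),
               class = "bg_error_integrity")
})
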