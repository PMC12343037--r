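identity_rt <- structure(list(rotation = diag(3), translation = rep(0, 3)),
                         class = "rigid_transform")

test_that("identical structures pair completely at distance zero; a 5 A shift pairs nothing", {
  m <- make_backbone(30, 1)
  p <- pair_ca(m, m, identity_rt)
  expect_equal(nrow(p$pairs), 30L)
  expect_equal(p$pairs$seed_index, 1:30)
  expect_equal(p$pairs$query_index, 1:30)
  expect_true(all(p$pairs$distance < 1e-9))
  expect_equal(structural_mapping_percentage(p, m), 100)
  expect_equal(local_similarity(p, m), 1.0)

  shifted <- m
  shifted$ca <- m$ca + 5
  p2 <- pair_ca(m, shifted, identity_rt)
  expect_equal(nrow(p2$pairs), 0L)
  expect_equal(structural_mapping_percentage(p2, shifted), 0)
  expect_equal(local_similarity(p2, shifted), 0)
})

test_that("dynamic-programming pairing retains the exhaustive-maximum number of sub-2 A pairs", {
  set.seed(21)
  for (rep in 1:30) {
    n <- sample(3:8, 1); m <- sample(3:8, 1)
    seed <- structure_model(seq_len(n), rep("ALA", n),
                            matrix(runif(3 * n, 0, 6), n, 3), id = "s")
    query <- structure_model(seq_len(m), rep("ALA", m),
                             matrix(runif(3 * m, 0, 6), m, 3), id = "q")
    p <- pair_ca(seed, query, identity_rt)
    S <- pair_indicator(seed, query, identity_rt)
    expect_equal(nrow(p$pairs), oracle_max_monotone_pairs(S))
    # returned pairs are a valid monotone sub-cutoff pairing
    if (nrow(p$pairs) > 1) {
      expect_true(all(diff(p$pairs$seed_index) > 0))
      expect_true(all(diff(p$pairs$query_index) > 0))
    }
    expect_true(all(p$pairs$distance < 2))
  }
})

test_that("local similarity weights contiguously aligned runs by length", {
  # one run of 12 in a query of 24: c5 = c10 = 0.5, c15 = c20 = 0
  fake <- structure(list(pairs = data.frame(seed_index = 1:12, query_index = 1:12,
                                            distance = 0),
                         n_seed = 24L, n_query = 24L), class = "ca_pairing")
  q24 <- make_backbone(24, 1)
  expect_equal(local_similarity(fake, q24), (5 * 0.5 + 10 * 0.5) / 50)
  # no run reaching length 5 -> 0 (pairs broken every 3 residues)
  broken <- data.frame(seed_index = c(1:3, 7:9, 13:15),
                       query_index = c(1:3, 8:10, 15:17), distance = 0)
  fake2 <- structure(list(pairs = broken, n_seed = 24L, n_query = 24L),
                     class = "ca_pairing")
  expect_equal(local_similarity(fake2, q24), 0)
  # a full-length run on a 100-residue chain gives exactly 1
  q100 <- make_backbone(100, 1)
  full <- structure(list(pairs = data.frame(seed_index = 1:100, query_index = 1:100,
                                            distance = 0),
                         n_seed = 100L, n_query = 100L), class = "ca_pairing")
  expect_equal(local_similarity(full, q100), 1.0)
})

test_that("metrics are rigid-motion invariant and local similarity never exceeds the pairing fraction", {
  sp <- fixture_spec(jitter_sigma = 0.3, rng_seed = 31)
  seed <- plant_site(make_backbone(60, 31), fixture_spec(rng_seed = 31))$model
  rt <- fixed_rigid_motion()
  set.seed(32)
  for (k in 1:5) {
    q <- plant_site(make_backbone(60, 31 + k), sp)$model
    t <- fit_transform(q$ca[c(10, 30, 50), ], seed$ca[c(10, 30, 50), ])
    p <- pair_ca(seed, q, t)
    smp <- structural_mapping_percentage(p, q)
    sls <- local_similarity(p, q)
    expect_lte(sls, smp / 100 + 1e-9)
    # move both structures by the same rigid motion; transform conjugates
    seed2 <- transform_model(seed, rt)
    q2 <- transform_model(q, rt)
    t2 <- fit_transform(q2$ca[c(10, 30, 50), ], seed2$ca[c(10, 30, 50), ])
    p2 <- pair_ca(seed2, q2, t2)
    expect_equal(structural_mapping_percentage(p2, q2), smp, tolerance = 1e-6)
    expect_equal(local_similarity(p2, q2), sls, tolerance = 1e-6)
  }
})

test_that("local-similarity thresholds separate faithful hits from near-miss decoys", {
  # regime filter: faithful planted sites keep high local similarity, the
  # shifted-site near-miss falls below the stricter 0.4 threshold when its
  # distortion breaks the alignment into short runs
  seed <- plant_site(make_backbone(60, 40), fixture_spec(rng_seed = 40))$model
  site <- build_seed_site(seed, c(10L, 30L, 50L))
  pos_hit <- search_one(plant_site(make_backbone(60, 41),
                                   fixture_spec(jitter_sigma = 0.3, rng_seed = 41))$model, site)
  expect_gt(pos_hit$structural_local_similarity, 0.4)
  miss <- search_one(plant_site(make_backbone(60, 43),
                                fixture_spec(jitter_sigma = 0.3,
                                             decoy_mode = "shifted_site",
                                             rng_seed = 43))$model, site)
  if (!is.null(miss)) {
    expect_lt(miss$structural_local_similarity, pos_hit$structural_local_similarity)
  }
})
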