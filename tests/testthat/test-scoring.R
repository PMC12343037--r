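# Builds seed/query pairs whose anchor C-alphas coincide exactly, so the
# CA-only fit is the identity and every scored distance is known in advance.
triangle_ca <- function() {
  d <- c(8, 10, 12)
  x3 <- (d[1]^2 + d[2]^2 - d[3]^2) / (2 * d[1])
  rbind(c(0, 0, 0), c(d[1], 0, 0), c(x3, sqrt(d[2]^2 - x3^2), 0))
}

identity_pair <- function(cb_shift = c(0, 0, 0), extra_seed = NULL, extra_query = NULL) {
  ca <- triangle_ca()
  cb <- ca + matrix(rep(c(0, 0, 1.5), 3), 3, byrow = TRUE)
  seed_ca <- ca; seed_cb <- cb
  query_ca <- ca
  query_cb <- cb + cb_shift
  aa <- c("CYS", "ASP", "HIS")
  pos <- 1:3
  if (!is.null(extra_seed)) {
    seed_ca <- rbind(seed_ca, extra_seed$ca); seed_cb <- rbind(seed_cb, extra_seed$cb)
    query_ca <- rbind(query_ca, extra_query$ca); query_cb <- rbind(query_cb, extra_query$cb)
    aa <- c(aa, extra_seed$aa3)
    pos <- seq_len(length(aa))
  }
  list(seed = structure_model(pos, aa, seed_ca, seed_cb, id = "seed"),
       query = structure_model(pos, c("CYS", "ASP", "HIS", extra_query$aa3),
                               query_ca, query_cb, id = "query"))
}

test_that("residue distance averages CA and CB separations, with CA-only fallback", {
  ident <- structure(list(rotation = diag(3), translation = rep(0, 3)),
                     class = "rigid_transform")
  r_seed <- list(position = 1L, aa3 = "SER", ca = c(0, 0, 0), cb = c(0, 0, 1.5))
  expect_equal(residue_distance(r_seed, r_seed, ident), 0)
  r_q <- list(position = 1L, aa3 = "SER", ca = c(1, 0, 0), cb = c(2, 0, 1.5))
  expect_equal(residue_distance(r_seed, r_q, ident), 1.5)  # mean of 1 and 2
  r_gly <- list(position = 1L, aa3 = "GLY", ca = c(0.7, 0, 0), cb = NULL)
  expect_equal(residue_distance(r_seed, r_gly, ident), 0.7)
})

test_that("the mapping score is mean distance over n divided by n, and finding an additional residue lowers it", {
  # anchors coincide in CA; CB displaced by 0.6/1.2/1.8 A -> distances 0.3/0.6/0.9
  shift <- rbind(c(0.6, 0, 0), c(1.2, 0, 0), c(1.8, 0, 0))
  mods <- identity_pair(cb_shift = shift)
  site <- build_seed_site(mods$seed, 1:3, neighbor_window = 0)
  sm <- score_mapping(mods$query, site, 1:3, fit_atoms = "ca")
  expect_equal(sm$n_mapped, 3L)
  expect_equal(sort(sm$mapped$distance), c(0.3, 0.6, 0.9), tolerance = 1e-9)
  expect_equal(sm$score, 0.2, tolerance = 1e-9)           # mean 0.6 / n 3
  # plain-average variant differs exactly by the factor n
  sm_avg <- score_mapping(mods$query, site, 1:3, fit_atoms = "ca",
                          score_formula = "sum_over_n")
  expect_equal(sm_avg$score, 0.6, tolerance = 1e-9)

  # a fourth (additional) residue matched at 0.6 A: mean stays 0.6, n -> 4
  extra_seed <- list(ca = c(4, 8, 0), cb = c(4, 8, 1.5), aa3 = "TRP")
  extra_query <- list(ca = c(4.6, 8, 0), cb = c(4.6, 8, 1.5), aa3 = "TRP")
  mods4 <- identity_pair(cb_shift = shift, extra_seed = extra_seed,
                         extra_query = extra_query)
  site4 <- build_seed_site(mods4$seed, 1:3, additional_positions = 4L,
                           neighbor_window = 0)
  sm4 <- score_mapping(mods4$query, site4, 1:3, fit_atoms = "ca")
  expect_equal(sm4$n_mapped, 4L)
  expect_equal(sm4$score, 0.15, tolerance = 1e-9)          # 0.6 / 4
  expect_lt(sm4$score, sm$score)                           # penalization direction
})

test_that("additional residues match greedily nearest-first, one-to-one, within the radius", {
  extra_seed <- list(ca = rbind(c(20, 0, 0), c(20.9, 0, 0)),
                     cb = rbind(c(NA, NA, NA), c(NA, NA, NA)),
                     aa3 = c("TRP", "TRP"))
  extra_query <- list(ca = rbind(c(20.4, 0, 0), c(21.9, 0, 0)),
                      cb = rbind(c(NA, NA, NA), c(NA, NA, NA)),
                      aa3 = c("TRP", "TRP"))
  mods <- identity_pair(extra_seed = extra_seed, extra_query = extra_query)
  site <- build_seed_site(mods$seed, 1:3, additional_positions = 4:5,
                          neighbor_window = 0)
  sm <- score_mapping(mods$query, site, 1:3, fit_atoms = "ca")
  addl <- sm$mapped[sm$mapped$kind == "additional", ]
  # seed 4 takes the shared closest query residue (0.4 A); seed 5 falls back
  # to its next candidate at 1.0 A
  expect_equal(addl$seed_position, c(4L, 5L))
  expect_equal(addl$query_position, c(4L, 5L))
  expect_equal(addl$distance, c(0.4, 1.0), tolerance = 1e-9)

  # no allowed-type residue within the radius -> the additional is dropped
  far_query <- extra_query
  far_query$ca <- rbind(c(30, 0, 0), c(40, 0, 0))
  mods2 <- identity_pair(extra_seed = extra_seed, extra_query = far_query)
  site2 <- build_seed_site(mods2$seed, 1:3, additional_positions = 4:5,
                           neighbor_window = 0)
  sm2 <- score_mapping(mods2$query, site2, 1:3, fit_atoms = "ca")
  expect_equal(sum(sm2$mapped$kind == "additional"), 0L)
  expect_equal(sm2$n_mapped, 3L)
})

test_that("neighbor pairs follow the sequence offset, truncate at termini, and ignore type", {
  sp <- fixture_spec(rng_seed = 9)
  planted <- plant_site(make_backbone(60, 9), sp)
  m <- planted$model
  site0 <- build_seed_site(m, planted$positions, neighbor_window = 0)
  core <- data.frame(seed_position = planted$positions,
                     query_position = planted$positions,
                     distance = 0, kind = "anchor")
  ident <- fit_transform(m$ca[1:4, ], m$ca[1:4, ])
  expect_equal(nrow(match_neighbors(m, site0, core, ident, w = 0)), 0L)

  nb1 <- match_neighbors(m, site0, core, ident, w = 1)
  expect_equal(nrow(nb1), 6L)   # +-1 around each of three anchors
  expect_true(all(nb1$kind == "neighbor"))
  expect_true(all(nb1$distance < 1e-9))

  # anchor at the first residue: the -4..-1 offsets fall off the chain
  site_first <- build_seed_site(m, c(1L, planted$positions[2:3]), neighbor_window = 4)
  core_first <- data.frame(seed_position = 1L, query_position = 1L,
                           distance = 0, kind = "anchor")
  nb <- match_neighbors(m, site_first, core_first, ident, w = 4)
  expect_equal(nb$seed_position, 2:5)

  # overlapping windows: adjacent cores count each pair once
  core_adj <- data.frame(seed_position = c(20L, 21L), query_position = c(20L, 21L),
                         distance = 0, kind = "anchor")
  nb_adj <- match_neighbors(m, site0, core_adj, ident, w = 1)
  expect_equal(anyDuplicated(nb_adj[c("seed_position", "query_position")]), 0L)
  # (19,19) and (22,22); the core pairs themselves are not re-counted
  expect_equal(nb_adj$seed_position, c(19L, 22L))
})

test_that("self-hit scores exactly zero; scores are rigid-motion invariant and non-negative", {
  sp <- fixture_spec(rng_seed = 12)
  planted <- plant_site(make_backbone(60, 12), sp)
  site <- build_seed_site(planted$model, planted$positions)
  sm <- score_mapping(planted$model, site, planted$positions)
  expect_lt(sm$score, 1e-9)
  expect_gte(sm$score, 0)
  expect_equal(select_best(list(sm), threshold = 1e-6)$score, sm$score)

  # moving the whole query rigidly changes no score beyond numerics
  moved <- transform_model(planted$model, fixed_rigid_motion())
  moved$id <- "moved"
  sm2 <- score_mapping(moved, site, planted$positions)
  expect_equal(sm2$score, sm$score, tolerance = 1e-6)
  expect_true(all(sm2$mapped$distance >= 0))
})

test_that("best-mapping selection: strict threshold, lexicographic tie-break, empty input", {
  mk <- function(score, mapping) structure(list(score = score, mapping = as.integer(mapping)),
                                           class = "scored_mapping")
  expect_equal(select_best(list(mk(0.4, c(1, 2, 3)), mk(0.9, c(4, 5, 6))))$score, 0.4)
  expect_null(select_best(list(mk(1.2, c(1, 2, 3)), mk(3.0, c(4, 5, 6)))))
  expect_null(select_best(list(mk(1.0, c(1, 2, 3)))))   # strict <
  expect_null(select_best(list()))
  tie <- select_best(list(mk(0.3, c(9, 1, 2)), mk(0.3, c(2, 8, 9))))
  expect_equal(tie$mapping, c(2L, 8L, 9L))
})
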