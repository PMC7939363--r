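test_that("developmental instability is zero without noise and grows with it", {
  cfg <- tiny_config(max_steps = 25L)
  mech <- make_fixture("gradient_contraction")
  inst0 <- developmental_instability(mech, 2, "emd", cfg, seed = 3)
  expect_equal(inst0$instability, 0, tolerance = 1e-12)

  insts <- vapply(c(0.002, 0.008, 0.03), function(na) {
    cfg2 <- tiny_config(max_steps = 25L, noise_amplitude = na)
    developmental_instability(mech, 4, "emd", cfg2, seed = 3)$instability
  }, numeric(1))
  expect_true(all(diff(insts) > 0))
})

test_that("pruning a couplings-free mechanism empties the network", {
  cfg <- tiny_config(max_steps = 10L, n_twins = 2L, prune_patience = 5L,
                     noise_amplitude = 0.002)
  mech <- dev_mechanism(matrix(0, 10, 10), default_division_rate = 0)
  mech$T[1, 2] <- 0.7
  mech$T[2, 3] <- -0.4
  mech$T[3, 4] <- 1.1
  res <- prune(mech, cfg, seed = 21)
  expect_equal(n_interactions(res$mechanism), 0L)
  expect_equal(res$n_deleted, 3L)
  expect_true(all(res$history$accepted))
})

test_that("pruning keeps the essential chain, matching the exhaustive oracle", {
  cfg <- tiny_config(max_steps = 50L, n_twins = 3L, prune_patience = 10L,
                     noise_amplitude = 0.002)
  mech <- make_fixture("knife_edge")  # g1 -> g2 -> apical contraction
  mech <- with_superfluous(mech, list(c(4, 5, 0.8), c(5, 6, -0.6),
                                      c(6, 7, 0.3)))
  parent_twins <- simulate_twins(mech, cfg$n_twins, cfg, seed = 500)$morphs
  inst <- morphozoo:::pairwise_distance(parent_twins, "cmd")
  threshold <- inst + cfg$cmd_margin

  # exhaustive single-deletion oracle over all interactions
  ints <- mech_interactions(mech)
  oracle_essential <- vapply(seq_len(nrow(ints)), function(i) {
    cand <- delete_interaction(mech, i)
    tw <- simulate_twins(cand, cfg$n_twins, cfg, seed = 600 + i)
    if (tw$n_aberrant > 0) return(TRUE)
    morphozoo:::cross_distance(tw$morphs, parent_twins, "cmd") > threshold
  }, logical(1))
  # the g1->g2 edge and the contraction coupling are essential; the
  # dangling chain among unexpressed genes is not
  expect_true(oracle_essential[ints$type == "coupling"])
  expect_true(oracle_essential[ints$gene_from == 1 & ints$type == "network"])
  expect_false(any(oracle_essential[ints$gene_from %in% c(4, 5, 6)]))

  res <- prune(mech, cfg, seed = 21, parent_twins = parent_twins)
  kept <- mech_interactions(res$mechanism)
  expect_setequal(
    paste(kept$type, kept$gene_from, kept$gene_to, kept$target),
    paste(ints$type, ints$gene_from, ints$gene_to,
          ints$target)[oracle_essential])

  # acceptance contract re-checked post hoc: pruned morphology within
  # threshold CMD of the parent
  tw <- simulate_twins(res$mechanism, cfg$n_twins, cfg, seed = 700)
  expect_lte(morphozoo:::cross_distance(tw$morphs, parent_twins, "cmd"),
             threshold)
})

test_that("IS neighborhood: 8 mutants per parameter, one-parameter diffs", {
  cfg <- tiny_config(max_steps = 5L, n_twins = 1L, noise_amplitude = 0.001)
  mech <- make_fixture("knife_edge")
  tab <- mech_parameters(mech)
  rec <- is_neighborhood(mech, cfg, seed = 4, score = FALSE)
  expect_equal(nrow(rec), 8L * nrow(tab))
  expect_setequal(unique(rec$magnitude), c(-80, -60, -40, -20, 20, 40, 60, 80))
  expect_false(any(rec$magnitude == 0))

  # every mutant differs from the parent in exactly one parameter
  pv <- tab$value
  for (i in seq_len(nrow(rec))) {
    mv <- mech_parameters(rec$mechanism[[i]])$value
    changed <- which(abs(mv - pv) > 1e-12)
    expect_length(changed, 1L)
    expect_equal(changed, rec$param[i])
    expect_equal(mv[changed], pv[changed] * (1 + rec$magnitude[i] / 100))
  }

  # all enumerated parameters are non-zero (pruned-parent invariant)
  expect_true(all(tab$value != 0))
})

test_that("T neighborhoods: N_c deletions and N_c non-colliding additions", {
  cfg <- tiny_config(max_steps = 5L, n_twins = 1L, noise_amplitude = 0.001)
  mech <- make_fixture("knife_edge")
  n_c <- n_interactions(mech)
  rec <- t_neighborhoods(mech, cfg, seed = 4, score = FALSE)
  expect_equal(sum(rec$kind == "T_del"), n_c)
  expect_equal(sum(rec$kind == "T_add"), n_c)
  for (i in which(rec$kind == "T_del")) {
    expect_equal(n_interactions(rec$mechanism[[i]]), n_c - 1L)
  }
  for (i in which(rec$kind == "T_add")) {
    mut <- rec$mechanism[[i]]
    expect_equal(n_interactions(mut), n_c + 1L)
    # the parent's interactions are all still present (no overwrites)
    expect_true(all(mech$T[mech$T != 0] ==
                      mut$T[which(mech$T != 0)]))
  }

  # deleting then re-adding the same interaction restores the mechanism
  del <- delete_interaction(mech, 1)
  ints <- mech_interactions(mech)
  restored <- del
  restored$T[ints$gene_from[1], ints$gene_to[1]] <- ints$value[1]
  expect_identical(restored$T, mech$T)

  # collisions are resampled: with a nearly saturated network the new
  # interaction always lands on a free slot
  dense <- mech
  dense$T[] <- 0.5
  dense$T[3, 3] <- 0
  set.seed(77)
  for (i in 1:10) {
    grown <- morphozoo:::add_random_interaction(dense, cfg)
    new_net <- grown$T != 0 & dense$T == 0
    if (any(new_net)) {
      expect_equal(which(new_net), which(dense$T == 0))
    }
  }
})

test_that("iso walks accept everything for an insensitive mechanism", {
  cfg <- tiny_config(max_steps = 10L, n_twins = 2L, n_walks = 2L,
                     walk_steps = 8L, walk_twins = 2L,
                     noise_amplitude = 0.002)
  # network among never-expressed genes: morphology never changes
  mech <- dev_mechanism(matrix(0, 10, 10), default_division_rate = 0)
  mech$T[4, 5] <- 0.8
  mech$T[5, 6] <- -0.5
  wk <- iso_walk(mech, cfg, seed = 31)
  expect_equal(wk$accepted, c(8L, 8L))
  expect_true(all(wk$accepted <= wk$steps))
})

test_that("iso walks reject every step of a knife-edge mechanism", {
  cfg <- tiny_config(max_steps = 80L, n_twins = 3L, n_walks = 1L,
                     walk_steps = 6L, walk_twins = 2L,
                     noise_amplitude = 0.002)
  mech <- make_fixture("knife_edge")
  parent_twins <- simulate_twins(mech, cfg$n_twins, cfg, seed = 900)$morphs
  wk <- iso_walk(mech, cfg, seed = 31, parent_twins = parent_twins)
  expect_equal(wk$accepted, 0L)

  # exhaustive one-step oracle: every parameter, both signs, changes the
  # morphology beyond the acceptance threshold
  inst <- morphozoo:::pairwise_distance(parent_twins, "cmd")
  tab <- mech_parameters(mech)
  for (p in tab$param) {
    for (sgn in c(-1, 1)) {
      cand <- set_parameter(mech, p, tab$value[p] + sgn * 2 * tab$value[p])
      tw <- simulate_twins(cand, 2, cfg, seed = 950 + 10 * p + sgn)
      d <- if (tw$n_aberrant > 0) Inf else
        morphozoo:::cross_distance(tw$morphs, parent_twins, "cmd")
      expect_gt(d, inst + cfg$cmd_margin)
    }
  }
})

test_that("walk eligibility and reproducibility contracts hold", {
  cfg <- tiny_config(max_steps = 10L, n_twins = 2L, n_walks = 1L,
                     walk_steps = 4L, walk_twins = 2L,
                     noise_amplitude = 0.002,
                     walk_eligibility_emd = 1e-9)
  mech <- dev_mechanism(matrix(0, 10, 10), default_division_rate = 0)
  mech$T[4, 5] <- 0.8
  expect_error(iso_walk(mech, cfg, seed = 3), "not eligible")

  cfg2 <- tiny_config(max_steps = 10L, n_twins = 2L, n_walks = 2L,
                      walk_steps = 5L, walk_twins = 2L,
                      noise_amplitude = 0.002)
  w1 <- iso_walk(mech, cfg2, seed = 5)
  w2 <- iso_walk(mech, cfg2, seed = 5)
  expect_identical(w1$accepted, w2$accepted)
})
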