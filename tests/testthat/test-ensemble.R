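test_that("network sampler honours the interaction probability and constraint", {
  cfg <- sim_config()
  set.seed(2)
  # p = 0: only the enforced activation of a diffusible gene by gene 1
  mech <- sample_network(10, 0, 1, cfg)
  nz <- which(mech$T != 0, arr.ind = TRUE)
  expect_equal(nrow(nz), 1L)
  expect_equal(unname(nz[1, 1]), 1L)
  expect_true(mech$gene_specs$diffusible[nz[1, 2]])
  expect_gt(mech$T[nz], 0)

  # the constraint holds for every draw
  set.seed(3)
  for (i in 1:50) {
    m <- sample_network(10, 0.2, 1, cfg)
    expect_true(any(m$T[1, m$gene_specs$diffusible] > 0))
    expect_true(all(m$gene_specs$diffusion_rate[!m$gene_specs$diffusible] == 0))
  }
})

test_that("mean efferent connectivity is ~2 and diffusibility ~1/2", {
  cfg <- sim_config()
  set.seed(8)
  n_draw <- 3000
  eff <- numeric(n_draw)
  diff_frac <- numeric(n_draw)
  for (i in seq_len(n_draw)) {
    m <- sample_network(10, 0.2, 1, cfg)
    eff[i] <- sum(m$T != 0) / 10
    diff_frac[i] <- mean(m$gene_specs$diffusible)
  }
  # 10 genes x p=0.2 => 2 efferent (and afferent) connections on average;
  # the enforced gene-1 activation adds a small excess
  expect_gt(mean(eff), 2 - 0.1)
  expect_lt(mean(eff), 2 + 0.1)
  p_hat <- mean(diff_frac)
  ci <- 2.58 * sqrt(0.25 / (10 * n_draw))
  expect_gt(p_hat, 0.5 - ci - 0.001)  # +0.001: enforced-diffusibility excess
  expect_lt(p_hat, 0.5 + ci + 0.001)

  # interaction density within 3 binomial standard errors of p
  dens <- mean(eff) / 10
  se <- sqrt(0.2 * 0.8 / (100 * n_draw))
  expect_lt(abs(dens - 0.2), 3 * se + 1 / 100)  # slack for the constraint
})

test_that("behavior coupling sampler: probability, menu uniformity, signs", {
  cfg <- sim_config()
  set.seed(12)
  base <- sample_network(10, 0.2, 1, cfg)
  expect_equal(nrow(attach_behaviors(base, 0, cfg)$couplings), 0L)

  n_draw <- 2000
  counts <- integer(0)
  targets <- character(0)
  for (i in seq_len(n_draw)) {
    m <- attach_behaviors(base, 0.5, cfg)
    counts <- c(counts, nrow(m$couplings))
    targets <- c(targets, m$couplings$target)
  }
  frac <- mean(counts) / 10
  ci <- 2.58 * sqrt(0.25 / (10 * n_draw))
  expect_gt(frac, 0.5 - ci)
  expect_lt(frac, 0.5 + ci)
  # uniform over the behavior menu (chi-square not rejected at alpha=0.01)
  tab <- table(factor(targets, levels = morphozoo:::COUPLING_TARGETS))
  expect_gt(chisq.test(tab)$p.value, 0.01)
  # rate-like couplings are positive (log-uniform); property couplings signed
  m <- attach_behaviors(base, 1, cfg)
  rate <- m$couplings$target %in% morphozoo:::RATE_TARGETS
  expect_true(all(m$couplings$strength[rate] > 0))
})

test_that("signaling screen fails an empty network and passes the cascade", {
  cfg <- tiny_config()
  empty <- dev_mechanism(matrix(0, 10, 10))
  res <- signaling_only_screen(empty, config = cfg, seed = 1)
  expect_false(res$pass)

  cas <- signaling_only_screen(make_fixture("threshold_cascade"),
                               config = cfg, seed = 1)
  expect_true(cas$pass)
  expect_gte(count_expression_territories(cas$trajectory$final, genes = 3:5),
             3L)
})

test_that("a mechanism that never settles fails the stability criterion", {
  cfg <- tiny_config(screen_max_steps = 200L)
  # near-zero degradation: expression keeps accumulating for the whole run
  slow <- dev_mechanism(matrix(0, 10, 10))
  slow$T[1, 2] <- 5
  slow$gene_specs$degradation_rate[2] <- 1e-4
  res <- signaling_only_screen(slow, config = cfg, seed = 1)
  expect_false(res$steady)
  expect_false(res$pass)
})

test_that("ensemble members are replayable and never aberrant", {
  cfg <- tiny_config(noise_amplitude = 0.003, max_steps = 30L,
                     screen_max_steps = 400L)
  e1 <- generate_ensemble(2, cfg, seed = 9, max_attempts = 60)
  e2 <- generate_ensemble(2, cfg, seed = 9, max_attempts = 60)
  expect_gte(nrow(e1), 1)
  expect_identical(e1$member_seed, e2$member_seed)
  expect_identical(e1$morphology[[1]]$nodes, e2$morphology[[1]]$nodes)
  expect_identical(e1$av, e2$av)
  for (i in seq_len(nrow(e1))) {
    expect_false(detect_aberrant(e1$morphology[[i]], cfg)$aberrant)
  }
})
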