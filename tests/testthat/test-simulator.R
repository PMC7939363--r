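inert_mechanism <- function(cfg) {
  mech <- dev_mechanism(matrix(0, cfg$n_genes, cfg$n_genes),
                        default_division_rate = 0)
  mech
}

test_that("an inert mechanism with zero noise leaves the sheet unchanged", {
  cfg <- tiny_config(default_division_rate = 0)
  mech <- inert_mechanism(cfg)
  mech$default_division_rate <- 0
  m0 <- build_initial_morphology(2)
  tr <- run_development(mech, m0, cfg, seed = 1)
  expect_true(tr$termination_reason %in% c("steady", "max_steps"))
  expect_equal(as.matrix(tr$final$nodes[, c("x", "y", "z")]),
               as.matrix(m0$nodes[, c("x", "y", "z")]), tolerance = 1e-10)
  expect_identical(tr$final$nodes$cell_label, m0$nodes$cell_label)
})

test_that("trajectories are bit-identical under the same seed, twins differ", {
  cfg <- tiny_config(noise_amplitude = 0.005)
  mech <- make_fixture("gradient_contraction")
  t1 <- run_development(mech, config = cfg, seed = 7)
  t2 <- run_development(mech, config = cfg, seed = 7)
  expect_identical(t1$final$nodes, t2$final$nodes)
  t3 <- run_development(mech, config = cfg, seed = 8)
  expect_false(identical(t1$final$nodes, t3$final$nodes))
  expect_gt(emd(t1$final, t3$final), 0)
})

test_that("signaling-only runs never move a node", {
  cfg <- tiny_config(noise_amplitude = 0.01)
  mech <- make_fixture("threshold_cascade")
  m0 <- build_initial_morphology(2)
  tr <- run_development(mech, m0, cfg, seed = 3, signaling_only = TRUE)
  expect_identical(as.matrix(tr$final$nodes[, c("x", "y", "z")]),
                   as.matrix(m0$nodes[, c("x", "y", "z")]))
  # but expression was transformed
  expect_gt(max(abs(tr$final$nodes$g2 - m0$nodes$g2)), 0.1)
})

test_that("steady state is detected for settled dynamics", {
  cfg <- tiny_config(default_division_rate = 0, max_steps = 300L)
  tr <- run_development(inert_mechanism(cfg), config = cfg, seed = 1)
  expect_equal(tr$termination_reason, "steady")
  expect_lt(tr$steps, 300L)
})

test_that("aberrance detection distinguishes intact, broken and stretched sheets", {
  cfg <- sim_config()
  m <- build_initial_morphology(2)
  expect_false(detect_aberrant(m, cfg)$aberrant)

  # split: displace half of the cells (whole cylinders) far away
  broken <- m
  right <- broken$nodes$x > 0.1
  broken$nodes$x[right] <- broken$nodes$x[right] + 100
  res <- detect_aberrant(broken, cfg)
  expect_true(res$aberrant)
  expect_equal(res$reason, "broken_epithelium")

  # one apical-basal spring stretched to 10x its rest length
  stretched <- m
  i <- which(stretched$nodes$kind == "epithelial_apical")[1]
  stretched$nodes$z[i] <- stretched$nodes$z[i] + 10
  res <- detect_aberrant(stretched, cfg)
  expect_true(res$aberrant)
  expect_equal(res$reason, "ruptured_spring")
})

test_that("deeply interpenetrating anti-aligned cells are flagged", {
  cfg <- sim_config()
  nd0 <- build_initial_morphology(1)$nodes
  nd0 <- nd0[nd0$kind != "mesenchymal", ]
  # second sheet on top, flipped upside down, apical nodes pushed deep
  # into the first sheet's apical layer
  flip <- nd0
  flip$cell_label <- flip$cell_label + 100L
  flip$id <- flip$id + 1000L
  flip$z <- -flip$z + 1.2  # apical at 0.7, basal at 1.7 (axis points down)
  m <- morphology(dplyr::bind_rows(nd0, flip))
  res <- detect_aberrant(m, cfg)
  expect_true(res$aberrant)
  expect_equal(res$reason, "folded_axes")
})

test_that("behaviors: no couplings and no default division leave only noise", {
  cfg <- tiny_config(noise_amplitude = 0.01)
  mech <- inert_mechanism(cfg)
  m0 <- build_initial_morphology(2)
  set.seed(4)
  m1 <- apply_behaviors(m0, mech, 0.1, cfg)
  expect_identical(m1$nodes$cell_label, m0$nodes$cell_label)
  expect_identical(nrow(m1$nodes), nrow(m0$nodes))
  expect_false(identical(m1$nodes$x, m0$nodes$x))
  expect_lt(max(abs(m1$nodes$x - m0$nodes$x)), 0.1)
})

test_that("division doubles the population on the cell-cycle schedule", {
  # with a pure default division rate r, every cell divides each time its
  # phase reaches 1, i.e. the population doubles every 1/r time units
  cfg <- tiny_config(noise_amplitude = 0.001, max_steps = 200L,
                     max_nodes = 2000L, default_division_rate = 0.2,
                     dt_max = 0.1)
  mech <- dev_mechanism(matrix(0, 10, 10), default_division_rate = 0.2)
  m0 <- build_initial_morphology(1)  # 7 epithelial + 7 mesenchymal cells
  tr <- run_development(mech, m0, cfg, seed = 2)
  n_cells <- length(unique(stats::na.omit(tr$final$nodes$cell_label)))
  doublings <- log2(n_cells / 14)
  expect_gt(doublings, 0)
  expect_equal(doublings, round(doublings))  # synchronized doubling
  # labels stay unique
  ap <- tr$final$nodes$cell_label[tr$final$nodes$kind == "epithelial_apical"]
  expect_false(anyDuplicated(ap) > 0)
})

test_that("apoptosis coupled to a half-sheet gene removes exactly that half", {
  cfg <- tiny_config(noise_amplitude = 0, max_steps = 150L,
                     default_division_rate = 0)
  mech <- dev_mechanism(matrix(0, 10, 10), default_division_rate = 0)
  mech$couplings <- tibble::tibble(gene = 2L, target = "apoptosis",
                                   strength = 1)
  m0 <- build_initial_morphology(2)
  doomed <- m0$nodes$x > 0.1
  m0$nodes$g2[doomed] <- 1
  doomed_labels <- unique(m0$nodes$cell_label[doomed])
  tr <- run_development(mech, m0, cfg, seed = 1)
  survivors <- unique(stats::na.omit(tr$final$nodes$cell_label))
  expect_length(intersect(survivors, doomed_labels), 0)
  expect_setequal(survivors, setdiff(unique(m0$nodes$cell_label),
                                     doomed_labels))
})

test_that("EMT converts epithelial cells and ECM secretion spawns matrix nodes", {
  cfg <- tiny_config(noise_amplitude = 0, max_steps = 60L,
                     default_division_rate = 0)
  mech <- dev_mechanism(matrix(0, 10, 10), default_division_rate = 0)
  mech$couplings <- tibble::tibble(gene = 1L, target = "emt", strength = 3)
  tr <- run_development(mech, build_initial_morphology(2), cfg, seed = 5)
  kinds <- table(tr$final$nodes$kind)
  # the high-gradient cells transition: fewer cylinders, more spheres
  expect_lt(kinds[["epithelial_apical"]], 19)
  expect_gt(kinds[["mesenchymal"]], 19)
  # labels are preserved through the transition
  expect_setequal(unique(stats::na.omit(tr$final$nodes$cell_label)),
                  1:38)

  mech2 <- dev_mechanism(matrix(0, 10, 10), default_division_rate = 0)
  mech2$couplings <- tibble::tibble(gene = 1L, target = "ecm_secretion",
                                    strength = 3)
  tr2 <- run_development(mech2, build_initial_morphology(2), cfg, seed = 5)
  expect_gt(sum(tr2$final$nodes$kind == "ecm"), 0)
  expect_true(all(is.na(
    tr2$final$nodes$cell_label[tr2$final$nodes$kind == "ecm"])))
})

test_that("the node cap terminates runaway growth", {
  cfg <- tiny_config(noise_amplitude = 0.001, max_steps = 500L,
                     max_nodes = 60L, default_division_rate = 0.5,
                     dt_max = 0.1)
  mech <- dev_mechanism(matrix(0, 10, 10), default_division_rate = 0.5)
  tr <- run_development(mech, build_initial_morphology(1), cfg, seed = 3)
  expect_equal(tr$termination_reason, "max_nodes")
  expect_gte(sum(tr$final$nodes$kind != "ecm"), 60)
})
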