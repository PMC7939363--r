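test_that("a large sphere with radial cells has near-zero angle variation", {
  sph <- make_fixture("sphere", params = list(n = 500))
  expect_lt(angle_variation(sph), 0.01)
})

test_that("angle variation is invariant under rigid rotation", {
  m <- build_initial_morphology(4)
  R <- rotation_matrix(c(1, 2, 0.5), 1.1)
  expect_equal(angle_variation(rotate_morphology(m, R)),
               angle_variation(m), tolerance = 1e-10)
  dome <- make_fixture("dome", params = list(n = 120))
  expect_equal(angle_variation(rotate_morphology(dome, R)),
               angle_variation(dome), tolerance = 1e-10)
})

test_that("angle variation grows with crumpling amplitude", {
  avs <- vapply(c(0.05, 0.15, 0.3), function(j) {
    angle_variation(make_fixture("crumpled_plane",
                                 params = list(rings = 4, jitter = j),
                                 seed = 9))
  }, numeric(1))
  expect_true(all(diff(avs) > 0))
})

test_that("orientation patch count: flat sheet is one patch, small patches filtered", {
  m <- build_initial_morphology(3)
  expect_equal(orientation_patch_count(m), 1L)

  flip_cells <- function(m, labels) {
    for (lab in labels) {
      sel <- m$nodes$cell_label == lab & grepl("^epithelial", m$nodes$kind)
      m$nodes$z[sel] <- -m$nodes$z[sel]
    }
    m
  }
  cells <- epithelial_cells(m)
  # a contiguous 3-cell cluster and a distant contiguous 5-cell cluster
  left <- cells$label[order(cells$cx)][1:3]
  right <- cells$label[order(-cells$cx)][1:5]
  m2 <- flip_cells(m, c(left, right))
  # background patch + the 5-cell patch; the 3-cell patch is filtered
  expect_equal(orientation_patch_count(m2), 2L)
  expect_equal(orientation_patch_count(m2, min_patch = 1L), 3L)
})

test_that("orientation patch count matches a brute-force flood fill on a dome", {
  dome <- make_fixture("dome", params = list(n = 150))
  cells <- epithelial_cells(dome)
  n <- nrow(cells)
  # independent octant labels
  v <- cbind(cells$bx - cells$ax, cells$by - cells$ay, cells$bz - cells$az)
  oct <- 1 + (v[, 1] < 0) + 2 * (v[, 2] < 0) + 4 * (v[, 3] < 0)
  # independent contact graph and iterative flood fill
  P <- as.matrix(cells[, c("ax", "ay", "az")])
  B <- as.matrix(cells[, c("bx", "by", "bz")])
  thr <- 2 * cells$p_ADD[1]
  touch <- function(X) as.matrix(dist(X)) < outer(cells$p_ADD, cells$p_ADD, "+")
  adj <- (touch(P) | touch(B)) & outer(oct, oct, "==")
  diag(adj) <- FALSE
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[cur, ] & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  oracle <- sum(table(comp) >= 4)
  expect_equal(orientation_patch_count(dome), oracle)
})

test_that("OPC is translation-invariant but octants are frame-fixed", {
  dome <- make_fixture("dome", params = list(n = 150))
  shifted <- dome
  shifted$nodes$x <- shifted$nodes$x + 17.3
  shifted$nodes$z <- shifted$nodes$z - 4.2
  expect_equal(orientation_patch_count(shifted),
               orientation_patch_count(dome))
  # rotation changes the octant assignment (axes are fixed to the frame)
  R <- rotation_matrix(c(0, 0, 1), pi / 7)
  rot <- rotate_morphology(dome, R)
  cells_a <- epithelial_cells(dome)
  cells_b <- epithelial_cells(rot)
  expect_false(identical(morphozoo:::cell_octants(cells_a),
                         morphozoo:::cell_octants(cells_b)))
  # while AV is unchanged by the same rotation
  expect_equal(angle_variation(rot), angle_variation(dome),
               tolerance = 1e-10)
})

test_that("local convexity is exactly zero on a flat sheet and signed at folds", {
  m <- build_initial_morphology(3)
  lc <- local_convexity(m)
  expect_true(all(lc$convexity == 0))
  expect_true(all(lc$convexity >= -1 & lc$convexity <= 1))

  # a pulled-up apical tip: neighbors lie toward the basal side, so the
  # tip's apical node (v1 pointing to its basal partner) scores positive
  i <- which(m$nodes$kind == "epithelial_apical" &
               abs(m$nodes$x) < 1e-9 & abs(m$nodes$y) < 1e-9)
  ib <- which(m$nodes$kind == "epithelial_basal" &
                abs(m$nodes$x) < 1e-9 & abs(m$nodes$y) < 1e-9)
  m$nodes$z[i] <- m$nodes$z[i] + 0.8
  m$nodes$z[ib] <- m$nodes$z[ib] + 0.8
  lc2 <- local_convexity(m)
  expect_gt(lc2$convexity[lc2$id == m$nodes$id[i]], 0)
})

test_that("sphere convexity matches the closed-form chord geometry", {
  sph <- make_fixture("sphere", params = list(n = 200, radius = 8,
                                              p_add = 1.5))
  lc <- local_convexity(sph)
  ap <- sph$nodes[sph$nodes$kind == "epithelial_apical", ]
  P <- as.matrix(ap[, c("x", "y", "z")])
  Rr <- sqrt(sum(P[1, ]^2))
  # oracle per apical node: v1 = -u (toward basal partner), neighbors at
  # angular distance alpha contribute dot = sin(alpha/2) * (distance
  # geometry of chords on a sphere)
  dmat <- as.matrix(dist(P))
  thr <- outer(ap$p_ADD, ap$p_ADD, "+")
  for (i in c(5, 60, 150)) {
    nb <- which(dmat[i, ] < thr[i, ] & dmat[i, ] > 1e-9)
    u_i <- P[i, ] / Rr
    dots <- vapply(nb, function(j) {
      vk <- P[j, ] - P[i, ]
      vk <- vk / sqrt(sum(vk^2))
      sum(vk * (-u_i))
    }, numeric(1))
    expect_equal(lc$convexity[lc$id == ap$id[i]], mean(dots),
                 tolerance = 1e-10)
    # closed form: dot of -u_i with a unit chord equals sin(alpha/2)
    alphas <- vapply(nb, function(j) {
      acos(max(-1, min(1, sum(P[i, ] * P[j, ]) / Rr^2)))
    }, numeric(1))
    expect_equal(mean(dots), mean(sin(alphas / 2)), tolerance = 1e-10)
  }
})

test_that("convexity distance: identity, rotation invariance, hand value", {
  m <- build_initial_morphology(2)
  expect_equal(cmd(m, m), 0)
  R <- rotation_matrix(c(1, 0, 1), 0.7)
  expect_equal(cmd(m, rotate_morphology(m, R)), 0, tolerance = 1e-10)

  # single raised cell: CMD equals the hand-computed mean |delta l|
  m2 <- m
  sel <- m2$nodes$cell_label == m2$nodes$cell_label[
    which(abs(m2$nodes$x) < 1e-9 & abs(m2$nodes$y) < 1e-9 &
            m2$nodes$kind == "epithelial_apical")] &
    grepl("^epithelial", m2$nodes$kind)
  m2$nodes$z[sel] <- m2$nodes$z[sel] + 0.5
  l1 <- local_convexity(m)
  l2 <- local_convexity(m2)
  key <- paste(l1$cell_label, l1$kind)
  oracle <- mean(abs(l1$convexity - l2$convexity[match(key, paste(
    l2$cell_label, l2$kind))]))
  expect_equal(cmd(m, m2), oracle, tolerance = 1e-12)
  expect_gt(cmd(m, m2), 0)
})

test_that("cmd errors without shared labels", {
  m <- build_initial_morphology(1)
  m2 <- build_initial_morphology(1)
  m2$nodes$cell_label <- m2$nodes$cell_label + 1000L
  m2$initial_labels <- m2$initial_labels + 1000L
  expect_error(cmd(m, m2), "labels")
})

test_that("EMD: identity, symmetry, single-node separation, brute-force match", {
  a <- point_morphology(0)
  b <- point_morphology(3.7)
  expect_equal(emd(a, a), 0)
  expect_equal(emd(a, b), 3.7)
  expect_equal(emd(a, b), emd(b, a))

  set.seed(13)
  A <- matrix(rnorm(150), 50, 3)
  B <- matrix(rnorm(150, 0.5), 50, 3)
  ma <- mesench_cloud(A)
  mb <- mesench_cloud(B)
  # O(n^2) double-loop oracle
  nn <- function(X, Y) {
    vapply(seq_len(nrow(X)), function(i) {
      min(sqrt(colSums((t(Y) - X[i, ])^2)))
    }, numeric(1))
  }
  oracle <- (sum(nn(A, B)) + sum(nn(B, A))) / (nrow(A) + nrow(B))
  expect_equal(emd(ma, mb), oracle, tolerance = 1e-12)
})

test_that("mean morphology averages homologous nodes", {
  m <- build_initial_morphology(2)
  expect_equal(nrow(mean_morphology(list(m))$nodes), nrow(m$nodes))

  up <- m
  up$nodes$z <- up$nodes$z + 1
  down <- m
  down$nodes$z <- down$nodes$z - 1
  mm <- mean_morphology(list(up, down))
  expect_equal(mm$nodes$z, m$nodes$z, tolerance = 1e-12)

  # the mean of noisy twins is closer to the noiseless sheet than the twins
  set.seed(21)
  twins <- lapply(1:10, function(i) {
    t <- m
    n <- nrow(t$nodes)
    t$nodes$x <- t$nodes$x + rnorm(n, 0, 0.1)
    t$nodes$y <- t$nodes$y + rnorm(n, 0, 0.1)
    t$nodes$z <- t$nodes$z + rnorm(n, 0, 0.1)
    t
  })
  mm <- mean_morphology(twins)
  d_mean <- emd(mm, m)
  d_each <- vapply(twins, function(t) emd(t, m), numeric(1))
  expect_lt(d_mean, min(d_each))
})

test_that("HMD: identity, translation closed form, rotation removed by alignment", {
  m <- build_initial_morphology(2)
  expect_equal(hmd(m, m), 0)
  shifted <- m
  shifted$nodes$x <- shifted$nodes$x + 2
  shifted$nodes$z <- shifted$nodes$z + 1
  n_hom <- sum(grepl("^epithelial", m$nodes$kind))
  expect_equal(hmd(m, shifted, align = FALSE),
               sqrt(n_hom) * sqrt(2^2 + 1^2), tolerance = 1e-10)
  expect_equal(hmd(m, shifted, align = TRUE), 0, tolerance = 1e-8)
  rot <- rotate_morphology(m, rotation_matrix(c(1, 1, 1), 0.9))
  expect_equal(hmd(m, rot, align = TRUE), 0, tolerance = 1e-8)
  expect_gt(hmd(m, rot, align = FALSE), 0.1)
})

test_that("distances are deterministic and non-negative on simulated twins", {
  cfg <- tiny_config(noise_amplitude = 0.005, max_steps = 20L)
  tw <- simulate_twins(make_fixture("gradient_contraction"), 2, cfg, seed = 5)
  a <- tw$morphs[[1]]
  b <- tw$morphs[[2]]
  for (f in list(emd, cmd, hmd)) {
    expect_gte(f(a, b), 0)
    expect_equal(f(a, b), f(a, b))
  }
})
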