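# fabricate an IS record set whose morphological distances are exactly
# linear in the genetic distance: member at magnitude m has separation
# base + slope * m / 100 (base large enough that nearest-neighbor
# matching stays apical-to-apical)
planted_records <- function(slope, base = 4) {
  mags <- c(-80, -60, -40, -20, 20, 40, 60, 80)
  rows <- lapply(mags, function(m) {
    tibble::tibble(
      param = 1L, kind = "IS", magnitude = m,
      mechanism = list(NULL),
      twins = list(list(epithelial_pair(base + slope * m / 100))),
      n_aberrant = 0L)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mutation_records", class(out))
  out
}

test_that("gpm regression recovers a planted slope to machine precision", {
  slope <- 0.37
  rec <- planted_records(slope)
  parent_twins <- list(epithelial_pair(4))
  # EMD between members a,b is |d_a - d_b| / 2, so the OLS slope on the
  # percent scale is slope / 200 exactly
  reg <- gpm_regression(parent_twins, rec, "emd")
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$beta, slope / 200, tolerance = 1e-12)
  expect_equal(reg$intercept, 0, tolerance = 1e-10)
  # HMD after centering: |d_a - d_b| / sqrt(2)
  regh <- gpm_regression(parent_twins, rec, "hmd")
  expect_equal(regh$beta, slope / (100 * sqrt(2)), tolerance = 1e-10)
})

test_that("identical morphologies give beta = 0 and flat distances stay flat", {
  rec <- planted_records(0)
  reg <- gpm_regression(list(epithelial_pair(4)), rec, "emd")
  expect_equal(reg$beta, 0, tolerance = 1e-12)

  # large instability but no genetic trend: beta ~ 0 despite big intercept
  set.seed(3)
  mags <- c(-80, -60, -40, -20, 20, 40, 60, 80)
  rows <- lapply(mags, function(m) {
    tibble::tibble(
      param = 1L, kind = "IS", magnitude = m, mechanism = list(NULL),
      twins = list(lapply(1:4, function(i) {
        point_morphology(rnorm(1, 0, 2))
      })),
      n_aberrant = 0L)
  })
  rec2 <- dplyr::bind_rows(rows)
  class(rec2) <- c("mutation_records", class(rec2))
  parent_twins <- lapply(1:4, function(i) point_morphology(rnorm(1, 0, 2)))
  reg2 <- gpm_regression(parent_twins, rec2, "emd")
  expect_gt(reg2$intercept, 0.5)
  expect_lt(abs(reg2$beta), reg2$intercept)
})

test_that("uniform rescaling of morphological distances rescales beta exactly", {
  rec1 <- planted_records(0.2)
  rec3 <- planted_records(0.6)  # all separations (hence all y) scaled by 3
  b1 <- gpm_regression(list(epithelial_pair(4)), rec1, "emd")$beta
  b3 <- gpm_regression(list(epithelial_pair(4)), rec3, "emd")$beta
  expect_equal(b3, 3 * b1, tolerance = 1e-12)
})

test_that("the genetic-distance design matches the screen geometry", {
  rec <- planted_records(0.3)
  reg <- gpm_regression(list(epithelial_pair(4)), rec, "emd")
  pts <- reg$points[[1]]
  # 9 members (8 mutants + parent): choose(9,2) = 36 cross pairs; single
  # twins contribute no 0% points
  expect_equal(nrow(pts), 36L)
  expect_setequal(unique(pts$genetic),
                  c(20, 40, 60, 80, 100, 120, 140, 160))
  # HMD design has no 0% level either way
  regh <- gpm_regression(list(epithelial_pair(4)), rec, "hmd")
  expect_true(all(regh$points[[1]]$genetic > 0))
})

test_that("asymmetry histogram matches a hand computation and normalizes", {
  parents <- c(0.10, 0.10, 0.10, 0.40, 0.40, 0.40)
  offspring <- c(0.10, 0.13, 0.16, 0.10, 0.40, 0.43)
  h <- asymmetry_histogram(parents, offspring, "av", bin = 0.03)
  # column at parent bin 0.09 (0.10 falls in [0.09, 0.12)): deltas 0, .03, .06
  col1 <- h[abs(h$parent_bin - 0.09) < 1e-9, ]
  expect_equal(nrow(col1), 3L)
  expect_true(all(abs(col1$rel_abundance - 1 / 3) < 1e-12))
  # column at 0.39: deltas -0.30, 0, +0.03
  col2 <- h[abs(h$parent_bin - 0.39) < 1e-9, ]
  expect_equal(sort(col2$delta_bin), c(-0.30, 0, 0.03), tolerance = 1e-9)
  # per-column relative abundances sum to one before the log
  sums <- tapply(h$rel_abundance, h$parent_bin, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_equal(h$log_rel_abundance, log(h$rel_abundance))
  # empty cells are absent, not -Inf
  expect_false(any(is.infinite(h$log_rel_abundance)))
})

test_that("frequency spectrum counts every member once", {
  s1 <- frequency_spectrum(0.05, "av")
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$count, 1L)
  set.seed(8)
  x <- rexp(200, 10)
  sp <- frequency_spectrum(x, "av")
  expect_equal(sum(sp$count), 200L)
  expect_equal(sum(sp$frequency), 1)
  spo <- frequency_spectrum(c(1, 1, 2, 5), "opc")
  expect_equal(sum(spo$count), 4L)
})

test_that("degeneracy heatmap is symmetric with zero diagonal for clones", {
  m <- build_initial_morphology(2)
  jitter_m <- function(seed) {
    set.seed(seed)
    t <- m
    t$nodes$z <- t$nodes$z + rnorm(nrow(t$nodes), 0, 0.2)
    t
  }
  ens <- tibble::tibble(
    member = 1:12,
    morphology = c(replicate(6, m, simplify = FALSE),
                   lapply(7:12, jitter_m)),
    av = c(rep(0.05, 6), rep(0.25, 6)))
  deg <- degeneracy_heatmap(ens, "av", breaks = c(0, 0.1, 0.2, 0.3),
                            n_per = 6, seed = 2)
  M <- deg$matrix
  expect_equal(M, t(M))
  expect_equal(M[1, 1], 0)          # identical morphologies
  expect_gt(M[3, 3], 0)             # jittered ones differ
  expect_true(all(is.na(M[2, ])))   # empty interval marked missing
  expect_gt(M[1, 3], 0)
})
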