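# tiny, fast configurations used across the unit tests
tiny_config <- function(...) {
  base <- list(sheet_rings = 2L, n_genes = 10L, max_steps = 40L,
               max_nodes = 200L, dt_max = 0.15, rk_tolerance = 2e-3,
               noise_amplitude = 0)
  do.call(sim_config, utils::modifyList(base, list(...)))
}

# a bare morphology of spherical (mesenchymal) nodes at given positions
mesench_cloud <- function(P, p_add = 0.65, p_eqd = 0.5, n_genes = 2L) {
  n <- nrow(P)
  nd <- tibble::tibble(
    id = seq_len(n), cell_label = seq_len(n), kind = "mesenchymal",
    x = P[, 1], y = P[, 2], z = P[, 3],
    p_ADD = p_add, p_EQD = p_eqd, p_EQS = 0.5, p_ERP = 1, p_EST = 0.5,
    p_PHA = 0)
  for (g in seq_len(n_genes)) nd[[paste0("g", g)]] <- 0
  morphology(nd)
}

# rigid rotation of a morphology about the origin
rotate_morphology <- function(m, R) {
  P <- as.matrix(m$nodes[, c("x", "y", "z")]) %*% t(R)
  m$nodes$x <- P[, 1]
  m$nodes$y <- P[, 2]
  m$nodes$z <- P[, 3]
  m
}

rotation_matrix <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
}

# single-node morphology at a position (used to plant exact distances)
point_morphology <- function(x, label = 1L) {
  mesench_cloud(matrix(c(x, 0, 0), 1), n_genes = 2L)
}

# a single epithelial cell whose apical-basal separation is d: member
# distances become exact closed forms of |d_a - d_b|
epithelial_pair <- function(d) {
  nd <- build_initial_morphology(1)$nodes
  nd <- nd[nd$cell_label == 1 & nd$kind != "mesenchymal", ]
  nd$x <- 0
  nd$y <- 0
  nd$z <- ifelse(nd$kind == "epithelial_apical", d, 0)
  morphology(nd)
}

# network-only mechanism with k superfluous interactions among genes that
# are never expressed
with_superfluous <- function(mech, edges) {
  for (e in edges) mech$T[e[1], e[2]] <- e[3]
  mech
}
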