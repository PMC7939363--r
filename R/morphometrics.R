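# pairwise squared distances between rows of A and rows of B
cross_dist2 <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  d2
}

#' Angle-variation (AV) complexity of an epithelium
#'
#' Complexity based on the variance of inter-cell angles: for each
#' epithelial cell `i`, the angle between its apical-basal vector and the
#' vector from the basal node of every other cell `j` to the apical node of
#' cell `i` is computed; cell pairs are grouped into seven distance
#' categories `D_c = [c * pADD', (c+1) * pADD')`, `c = 3..9`, where `pADD'`
#' is the average adhesion distance of all epithelial cells (a measure of
#' mean cell size).  The per-cell, per-category population variances
#' `V_ic` of these angles are summed and normalized:
#' `AV = sum_i sum_c V_ic / (7n)`.  Categories with fewer than two pairs
#' contribute zero.  A flat sheet or a perfect sphere scores (near) zero;
#' irregularly folded epithelia score high.  AV is invariant under rigid
#' motions of the morphology.
#'
#' @param m A `morphology` with at least 2 epithelial cells.
#' @param reference Reference points for the inter-cell distance
#'   categories: cell centers (midpoint of apical and basal node, the
#'   default symmetric choice) or apical nodes.
#' @return Non-negative scalar (squared radians).
#' @export
angle_variation <- function(m, reference = c("center", "apical")) {
  reference <- match.arg(reference)
  cells <- epithelial_cells(m)
  n <- nrow(cells)
  if (n < 2) abort("angle_variation needs at least 2 epithelial cells")
  A <- as.matrix(cells[, c("ax", "ay", "az")])
  B <- as.matrix(cells[, c("bx", "by", "bz")])
  Cc <- if (reference == "center") {
    as.matrix(cells[, c("cx", "cy", "cz")])
  } else A
  U <- as.matrix(cells[, c("ux", "uy", "uz")])
  p_add_bar <- 2 * mean(cells$p_ADD)

  # v_ij = apical_i - basal_j ; cos angle_ij = u_i . v_ij / |v_ij|
  dotv <- matrix(rowSums(U * A), n, n) - U %*% t(B)
  vnorm <- sqrt(cross_dist2(A, B))
  cosang <- dotv / vnorm
  cosang[vnorm < 1e-12] <- NA
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  ang <- acos(cosang)
  diag(ang) <- NA

  cdist <- sqrt(cross_dist2(Cc, Cc))
  total <- 0
  for (cat in 3:9) {
    mask <- !is.na(ang) & cdist >= cat * p_add_bar &
      cdist < (cat + 1) * p_add_bar
    k <- rowSums(mask)
    a0 <- ifelse(is.na(ang), 0, ang)
    s <- rowSums(a0 * mask)
    ss <- rowSums(a0^2 * mask)
    ok <- k >= 2
    v <- numeric(n)
    v[ok] <- pmax(ss[ok] / k[ok] - (s[ok] / k[ok])^2, 0)
    total <- total + sum(v)
  }
  total / (7 * n)
}

# octant (1..8) of each epithelial cell from the signs of its
# apical-to-basal vector; a zero component counts as positive
cell_octants <- function(cells) {
  vx <- cells$bx - cells$ax
  vy <- cells$by - cells$ay
  vz <- cells$bz - cells$az
  1L + (vx < 0) + 2L * (vy < 0) + 4L * (vz < 0)
}

#' Orientation patch count (OPC) complexity
#'
#' Each epithelial cell is assigned to one of eight octants by the signs of
#' the components of its apical-to-basal vector (a zero component counts as
#' positive).  Patches are connected components, on the epithelial contact
#' graph, of cells sharing an octant; patches with fewer than `min_patch`
#' cells are not counted.  OPC is frame-dependent by construction (octants
#' are fixed to the coordinate axes): it is invariant under translation but
#' not under rotation.
#'
#' @param m A `morphology` with at least 1 epithelial cell.
#' @param min_patch Minimum patch size counted (default 4).
#' @return Non-negative integer patch count.
#' @export
orientation_patch_count <- function(m, min_patch = 4L) {
  cells <- epithelial_cells(m)
  n <- nrow(cells)
  if (n == 0) abort("orientation_patch_count needs epithelial cells")
  oct <- cell_octants(cells)
  adj <- cell_contact_pairs(m)
  adj <- adj[oct[adj$i] == oct[adj$j], ]
  g <- igraph::graph_from_data_frame(
    data.frame(from = adj$i, to = adj$j), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)
  sum(comp$csize >= min_patch)
}

#' Complexity scores of a morphology
#'
#' @param m A `morphology`.
#' @return Tibble with columns `av` and `opc`.
#' @export
complexity_scores <- function(m) {
  tibble::tibble(av = angle_variation(m), opc = orientation_patch_count(m))
}

#' Local convexity of epithelial nodes
#'
#' For each epithelial node, `v1` is the unit vector from the node to the
#' other node of the same cell, and `v_k` are the unit vectors to its
#' contacting in-plane neighbors of the same type (apical or basal).  The
#' local convexity is the mean of the dot products `v1 . v_k`: close to 0
#' when the neighborhood is planar, and approaching +/-1 at sharp folds of
#' the epithelium (viewed from the apical surface, an evagination is
#' positive at its apical nodes).  The value is invariant under rigid
#' motions.  Nodes without same-type neighbors get `NA` and are excluded
#' from the convexity distance.
#'
#' @param m A `morphology`.
#' @return Tibble with columns `id`, `cell_label`, `kind`, `convexity`
#'   (one row per epithelial node, values in `[-1, 1]`).
#' @export
local_convexity <- function(m) {
  nd <- m$nodes
  out <- list()
  for (side in c("epithelial_apical", "epithelial_basal")) {
    sub <- nd[nd$kind == side, ]
    if (!nrow(sub)) next
    other_kind <- if (side == "epithelial_apical") "epithelial_basal" else
      "epithelial_apical"
    oth <- nd[nd$kind == other_kind, ]
    oth <- oth[match(sub$cell_label, oth$cell_label), ]
    P <- as.matrix(sub[, c("x", "y", "z")])
    Q <- as.matrix(oth[, c("x", "y", "z")])
    v1 <- Q - P
    l1 <- sqrt(rowSums(v1^2))
    if (any(l1 < 1e-12)) abort("degenerate apical-basal vector")
    v1 <- v1 / l1
    dmat <- as.matrix(stats::dist(P))
    thr <- outer(sub$p_ADD, sub$p_ADD, "+")
    contact <- dmat < thr & dmat > 1e-12
    conv <- rep(NA_real_, nrow(sub))
    for (i in seq_len(nrow(sub))) {
      nb <- which(contact[i, ])
      if (!length(nb)) next
      vk <- P[nb, , drop = FALSE] -
        matrix(P[i, ], length(nb), 3, byrow = TRUE)
      vk <- vk / sqrt(rowSums(vk^2))
      conv[i] <- mean(vk %*% v1[i, ])
    }
    out[[side]] <- tibble::tibble(id = sub$id, cell_label = sub$cell_label,
                                  kind = side, convexity = conv)
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$id)
}

# homologous epithelial node pairs between two morphologies: same lineage
# label and same node type, restricted to the shared initial label set
homologous_pairs <- function(m1, m2, epithelial_only = TRUE) {
  shared <- intersect(m1$initial_labels, m2$initial_labels)
  if (!length(shared)) abort("morphologies share no initial labels")
  pick <- function(m) {
    nd <- m$nodes[!is.na(m$nodes$cell_label) &
                    m$nodes$cell_label %in% shared, ]
    if (epithelial_only) nd <- nd[grepl("^epithelial", nd$kind), ]
    nd <- nd[nd$kind != "ecm", ]
    nd$key <- paste(nd$cell_label, nd$kind)
    nd
  }
  n1 <- pick(m1)
  n2 <- pick(m2)
  keys <- intersect(n1$key, n2$key)
  if (!length(keys)) abort("no homologous nodes between morphologies")
  list(a = n1[match(keys, n1$key), ], b = n2[match(keys, n2$key), ])
}

#' Convexity morphological distance (CMD)
#'
#' Mean absolute difference in [local_convexity()] over the homologous
#' epithelial nodes (same lineage label and node type) shared by the two
#' morphologies.  The normalizer is the number of homologous nodes with a
#' defined convexity in both morphologies.  Values lie in `[0, 2]`.
#'
#' @param m1,m2 Morphologies sharing initial labels.
#' @return Non-negative scalar.
#' @export
cmd <- function(m1, m2) {
  hp <- homologous_pairs(m1, m2, epithelial_only = TRUE)
  c1 <- local_convexity(m1)
  c2 <- local_convexity(m2)
  l1 <- c1$convexity[match(paste(hp$a$cell_label, hp$a$kind),
                           paste(c1$cell_label, c1$kind))]
  l2 <- c2$convexity[match(paste(hp$b$cell_label, hp$b$kind),
                           paste(c2$cell_label, c2$kind))]
  ok <- !is.na(l1) & !is.na(l2)
  if (!any(ok)) abort("no homologous nodes with defined convexity")
  mean(abs(l1[ok] - l2[ok]))
}

#' Euclidean minimal distance (EMD) between morphologies
#'
#' Homology-free distance between two node clouds: the sum over every node
#' of its Euclidean distance to the closest node of the other morphology,
#' in both directions, divided by the total node count `n1 + n2`.
#' Symmetric and zero on identical clouds; it works across unequal node
#' counts.  Not guaranteed to satisfy the triangle inequality.
#'
#' @param m1,m2 Morphologies (non-empty).
#' @param include `"cells"` (default: epithelial and mesenchymal nodes) or
#'   `"all"` (adds ECM nodes).
#' @return Non-negative scalar (model length units).
#' @export
emd <- function(m1, m2, include = c("cells", "all")) {
  include <- match.arg(include)
  pts <- function(m) {
    nd <- m$nodes
    if (include == "cells") nd <- nd[nd$kind != "ecm", ]
    as.matrix(nd[, c("x", "y", "z")])
  }
  A <- pts(m1)
  B <- pts(m2)
  if (!nrow(A) || !nrow(B)) abort("emd needs non-empty morphologies")
  cpp_emd(A, B)
}

#' Mean morphology of a set of twins
#'
#' Averages the positions of homologous nodes (same lineage label and node
#' type) across twin simulations of one mechanism, restricted to the
#' homologous set present in every twin.  Reduces the imprint of
#' developmental noise before homologous distance comparisons.
#'
#' @param twins List of morphologies sharing initial labels.
#' @return A `morphology` on the shared homologous node set.
#' @export
mean_morphology <- function(twins) {
  stopifnot(length(twins) >= 1)
  keyed <- lapply(twins, function(m) {
    nd <- m$nodes[!is.na(m$nodes$cell_label) & m$nodes$kind != "ecm" &
                    m$nodes$cell_label %in% m$initial_labels, ]
    nd$key <- paste(nd$cell_label, nd$kind)
    nd
  })
  keys <- Reduce(intersect, lapply(keyed, function(x) x$key))
  if (!length(keys)) abort("twins share no homologous nodes")
  base <- keyed[[1]][match(keys, keyed[[1]]$key), ]
  for (ax in c("x", "y", "z")) {
    base[[ax]] <- rowMeans(vapply(keyed, function(nd) {
      nd[[ax]][match(keys, nd$key)]
    }, numeric(length(keys))))
  }
  base$key <- NULL
  morphology(base,
             initial_labels = Reduce(intersect,
                                     lapply(twins, function(m) m$initial_labels)),
             time = twins[[1]]$time)
}

#' Homologous morphological distance (HMD)
#'
#' Procrustes-style distance over homologous nodes: after optional
#' superimposition (centroid translation plus optimal rotation, no
#' scaling), the square root of the sum of squared positional differences
#' between each pair of homologous nodes.  Typically applied to mean
#' morphologies of twin sets.
#'
#' @param m1,m2 Morphologies sharing initial labels.
#' @param align Superimpose before measuring (default `TRUE`).
#' @param epithelial_only Restrict to epithelial nodes (default `TRUE`, the
#'   homology set used throughout).
#' @return Non-negative scalar (model length units).
#' @export
hmd <- function(m1, m2, align = TRUE, epithelial_only = TRUE) {
  hp <- homologous_pairs(m1, m2, epithelial_only = epithelial_only)
  X <- as.matrix(hp$a[, c("x", "y", "z")])
  Y <- as.matrix(hp$b[, c("x", "y", "z")])
  if (align) {
    X <- scale(X, scale = FALSE)
    Y <- scale(Y, scale = FALSE)
    s <- svd(t(X) %*% Y)
    R <- s$v %*% t(s$u)
    if (det(R) < 0) {
      s$v[, 3] <- -s$v[, 3]
      R <- s$v %*% t(s$u)
    }
    Y <- Y %*% R
  }
  sqrt(sum((X - Y)^2))
}

#' Count stable expression territories
#'
#' Assigns each epithelial cell the dominant gene (largest expression among
#' `genes`, or none if all are below `threshold`, averaging the cell's
#' nodes) and counts the connected components of same-assignment cells on
#' the epithelial contact graph, ignoring components smaller than
#' `min_cells`.
#'
#' @param m A `morphology`.
#' @param genes Gene indices considered (default: all but the gradient
#'   gene, assumed to be gene 1).
#' @param threshold Expression level below which a cell counts as
#'   unpatterned.
#' @param min_cells Smallest component counted as a territory.
#' @return Integer number of territories.
#' @export
count_expression_territories <- function(m, genes = NULL, threshold = 0.05,
                                         min_cells = 2L) {
  G <- n_genes_of(m)
  if (is.null(genes)) genes <- setdiff(seq_len(G), 1L)
  cells <- epithelial_cells(m)
  nd <- m$nodes
  expr <- vapply(gene_cols(G)[genes], function(col) {
    tapply(nd[[col]][grepl("^epithelial", nd$kind)],
           nd$cell_label[grepl("^epithelial", nd$kind)], mean)
  }, numeric(nrow(cells)))
  expr <- matrix(expr, nrow = nrow(cells))
  expr <- expr[match(cells$label, sort(unique(cells$label))), , drop = FALSE]
  dom <- apply(expr, 1, function(v) {
    if (max(v) < threshold) 0L else which.max(v)
  })
  adj <- cell_contact_pairs(m)
  adj <- adj[dom[adj$i] == dom[adj$j], ]
  g <- igraph::graph_from_data_frame(
    data.frame(from = adj$i, to = adj$j), directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(cells))))
  comp <- igraph::components(g)
  sum(comp$csize >= min_cells)
}
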