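#' Quiescent default mechanical properties
#'
#' Default per-node mechanical parameters used for every node of the initial
#' morphology.  They are chosen so that the initial flat sheet is a mechanical
#' equilibrium: lateral neighbors sit exactly at their summed equilibrium
#' radius (`2 * p_EQD = 1` lattice unit), apical-basal springs are at rest
#' (`2 * p_EQS = 1`), and the bending terms vanish on a flat sheet.  Without
#' gene regulation of behaviors, no morphological change occurs.
#'
#' @return Named numeric vector with elements `p_ADD`, `p_EQD`, `p_EQS`,
#'   `p_ERP`, `p_EST`, `p_PHA` (model length units; `p_PHA` is a rate).
#' @export
default_node_props <- function() {
  c(p_ADD = 0.65, p_EQD = 0.5, p_EQS = 0.5, p_ERP = 1.0, p_EST = 0.5, p_PHA = 0)
}

gene_cols <- function(n_genes) paste0("g", seq_len(n_genes))

#' Construct a morphology from a node table
#'
#' A morphology is a labelled set of nodes in 3D: epithelial cells are
#' apical+basal node pairs (cylinders), mesenchymal cells and extracellular
#' matrix (ECM) are single spherical nodes.  Each node carries mechanical
#' properties and a gene-expression vector.
#'
#' @param nodes Tibble with columns `id`, `cell_label`, `kind` (one of
#'   `"epithelial_apical"`, `"epithelial_basal"`, `"mesenchymal"`, `"ecm"`),
#'   `x`, `y`, `z`, the mechanical columns `p_ADD`, `p_EQD`, `p_EQS`,
#'   `p_ERP`, `p_EST`, `p_PHA`, and expression columns `g1..gN`.
#' @param initial_labels Integer vector of cell labels present at time 0
#'   (the homology reference set).  Defaults to the labels in `nodes`.
#' @param time Developmental time of the snapshot.
#' @return An object of class `morphology`.
#' @export
morphology <- function(nodes, initial_labels = NULL, time = 0) {
  nodes <- tibble::as_tibble(nodes)
  stopifnot(all(c("id", "cell_label", "kind", "x", "y", "z", PROP_COLS) %in%
                  names(nodes)))
  if (!all(nodes$kind %in% NODE_KINDS)) {
    abort("unknown node kind in morphology node table")
  }
  bad <- nodes$p_ADD < nodes$p_EQD | nodes$p_EQD <= 0
  if (any(bad)) abort("node invariant violated: need p_ADD >= p_EQD > 0")
  cell_lab <- c(nodes$cell_label[nodes$kind == "epithelial_apical"],
                nodes$cell_label[nodes$kind == "mesenchymal"])
  if (anyDuplicated(cell_lab)) abort("cell labels must be unique")
  ap_lab <- nodes$cell_label[nodes$kind == "epithelial_apical"]
  ba_lab <- nodes$cell_label[nodes$kind == "epithelial_basal"]
  if (!setequal(ap_lab, ba_lab) || length(ap_lab) != length(ba_lab)) {
    abort("every epithelial cell needs exactly one apical and one basal node")
  }
  lab <- nodes$cell_label[nodes$kind != "ecm"]
  if (is.null(initial_labels)) initial_labels <- sort(unique(lab))
  structure(
    list(nodes = nodes, initial_labels = as.integer(initial_labels),
         time = time),
    class = "morphology"
  )
}

#' @export
print.morphology <- function(x, ...) {
  n_epi <- sum(x$nodes$kind == "epithelial_apical")
  n_mes <- sum(x$nodes$kind == "mesenchymal")
  n_ecm <- sum(x$nodes$kind == "ecm")
  cat(sprintf(
    "<morphology> %d nodes (%d epithelial cells, %d mesenchymal, %d ECM), %d genes, t = %.3g\n",
    nrow(x$nodes), n_epi, n_mes, n_ecm, n_genes_of(x), x$time))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @method as_tibble morphology
#' @export
as_tibble.morphology <- function(x, ...) x$nodes

#' Tidy a morphology into its node table
#'
#' @param x A `morphology`.
#' @param ... Unused.
#' @return The node tibble (one row per node).
#' @export
tidy.morphology <- function(x, ...) x$nodes

n_genes_of <- function(m) {
  nodes <- if (inherits(m, "morphology")) m$nodes else m
  sum(grepl("^g[0-9]+$", names(nodes)))
}

#' Number of centered-hexagonal cells for a ring count
#'
#' @param rings Hexagonal ring count (radius); `rings = 1` gives 7 cells.
#' @return Integer cell count `3*rings*(rings+1) + 1`.
#' @export
hex_cell_count <- function(rings) as.integer(3 * rings * (rings + 1) + 1)

hex_lattice <- function(rings, spacing = 1) {
  qr <- expand.grid(q = -rings:rings, r = -rings:rings)
  qr <- qr[abs(qr$q + qr$r) <= rings, , drop = FALSE]
  x <- spacing * (qr$q + qr$r / 2)
  y <- spacing * (sqrt(3) / 2) * qr$r
  ord <- order(round(x, 9), round(y, 9))
  cbind(x = x[ord], y = y[ord])
}

#' Build the initial flat hexagonal sheet
#'
#' Constructs the standard initial condition of every simulation: a flat,
#' centered-hexagonal sheet of epithelial cells (one apical node above one
#' basal node per cell, all apical-basal axes parallel to +z) with an
#' equal-count layer of mesenchymal cells one cell diameter beneath the basal
#' surface.  One gene (the gradient gene) is initialized as a linear
#' expression gradient across the sheet plane (0 to 1 along x); all other
#' expression is zero.  All mechanical parameters take their quiescent
#' defaults, so the sheet does not move unless a mechanism regulates it.
#'
#' @param sheet_rings Hexagonal ring count; the sheet has
#'   `3*sheet_rings*(sheet_rings+1)+1` epithelial cells (`sheet_rings = 9`
#'   gives 271 cells = 542 epithelial nodes).
#' @param gradient_gene Index of the gene carrying the initial gradient.
#' @param n_genes Number of genes in the expression vector.
#' @return A `morphology`: epithelial cell labels `1..n`, mesenchymal labels
#'   `n+1..2n`, apical nodes at z = +0.5, basal at z = -0.5, mesenchyme at
#'   z = -1.5.
#' @examples
#' m <- build_initial_morphology(1)
#' nrow(m$nodes)  # 7 cells * 2 nodes + 7 mesenchymal = 21
#' @export
build_initial_morphology <- function(sheet_rings, gradient_gene = 1L,
                                     n_genes = 10L) {
  stopifnot(sheet_rings >= 1, gradient_gene >= 1, gradient_gene <= n_genes)
  xy <- hex_lattice(sheet_rings, spacing = 1)
  n <- nrow(xy)
  props <- default_node_props()
  grad <- if (diff(range(xy[, "x"])) > 0) {
    (xy[, "x"] - min(xy[, "x"])) / diff(range(xy[, "x"]))
  } else rep(0, n)

  mk <- function(kind, z, label, id0) {
    tb <- tibble::tibble(
      id = id0 + seq_len(n), cell_label = label, kind = kind,
      x = xy[, "x"], y = xy[, "y"], z = z)
    for (p in PROP_COLS) tb[[p]] <- props[[p]]
    tb
  }
  nodes <- dplyr::bind_rows(
    mk("epithelial_apical", 0.5, seq_len(n), 0L),
    mk("epithelial_basal", -0.5, seq_len(n), n),
    mk("mesenchymal", -1.5, n + seq_len(n), 2L * n)
  )
  gmat <- matrix(0, nrow(nodes), n_genes)
  gmat[, gradient_gene] <- rep(grad, 3)
  colnames(gmat) <- gene_cols(n_genes)
  nodes <- dplyr::bind_cols(nodes, tibble::as_tibble(gmat))
  morphology(nodes, initial_labels = seq_len(2L * n), time = 0)
}

#' Assign lineage labels to the daughters of a dividing cell
#'
#' On division one daughter keeps the mother's lineage label while the other
#' receives a fresh label; which daughter keeps it is decided uniformly at
#' random.  Uses the current R random number stream.
#'
#' @param mother_label Lineage label of the mother cell.
#' @param next_label Next unused label.
#' @return List with `first` and `second` daughter labels and `next_label`,
#'   the updated fresh-label counter.
#' @export
assign_division_labels <- function(mother_label, next_label) {
  keep_first <- runif(1) < 0.5
  if (keep_first) {
    list(first = mother_label, second = next_label,
         next_label = next_label + 1L)
  } else {
    list(first = next_label, second = mother_label,
         next_label = next_label + 1L)
  }
}

#' Per-cell summary of an epithelial morphology
#'
#' @param m A `morphology`.
#' @return Tibble with one row per epithelial cell: label, apical and basal
#'   node positions, cell center, and the basal-to-apical unit axis.
#' @export
epithelial_cells <- function(m) {
  nd <- m$nodes
  ap <- nd[nd$kind == "epithelial_apical", ]
  ba <- nd[nd$kind == "epithelial_basal", ]
  ba <- ba[match(ap$cell_label, ba$cell_label), ]
  axis <- cbind(ap$x - ba$x, ap$y - ba$y, ap$z - ba$z)
  len <- sqrt(rowSums(axis^2))
  if (any(len < 1e-12)) abort("degenerate apical-basal axis (zero length)")
  tibble::tibble(
    label = ap$cell_label,
    ax = ap$x, ay = ap$y, az = ap$z,
    bx = ba$x, by = ba$y, bz = ba$z,
    cx = (ap$x + ba$x) / 2, cy = (ap$y + ba$y) / 2, cz = (ap$z + ba$z) / 2,
    ux = axis[, 1] / len, uy = axis[, 2] / len, uz = axis[, 3] / len,
    p_ADD = (ap$p_ADD + ba$p_ADD) / 2
  )
}

#' Write / read a morphology node table
#'
#' Plain-CSV serialization of the node table (`id`, `cell_label`, `kind`,
#' coordinates, mechanical properties, `g1..gN`).  The node table round-trips
#' exactly at full double precision.
#'
#' @param m A `morphology`.
#' @param path File path.
#' @return `read_morphology` returns a `morphology`; lineage bookkeeping
#'   (`initial_labels`) can be supplied if the table is not an initial state.
#' @export
write_morphology <- function(m, path) {
  df <- as.data.frame(m$nodes)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_morphology
#' @param initial_labels Optional homology label set (defaults to the labels
#'   present in the file).
#' @param time Developmental time to stamp on the object.
#' @export
read_morphology <- function(path, initial_labels = NULL, time = 0) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$id <- as.integer(df$id)
  df$cell_label <- as.integer(df$cell_label)
  morphology(tibble::as_tibble(df), initial_labels = initial_labels,
             time = time)
}

# --- internal flat-state representation used by the integrator ------------

# kinds as integers for the compiled core
KIND_CODE <- c(epithelial_apical = 1L, epithelial_basal = 2L,
               mesenchymal = 3L, ecm = 4L)

morph_to_state <- function(m) {
  nd <- m$nodes
  G <- n_genes_of(m)
  kind <- unname(KIND_CODE[nd$kind])
  # partner index (row) of the other node of the same epithelial cell
  partner <- integer(nrow(nd))
  epi <- kind <= 2L
  key <- paste(nd$cell_label, ifelse(kind == 1L, 2L, 1L))
  own <- paste(nd$cell_label, kind)
  partner[epi] <- match(key[epi], own)
  partner[!epi] <- 0L
  list(
    P = unname(as.matrix(nd[, c("x", "y", "z")])),
    E = unname(as.matrix(nd[, gene_cols(G), drop = FALSE])),
    props = unname(as.matrix(nd[, PROP_COLS])),
    kind = kind,
    label = as.integer(nd$cell_label),
    partner = as.integer(partner),
    phase = rep(0, nrow(nd)),
    initial_labels = m$initial_labels,
    next_label = max(nd$cell_label, na.rm = TRUE) + 1L,
    time = m$time
  )
}

state_to_morph <- function(st) {
  G <- ncol(st$E)
  nd <- tibble::tibble(
    id = seq_along(st$kind),
    cell_label = st$label,
    kind = names(KIND_CODE)[st$kind],
    x = st$P[, 1], y = st$P[, 2], z = st$P[, 3])
  pr <- st$props
  colnames(pr) <- PROP_COLS
  E <- st$E
  colnames(E) <- gene_cols(G)
  nd <- dplyr::bind_cols(nd, tibble::as_tibble(pr), tibble::as_tibble(E))
  morphology(nd, initial_labels = st$initial_labels, time = st$time)
}
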