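fibonacci_dirs <- function(n, hemisphere = FALSE) {
  i <- seq_len(n) - 0.5
  zmax <- if (hemisphere) 1 else 2
  z <- 1 - zmax * i / n
  phi_ang <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(x = r * cos(phi_ang), y = r * sin(phi_ang), z = z)
}

shell_morphology <- function(dirs, radius, p_add, p_eqd, n_genes = 10L) {
  n <- nrow(dirs)
  props <- default_node_props()
  props["p_ADD"] <- p_add
  props["p_EQD"] <- p_eqd
  mk <- function(kind, rad, label, id0) {
    tb <- tibble::tibble(
      id = id0 + seq_len(n), cell_label = label, kind = kind,
      x = rad * dirs[, 1], y = rad * dirs[, 2], z = rad * dirs[, 3])
    for (p in PROP_COLS) tb[[p]] <- props[[p]]
    tb
  }
  nodes <- dplyr::bind_rows(
    mk("epithelial_apical", radius + 0.5, seq_len(n), 0L),
    mk("epithelial_basal", radius - 0.5, seq_len(n), n))
  gmat <- matrix(0, nrow(nodes), n_genes)
  colnames(gmat) <- gene_cols(n_genes)
  morphology(dplyr::bind_cols(nodes, tibble::as_tibble(gmat)),
             initial_labels = seq_len(n), time = 0)
}

empty_network <- function(n_genes = 10L, config = sim_config()) {
  gs <- tibble::tibble(
    gene = seq_len(n_genes),
    diffusible = c(FALSE, TRUE, rep(FALSE, n_genes - 2)),
    diffusion_rate = c(0, 0.5, rep(0, n_genes - 2)),
    degradation_rate = 0.2)
  dev_mechanism(matrix(0, n_genes, n_genes), gs, NULL,
                default_division_rate = config$default_division_rate)
}

#' Deterministic fixture morphologies and mechanisms
#'
#' Builds the hand-wired objects used in tests and worked examples.
#' Morphology fixtures: `"sphere"` (epithelial cells on a sphere with
#' radial apical-basal axes; near-zero angle-variation complexity),
#' `"plane"` (the standard flat sheet), `"crumpled_plane"` (the sheet with
#' seeded Gaussian node jitter), `"dome"` (a contact-dense hemisphere).
#' Mechanism fixtures: `"uniform_contraction"` (a quasi-uniformly expressed
#' diffusible gene drives apical contraction everywhere: a complex but
#' noise-sensitive morphology), `"gradient_contraction"` (contraction
#' follows the maintained gradient: a single stable evagination),
#' `"banded_contraction"` (an incoherent feed-forward motif confines
#' contraction to an intermediate band of the gradient),
#' `"threshold_cascade"` (a diffusible signal read at different thresholds
#' with mutual inhibition forms several distinct expression territories),
#' `"knife_edge"` (a minimal two-interaction mechanism in which every
#' parameter is morphologically critical), and `"negative_feedback"` (a
#' driven two-gene negative-feedback loop).
#'
#' @param name Fixture name (see Details).
#' @param params Named list of overrides (e.g. `n`, `radius`, `rings`,
#'   `jitter`, `strength`).
#' @param seed Seed for the stochastic fixtures (default 1).
#' @return A `morphology` or a `dev_mechanism`.
#' @export
make_fixture <- function(name, params = list(), seed = 1) {
  cfg <- sim_config()
  p <- function(key, default) if (!is.null(params[[key]])) params[[key]] else
    default
  switch(
    name,
    sphere = {
      n <- p("n", 500L)
      p_add <- p("p_add", 0.65)
      radius <- p("radius", 20 * 2 * p_add)
      shell_morphology(fibonacci_dirs(n), radius, p_add, 0.77 * p_add)
    },
    dome = {
      n <- p("n", 200L)
      radius <- p("radius", sqrt(n / (2 * pi)))
      shell_morphology(fibonacci_dirs(n, hemisphere = TRUE), radius,
                       0.65, 0.5)
    },
    plane = build_initial_morphology(p("rings", 4L)),
    crumpled_plane = {
      m <- build_initial_morphology(p("rings", 4L))
      jitter <- p("jitter", 0.2)
      with_seed(seed, {
        epi <- grepl("^epithelial", m$nodes$kind)
        for (ax in c("x", "y", "z")) {
          m$nodes[[ax]][epi] <- m$nodes[[ax]][epi] +
            rnorm(sum(epi), 0, jitter)
        }
      })
      m
    },
    uniform_contraction = {
      mech <- empty_network(10L, cfg)
      mech$T[1, 2] <- 1
      mech$gene_specs$diffusion_rate[2] <- 2
      mech$gene_specs$degradation_rate[2] <- 0.05
      mech$couplings <- tibble::tibble(
        gene = 2L, target = "contraction_apical",
        strength = p("strength", -0.12))
      mech
    },
    gradient_contraction = {
      mech <- empty_network(10L, cfg)
      mech$T[1, 2] <- 1
      mech$couplings <- tibble::tibble(
        gene = 1L, target = "contraction_apical",
        strength = p("strength", -0.05))
      mech
    },
    banded_contraction = {
      mech <- empty_network(10L, cfg)
      mech$T[1, 2] <- 5
      mech$T[2, 3] <- 2
      mech$T[1, 3] <- -6
      mech$gene_specs$degradation_rate[2] <- 0.5
      mech$gene_specs$degradation_rate[3] <- 0.3
      mech$couplings <- tibble::tibble(
        gene = 3L, target = "contraction_apical",
        strength = p("strength", -0.12))
      mech
    },
    threshold_cascade = {
      mech <- empty_network(10L, cfg)
      # maintained gradient -> diffusible signal g2; g6 is a saturated
      # (spatially uniform) readout of g2 acting as a threshold reference.
      # g3/g4/g5 read the gradient at decreasing thresholds (subtracting
      # the uniform reference) and each band represses the bands below,
      # yielding distinct expression territories along the gradient.
      mech$T[1, 2] <- 2
      mech$gene_specs$diffusion_rate[2] <- 1
      mech$gene_specs$degradation_rate[2] <- 0.3
      mech$T[2, 6] <- 20
      mech$T[1, 3] <- 3; mech$T[6, 3] <- -0.8
      mech$T[1, 4] <- 3; mech$T[6, 4] <- -0.47; mech$T[3, 4] <- -4
      mech$T[1, 5] <- 3; mech$T[6, 5] <- -0.16; mech$T[3, 5] <- -4
      mech$T[4, 5] <- -4
      mech$gene_specs$degradation_rate[3:6] <- 0.3
      mech
    },
    knife_edge = {
      # minimal pruned-style mechanism: exactly three parameters (one
      # regulatory strength, one degradation rate, one coupling), each of
      # which is morphologically critical
      mech <- empty_network(10L, cfg)
      mech$gene_specs$diffusible[2] <- FALSE
      mech$gene_specs$diffusion_rate[2] <- 0
      mech$gene_specs$degradation_rate[] <- 0
      mech$gene_specs$degradation_rate[2] <- 1
      mech$T[1, 2] <- 0.8
      mech$couplings <- tibble::tibble(
        gene = 2L, target = "contraction_apical",
        strength = p("strength", -0.15))
      mech
    },
    negative_feedback = {
      mech <- empty_network(10L, cfg)
      mech$T[1, 2] <- 3
      mech$T[2, 3] <- 4
      mech$T[3, 2] <- -8
      mech$gene_specs$degradation_rate[2:3] <- 0.1
      mech
    },
    abort(paste0("unknown fixture name: ", name))
  )
}
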