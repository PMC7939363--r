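#' Sample a random gene network
#'
#' Draws a random regulatory network: every ordered gene pair (including
#' self-regulation) receives an interaction with probability `p_interact`;
#' the sign is positive or negative with equal chance and the magnitude
#' uniform on `(0, t_max)`.  Each gene is extracellularly diffusible with
#' probability one half; diffusion rates (diffusible genes) and degradation
#' rates are drawn uniformly from the configured ranges.  Gene 1 (the
#' maintained-gradient input) is constrained to directly activate one
#' extracellularly diffusible gene product: if no such activation is
#' present, one is added (a diffusible target is created if none exists).
#' With 10 genes and `p_interact = 0.2` a gene has on average two efferent
#' and two afferent connections.
#'
#' Draws from the current R random number stream; wrap in a seeded context
#' for reproducibility.
#'
#' @param n_genes Number of genes (>= 2).
#' @param p_interact Interaction probability per ordered pair.
#' @param t_max Upper bound of interaction magnitudes.
#' @param config A [sim_config()] (rate ranges, default division rate).
#' @return A `dev_mechanism` without behavior couplings.
#' @export
sample_network <- function(n_genes = 10L, p_interact = 0.2, t_max = 1,
                           config = sim_config()) {
  stopifnot(n_genes >= 2)
  n <- as.integer(n_genes)
  present <- matrix(runif(n * n) < p_interact, n, n)
  sign_m <- matrix(ifelse(runif(n * n) < 0.5, 1, -1), n, n)
  mag <- matrix(runif(n * n, 0, t_max), n, n)
  T_mat <- ifelse(present, sign_m * mag, 0)
  diffusible <- runif(n) < 0.5
  D <- ifelse(diffusible, runif(n, config$D_range[1], config$D_range[2]), 0)
  mu <- runif(n, config$mu_range[1], config$mu_range[2])
  # constraint: gene 1 activates a diffusible gene product
  if (!any(diffusible)) {
    tgt <- sample.int(n, 1)
    diffusible[tgt] <- TRUE
    D[tgt] <- runif(1, config$D_range[1], config$D_range[2])
  }
  if (!any(T_mat[1, diffusible] > 0)) {
    cand <- which(diffusible)
    tgt <- cand[sample.int(length(cand), 1)]
    T_mat[1, tgt] <- runif(1, 0, t_max)
  }
  gs <- tibble::tibble(gene = seq_len(n), diffusible = diffusible,
                       diffusion_rate = ifelse(diffusible, D, 0),
                       degradation_rate = mu)
  dev_mechanism(T_mat, gs, NULL,
                default_division_rate = config$default_division_rate,
                gradient_gene = config$gradient_gene)
}

#' Attach random behavior couplings to a network
#'
#' Gives each gene a `p_couple` chance of regulating one cell behavior or
#' mechanical property, chosen uniformly from the menu: cell division rate
#' (`p_PHA`), apoptosis, contraction/growth of `p_EQD` (apical, basal, or
#' mesenchymal), ECM secretion, epithelial-mesenchymal transition, adhesion
#' strength (`p_ADD`), and the epithelial stiffnesses `p_EQS`, `p_ERP`,
#' `p_EST`.  Rate-like couplings (division, apoptosis, ECM secretion, EMT)
#' get log-uniform magnitudes; property couplings get signed uniform
#' magnitudes.  All cells keep a small default division rate.
#'
#' @param mech A `dev_mechanism`.
#' @param p_couple Per-gene coupling probability.
#' @param config A [sim_config()].
#' @return The mechanism with couplings attached.
#' @export
attach_behaviors <- function(mech, p_couple = 0.5, config = sim_config()) {
  rows <- list()
  lr <- config$rate_coupling_log10_range
  for (g in seq_len(mech$n_genes)) {
    if (runif(1) >= p_couple) next
    target <- COUPLING_TARGETS[sample.int(length(COUPLING_TARGETS), 1)]
    strength <- if (target %in% RATE_TARGETS) {
      10^runif(1, lr[1], lr[2])
    } else {
      runif(1, -config$prop_coupling_max, config$prop_coupling_max)
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      gene = g, target = target, strength = strength)
  }
  mech$couplings <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(gene = integer(), target = character(),
                   strength = numeric())
  mech$default_division_rate <- config$default_division_rate
  mech
}

#' Screen a network for stable pattern transformation (signaling only)
#'
#' Runs the mechanism with all motion, behaviors and noise frozen (only
#' gene regulation and diffusion act) and asks whether it produces a
#' temporally stable pattern transformation: the expression dynamics must
#' reach the steady-state criterion, the final pattern must differ from the
#' initial one beyond `pattern_change_threshold` (mean absolute expression
#' change per node and gene), and the final pattern must be spatially
#' structured (some non-input gene varies across the epithelium beyond
#' `pattern_spatial_threshold`).
#'
#' @param mech A `dev_mechanism`.
#' @param initial Initial morphology (default: standard sheet).
#' @param config A [sim_config()].
#' @param seed Seed (default `config$seed`).
#' @return List with `pass`, `steady`, `change`, `spatial_sd`, and the
#'   final `trajectory`.
#' @export
signaling_only_screen <- function(mech, initial = NULL,
                                  config = sim_config(), seed = NULL) {
  if (is.null(initial)) {
    initial <- build_initial_morphology(config$sheet_rings,
                                        mech$gradient_gene, mech$n_genes)
  }
  scfg <- sim_config(utils::modifyList(unclass(config),
                                       list(max_steps = config$screen_max_steps)))
  traj <- run_development(mech, initial, scfg, seed = seed,
                          signaling_only = TRUE)
  G <- mech$n_genes
  gcols <- gene_cols(G)
  E0 <- as.matrix(initial$nodes[, gcols])
  E1 <- as.matrix(traj$final$nodes[, gcols])
  change <- mean(abs(E1 - E0))
  epi <- grepl("^epithelial", traj$final$nodes$kind)
  others <- setdiff(seq_len(G), mech$gradient_gene)
  spatial_sd <- if (length(others)) {
    max(apply(E1[epi, others, drop = FALSE], 2, sd))
  } else 0
  steady <- traj$termination_reason == "steady"
  list(pass = steady && change > config$pattern_change_threshold &&
         spatial_sd > config$pattern_spatial_threshold,
       steady = steady, change = change, spatial_sd = spatial_sd,
       trajectory = traj)
}

#' Generate an ensemble of random developmental mechanisms
#'
#' Repeats the two-stage protocol until `n_mechanisms` members are
#' collected: sample a random network, keep it only if it passes the
#' signaling-only stable-pattern-transformation screen, attach random
#' behavior couplings, simulate full development, and discard aberrant
#' outcomes.  Every member records the derived seeds that make it exactly
#' replayable from `(seed, config)`.  With `config$broad_ensemble = TRUE`
#' the signaling screen is skipped (behaviors are attached to every
#' sampled network), mirroring the broader but far less productive variant
#' protocol.
#'
#' @param n_mechanisms Number of ensemble members to collect.
#' @param config A [sim_config()].
#' @param seed Base seed (default `config$seed`).
#' @param max_attempts Cap on sampling attempts (default `50 * n_mechanisms`).
#' @param verbose Print progress.
#' @return Tibble with one row per member: `member`, `attempt`,
#'   `member_seed`, list-columns `mechanism` and `morphology`, the
#'   termination reason, node count, and complexity scores `av`, `opc`.
#' @export
generate_ensemble <- function(n_mechanisms, config = sim_config(),
                              seed = NULL, max_attempts = 50 * n_mechanisms,
                              verbose = FALSE) {
  stopifnot(n_mechanisms >= 1)
  if (is.null(seed)) seed <- config$seed
  members <- list()
  attempt <- 0L
  while (length(members) < n_mechanisms && attempt < max_attempts) {
    attempt <- attempt + 1L
    mseed <- derive_seed(seed, attempt)
    mech <- with_seed(mseed, sample_network(
      config$n_genes, config$p_interact, config$t_max, config))
    if (!config$broad_ensemble) {
      scr <- signaling_only_screen(mech, config = config,
                                   seed = derive_seed(mseed, 1L))
      if (!scr$pass) next
    }
    mech <- with_seed(derive_seed(mseed, 2L),
                      attach_behaviors(mech, config$p_couple, config))
    traj <- run_development(mech, config = config,
                            seed = derive_seed(mseed, 3L))
    if (traj$termination_reason == "aberrant") next
    sc <- complexity_scores(traj$final)
    members[[length(members) + 1L]] <- tibble::tibble(
      member = length(members) + 1L, attempt = attempt, member_seed = mseed,
      mechanism = list(mech), morphology = list(traj$final),
      termination = traj$termination_reason,
      n_nodes = nrow(traj$final$nodes), av = sc$av, opc = sc$opc)
    if (verbose) {
      message(sprintf("member %d/%d (attempt %d): av=%.3f opc=%d",
                      length(members), n_mechanisms, attempt, sc$av, sc$opc))
    }
  }
  out <- dplyr::bind_rows(members)
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  out
}
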