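#' Study configurations for the scaled ensemble analyses
#'
#' The full-size ensemble behind the published-scale statistics (20,000
#' mechanisms, 700 parents, sheets of 542 epithelial nodes) is far beyond a
#' desk run, so the package analyses the same pipeline at reduced scale.
#' `"smoke"` is sized to finish within minutes on one core (a 3-ring sheet
#' of 37 epithelial cells, a 300-node cap, 3 twins per mechanism, pruning
#' patience 8, one 25-step walk with 2 twins per step); `"scaled"` keeps
#' the published screen protocol (10 twins, pruning patience 40, 10 walks
#' of 200 steps with 5 twins) on a 3-ring sheet with an 800-node cap and
#' takes a few CPU-hours for a 200-mechanism ensemble.
#'
#' @param scale `"smoke"` or `"scaled"`.
#' @param ... Further overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
study_config <- function(scale = c("smoke", "scaled"), ...) {
  scale <- match.arg(scale)
  base <- list(dt_max = 0.15, rk_tolerance = 2e-3)
  extra <- if (scale == "smoke") {
    list(sheet_rings = 5L, max_steps = 260L, max_nodes = 500L,
         n_twins = 2L, prune_patience = 4L, prune_twins = 1L,
         n_walks = 1L, walk_steps = 8L, walk_twins = 2L)
  } else {
    list(sheet_rings = 5L, max_steps = 300L, max_nodes = 800L,
         n_twins = 10L, prune_patience = 40L,
         n_walks = 10L, walk_steps = 200L, walk_twins = 5L)
  }
  do.call(sim_config, utils::modifyList(c(base, extra), list(...)))
}

#' Run the ensemble genotype-phenotype study
#'
#' Executes the whole pipeline at the configured scale: generate an
#' ensemble of random developmental mechanisms (signaling screen included),
#' measure each member's complexity and developmental instability, pick a
#' parental set spread across the complexity range, prune each parent,
#' run the IS one-mutant neighborhood screen (optionally on a parameter
#' subset), fit the GPM regressions, and run iso-morphological random
#' walks on the eligible parents.
#'
#' @param n_mechanisms Ensemble size.
#' @param config A [sim_config()], typically from [study_config()].
#' @param seed Base seed.
#' @param n_parents Number of parents, spread evenly over the complexity
#'   range.
#' @param max_params_per_parent Cap on mutated parameters per parent
#'   (`Inf` mutates every parameter, the full protocol).
#' @param verbose Print progress.
#' @return List with tibbles `ensemble` (member scores + instability),
#'   `parents`, `offspring` (per-mutant complexity for the asymmetry
#'   analysis), `regressions` (per parent and parameter), and `walks`
#'   (accepted steps per parent and walk).
#' @export
run_gpm_study <- function(n_mechanisms = 50, config = study_config("smoke"),
                          seed = NULL, n_parents = 12,
                          max_params_per_parent = 3, verbose = FALSE) {
  if (is.null(seed)) seed <- config$seed
  say <- function(...) if (verbose) message(sprintf(...))

  say("generating ensemble of %d mechanisms", n_mechanisms)
  ens <- generate_ensemble(n_mechanisms, config, seed = seed,
                           verbose = verbose)
  if (!nrow(ens)) abort("ensemble generation produced no members")

  say("measuring developmental instability")
  inst <- lapply(seq_len(nrow(ens)), function(i) {
    tw <- simulate_twins(ens$mechanism[[i]], config$n_twins, config,
                         derive_seed(seed, 500000L + i))
    tibble::tibble(
      member = ens$member[i],
      emd_instability = pairwise_distance(tw$morphs, "emd"),
      cmd_instability = pairwise_distance(tw$morphs, "cmd"),
      twins = list(tw$morphs), n_aberrant = tw$n_aberrant)
  })
  inst <- dplyr::bind_rows(inst)
  ensemble <- dplyr::left_join(ens, inst, by = "member")

  # parental set: evenly spread over the observed complexity range, among
  # members with enough non-aberrant twins to support the screens
  usable <- vapply(ensemble$twins, length, integer(1)) >= 2
  ord <- order(ensemble$av)
  ord <- ord[usable[ord]]
  pick <- unique(round(seq(1, length(ord),
                           length.out = min(n_parents, length(ord)))))
  parent_ids <- ensemble$member[ord[pick]]

  offspring <- list()
  regressions <- list()
  walks <- list()
  parents <- list()
  for (pid in parent_ids) {
    row <- ensemble[ensemble$member == pid, ]
    say("parent %d (av=%.3f): pruning", pid, row$av)
    pr <- prune(row$mechanism[[1]], config,
                seed = derive_seed(seed, 600000L + pid),
                parent_twins = row$twins[[1]])
    parent <- pr$mechanism
    ptab <- mech_parameters(parent)
    n_par <- nrow(ptab)
    # when only a subset of parameters is screened, prefer the pruned
    # mechanism's structural parameters (interaction strengths and
    # couplings), then the rates of genes involved in them: these carry the
    # GPM signal, while rates of disconnected genes are vestigial
    params <- if (n_par > max_params_per_parent) {
      involved <- unique(c(
        ptab$gene_from[ptab$type %in% c("network", "coupling")],
        ptab$gene_to[ptab$type == "network"]))
      tier <- ifelse(ptab$type %in% c("network", "coupling"), 1L,
                     ifelse(ptab$gene_from %in% involved, 2L, 3L))
      with_seed(derive_seed(seed, 650000L + pid), {
        ord <- order(tier, runif(n_par))
        sort(ptab$param[ord][seq_len(max_params_per_parent)])
      })
    } else ptab$param
    say("parent %d: IS screen on %d of %d parameters", pid, length(params),
        n_par)
    rec <- is_neighborhood(parent, config,
                           seed = derive_seed(seed, 700000L + pid),
                           params = params)
    offspring[[length(offspring) + 1L]] <- tibble::tibble(
      member = pid, parent_av = row$av, parent_opc = row$opc,
      param = rec$param, magnitude = rec$magnitude,
      av = rec$av, opc = rec$opc, n_aberrant = rec$n_aberrant)
    reg <- gpm_regression(row$twins[[1]], rec, metric = "emd")
    regressions[[length(regressions) + 1L]] <- dplyr::mutate(
      tidy(reg), member = pid, parent_av = row$av, .before = 1)

    walk_note <- NA_character_
    wk <- tryCatch(
      iso_walk(parent, config, seed = derive_seed(seed, 800000L + pid),
               parent_twins = row$twins[[1]]),
      error = function(e) {
        walk_note <<- conditionMessage(e)
        NULL
      })
    if (!is.null(wk)) {
      walks[[length(walks) + 1L]] <- tibble::tibble(
        member = pid, parent_av = row$av, walk = wk$walk,
        steps = wk$steps, accepted = wk$accepted)
    }
    parents[[length(parents) + 1L]] <- tibble::tibble(
      member = pid, parent_av = row$av, parent_opc = row$opc,
      n_params_total = n_par, n_params_screened = length(params),
      n_deleted = pr$n_deleted,
      cmd_instability = pr$parent_instability,
      walk_eligible = !is.null(wk), walk_note = walk_note)
  }
  list(
    ensemble = dplyr::select(ensemble, -"mechanism", -"morphology",
                             -"twins"),
    parents = dplyr::bind_rows(parents),
    offspring = dplyr::bind_rows(offspring),
    regressions = dplyr::bind_rows(regressions),
    walks = dplyr::bind_rows(walks),
    seed = seed)
}
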