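#' Simulate twin replicates of a mechanism
#'
#' A twin is one stochastic simulation of a mechanism under the same
#' parameters; twins differ only through the developmental noise seed.
#' Twin seeds are derived deterministically from `seed` by counter, so the
#' set is reproducible and independent of execution order.
#'
#' @param mech A `dev_mechanism`.
#' @param k Number of twins.
#' @param config A [sim_config()].
#' @param seed Base seed (default `config$seed`).
#' @param initial Initial morphology (default: standard sheet).
#' @return List with `morphs` (non-aberrant final morphologies),
#'   `n_aberrant`, and `seeds`.
#' @export
simulate_twins <- function(mech, k, config = sim_config(), seed = NULL,
                           initial = NULL) {
  if (is.null(seed)) seed <- config$seed
  if (is.null(initial)) {
    initial <- build_initial_morphology(config$sheet_rings,
                                        mech$gradient_gene, mech$n_genes)
  }
  seeds <- vapply(seq_len(k), function(i) derive_seed(seed, i), integer(1))
  morphs <- list()
  n_ab <- 0L
  for (s in seeds) {
    traj <- run_development(mech, initial, config, seed = s)
    if (traj$termination_reason == "aberrant") {
      n_ab <- n_ab + 1L
    } else {
      morphs[[length(morphs) + 1L]] <- traj$final
    }
  }
  list(morphs = morphs, n_aberrant = n_ab, seeds = seeds)
}

pairwise_distance <- function(morphs, metric = c("emd", "cmd", "hmd")) {
  metric <- match.arg(metric)
  k <- length(morphs)
  if (k < 2) return(NA_real_)
  f <- switch(metric, emd = emd, cmd = cmd, hmd = hmd)
  vals <- c()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      vals <- c(vals, f(morphs[[i]], morphs[[j]]))
    }
  }
  mean(vals)
}

cross_distance <- function(ma, mb, metric = c("emd", "cmd", "hmd")) {
  metric <- match.arg(metric)
  f <- switch(metric, emd = emd, cmd = cmd, hmd = hmd)
  mean(vapply(ma, function(a) {
    mean(vapply(mb, function(b) f(a, b), numeric(1)))
  }, numeric(1)))
}

#' Developmental instability of a mechanism
#'
#' Simulates `k_twins` twins (distinct noise seeds) and returns the mean
#' pairwise morphological distance between them under the chosen metric —
#' the measure of developmental instability.  Aberrant twins are excluded
#' and counted.
#'
#' @param mech A `dev_mechanism`.
#' @param k_twins Number of twins (>= 2).
#' @param metric `"emd"`, `"cmd"` or `"hmd"`.
#' @param config A [sim_config()].
#' @param seed Base seed.
#' @return Tibble with `metric`, `instability`, `n_twins`, `n_aberrant`.
#' @export
developmental_instability <- function(mech, k_twins = NULL,
                                      metric = c("emd", "cmd", "hmd"),
                                      config = sim_config(), seed = NULL) {
  metric <- match.arg(metric)
  if (is.null(k_twins)) k_twins <- config$n_twins
  stopifnot(k_twins >= 2)
  tw <- simulate_twins(mech, k_twins, config, seed)
  tibble::tibble(metric = metric,
                 instability = pairwise_distance(tw$morphs, metric),
                 n_twins = k_twins, n_aberrant = tw$n_aberrant)
}

#' Prune superfluous interactions from a mechanism
#'
#' Iteratively deletes randomly chosen interactions (network entries or
#' behavior couplings).  A candidate deletion is simulated
#' `config$n_twins` times; it is accepted when the mean convexity distance
#' (CMD) between the candidate twins and the parent twins does not exceed
#' the parent's CMD developmental instability plus `config$cmd_margin`
#' (default 0.01) — i.e. the deletion leaves the morphology unchanged up to
#' developmental noise.  Any aberrant candidate twin counts as a changed
#' morphology (rejection).  Pruning stops after `config$prune_patience`
#' consecutive rejections (default 40) or when no interactions remain.
#'
#' @param mech The parent `dev_mechanism`.
#' @param config A [sim_config()].
#' @param seed Base seed.
#' @param parent_twins Optional precomputed parent twin morphologies.
#' @return List with `mechanism` (the pruned mechanism), `parent_twins`,
#'   `parent_instability` (CMD), `n_deleted`, and a `history` tibble of
#'   attempted deletions.
#' @export
prune <- function(mech, config = sim_config(), seed = NULL,
                  parent_twins = NULL) {
  if (is.null(seed)) seed <- config$seed
  if (is.null(parent_twins)) {
    parent_twins <- simulate_twins(mech, config$n_twins, config,
                                   derive_seed(seed, 1L))$morphs
  }
  if (length(parent_twins) < 2) abort("parent twins mostly aberrant")
  inst <- pairwise_distance(parent_twins, "cmd")
  threshold <- inst + config$cmd_margin
  current <- mech
  consec <- 0L
  n_del <- 0L
  hist <- list()
  step <- 0L
  cand_twins <- if (config$prune_twins > 0) config$prune_twins else
    config$n_twins
  with_seed(derive_seed(seed, 2L), {
    while (consec < config$prune_patience && n_interactions(current) > 0) {
      step <- step + 1L
      ints <- mech_interactions(current)
      pick <- sample.int(nrow(ints), 1)
      cand <- delete_interaction(current, pick)
      tw <- simulate_twins(cand, cand_twins, config,
                           derive_seed(seed, 100L + step))
      d <- if (tw$n_aberrant > 0 || !length(tw$morphs)) Inf else
        cross_distance(tw$morphs, parent_twins, "cmd")
      accept <- d <= threshold
      hist[[step]] <- tibble::tibble(
        step = step, type = ints$type[pick],
        gene_from = ints$gene_from[pick], gene_to = ints$gene_to[pick],
        target = ints$target[pick], cmd = d, accepted = accept)
      if (accept) {
        current <- cand
        consec <- 0L
        n_del <- n_del + 1L
      } else {
        consec <- consec + 1L
      }
    }
  })
  list(mechanism = current, parent_twins = parent_twins,
       parent_instability = inst, n_deleted = n_del,
       history = dplyr::bind_rows(hist))
}

is_magnitudes <- function() c(-80, -60, -40, -20, 20, 40, 60, 80)

#' One-mutant neighborhood of interaction-strength (IS) mutations
#'
#' For each parameter of the parent (all of them by default), generates 8
#' mutant offspring whose parameter value is changed proportionally to the
#' parental value (-80% to +80% in 20% steps, never 0%), and simulates each
#' mutant `config$n_twins` times with distinct derived seeds.  Parents are
#' expected to be pruned, so every enumerated parameter is non-zero.
#'
#' @param mech The (pruned) parent mechanism.
#' @param config A [sim_config()].
#' @param seed Base seed.
#' @param params Parameter indices to mutate (default: all).
#' @param score Also record mean complexity of the mutant twins.
#' @return A `mutation_records` tibble: one row per mutant with `param`,
#'   `kind = "IS"`, `magnitude` (signed percent), list-columns `mechanism`
#'   and `twins`, `n_aberrant`, and (if `score`) mean twin `av` and `opc`.
#' @export
is_neighborhood <- function(mech, config = sim_config(), seed = NULL,
                            params = NULL, score = TRUE) {
  if (is.null(seed)) seed <- config$seed
  tab <- mech_parameters(mech)
  if (is.null(params)) params <- tab$param
  stopifnot(all(tab$value[match(params, tab$param)] != 0))
  rows <- list()
  stream <- 0L
  for (p in params) {
    v0 <- tab$value[match(p, tab$param)]
    for (mag in is_magnitudes()) {
      stream <- stream + 1L
      mut <- set_parameter(mech, p, v0 * (1 + mag / 100))
      mut_seed <- derive_seed(seed, stream)
      tw <- simulate_twins(mut, config$n_twins, config, mut_seed)
      row <- tibble::tibble(
        param = p, kind = "IS", magnitude = mag, seed = mut_seed,
        mechanism = list(mut), twins = list(tw$morphs),
        n_aberrant = tw$n_aberrant)
      if (score && length(tw$morphs)) {
        sc <- dplyr::bind_rows(lapply(tw$morphs, complexity_scores))
        row$av <- mean(sc$av)
        row$opc <- mean(sc$opc)
      } else if (score) {
        row$av <- NA_real_
        row$opc <- NA_real_
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mutation_records", class(out))
  out
}

#' One-mutant neighborhoods of topology (T) mutations
#'
#' Deletion neighborhood: one mutant per existing interaction, with that
#' interaction removed.  Addition neighborhood: `N_c` mutants (one per
#' existing interaction), each with one random new interaction drawn by the
#' ensemble samplers — a network edge with random sign and magnitude, or a
#' behavior coupling — resampling on collision with an existing
#' interaction.  Each mutant is simulated `config$n_twins` times.
#'
#' @inheritParams is_neighborhood
#' @return A `mutation_records` tibble with `kind` `"T_del"` or `"T_add"`.
#' @export
t_neighborhoods <- function(mech, config = sim_config(), seed = NULL,
                            score = TRUE) {
  if (is.null(seed)) seed <- config$seed
  ints <- mech_interactions(mech)
  n_c <- nrow(ints)
  rows <- list()
  stream <- 0L
  score_row <- function(row, tw) {
    if (score && length(tw$morphs)) {
      sc <- dplyr::bind_rows(lapply(tw$morphs, complexity_scores))
      row$av <- mean(sc$av)
      row$opc <- mean(sc$opc)
    } else if (score) {
      row$av <- NA_real_
      row$opc <- NA_real_
    }
    row
  }
  for (i in seq_len(n_c)) {
    stream <- stream + 1L
    mut <- delete_interaction(mech, i)
    mut_seed <- derive_seed(seed, stream)
    tw <- simulate_twins(mut, config$n_twins, config, mut_seed)
    rows[[length(rows) + 1L]] <- score_row(tibble::tibble(
      param = i, kind = "T_del", magnitude = NA_real_, seed = mut_seed,
      mechanism = list(mut), twins = list(tw$morphs),
      n_aberrant = tw$n_aberrant), tw)
  }
  for (i in seq_len(n_c)) {
    stream <- stream + 1L
    mut <- with_seed(derive_seed(seed, 10000L + i),
                     add_random_interaction(mech, config))
    mut_seed <- derive_seed(seed, stream)
    tw <- simulate_twins(mut, config$n_twins, config, mut_seed)
    rows[[length(rows) + 1L]] <- score_row(tibble::tibble(
      param = i, kind = "T_add", magnitude = NA_real_, seed = mut_seed,
      mechanism = list(mut), twins = list(tw$morphs),
      n_aberrant = tw$n_aberrant), tw)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mutation_records", class(out))
  out
}

# one random new interaction, drawn like the ensemble samplers; resamples
# until it does not collide with an existing interaction
add_random_interaction <- function(mech, config = sim_config()) {
  lr <- config$rate_coupling_log10_range
  for (try in 1:1000) {
    if (runif(1) < 0.5) {
      from <- sample.int(mech$n_genes, 1)
      to <- sample.int(mech$n_genes, 1)
      if (mech$T[from, to] != 0) next
      s <- if (runif(1) < 0.5) 1 else -1
      mech$T[from, to] <- s * runif(1, 0, config$t_max)
      return(mech)
    } else {
      g <- sample.int(mech$n_genes, 1)
      target <- COUPLING_TARGETS[sample.int(length(COUPLING_TARGETS), 1)]
      if (any(mech$couplings$gene == g & mech$couplings$target == target)) next
      strength <- if (target %in% RATE_TARGETS) {
        10^runif(1, lr[1], lr[2])
      } else {
        runif(1, -config$prop_coupling_max, config$prop_coupling_max)
      }
      mech$couplings <- dplyr::bind_rows(
        mech$couplings,
        tibble::tibble(gene = g, target = target, strength = strength))
      return(mech)
    }
  }
  abort("could not draw a non-colliding interaction")
}

#' Iso-morphological random walks
#'
#' Estimates the size of the parameter-space region in which the parent's
#' morphology forms.  Performs `config$n_walks` independent random walks of
#' `config$walk_steps` IS-mutation steps.  Each step picks one parameter
#' uniformly and adds or subtracts (uniformly) twice the PARENTAL value of
#' that parameter; the candidate is simulated `config$walk_twins` times and
#' the step is accepted when the mean CMD of the candidate twins to the
#' parent twins stays within the parent's CMD instability plus
#' `config$cmd_margin` (aberrant twins force rejection).  Rejected steps
#' are reverted; accepted steps compound by default
#' (`config$walk_mode = "reset"` restarts each candidate from the parental
#' values instead).  Walks are only run for developmentally very stable
#' parents (twin EMD below `config$walk_eligibility_emd`, default 0.3);
#' others raise an eligibility error.
#'
#' @param mech The (pruned) parent mechanism.
#' @param config A [sim_config()].
#' @param seed Base seed.
#' @param parent_twins Optional precomputed parent twins.
#' @return A `walk_result` tibble: one row per walk with `walk`, `steps`,
#'   `accepted`, and the final mechanism as a list-column; attributes carry
#'   the parent EMD and CMD instabilities.
#' @export
iso_walk <- function(mech, config = sim_config(), seed = NULL,
                     parent_twins = NULL) {
  if (is.null(seed)) seed <- config$seed
  if (is.null(parent_twins)) {
    parent_twins <- simulate_twins(mech, config$n_twins, config,
                                   derive_seed(seed, 1L))$morphs
  }
  if (length(parent_twins) < 2) abort("parent twins mostly aberrant")
  emd_inst <- pairwise_distance(parent_twins, "emd")
  if (emd_inst >= config$walk_eligibility_emd) {
    abort(sprintf(
      "parent not eligible for iso-morphological walks: twin EMD %.3f >= %.3f",
      emd_inst, config$walk_eligibility_emd))
  }
  cmd_inst <- pairwise_distance(parent_twins, "cmd")
  threshold <- cmd_inst + config$cmd_margin
  ptab <- mech_parameters(mech)
  walks <- list()
  for (w in seq_len(config$n_walks)) {
    current <- mech
    accepted <- 0L
    wseed <- derive_seed(seed, 1000L + w)
    with_seed(wseed, {
      for (s in seq_len(config$walk_steps)) {
        p <- sample.int(nrow(ptab), 1)
        sgn <- if (runif(1) < 0.5) 1 else -1
        base <- if (config$walk_mode == "compound") current else mech
        row <- ptab[p, ]
        v_now <- get_parameter_row(base, row)
        cand <- set_parameter_row(base, row, v_now + sgn * 2 * ptab$value[p])
        tw <- simulate_twins(cand, config$walk_twins, config,
                             derive_seed(wseed, s))
        d <- if (tw$n_aberrant > 0 || !length(tw$morphs)) Inf else
          cross_distance(tw$morphs, parent_twins, "cmd")
        if (d <= threshold) {
          accepted <- accepted + 1L
          current <- cand
        }
      }
    })
    walks[[w]] <- tibble::tibble(walk = w, steps = config$walk_steps,
                                 accepted = accepted,
                                 mechanism = list(current))
  }
  out <- dplyr::bind_rows(walks)
  attr(out, "emd_instability") <- emd_inst
  attr(out, "cmd_instability") <- cmd_inst
  class(out) <- c("walk_result", class(out))
  out
}
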