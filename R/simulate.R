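# --- flat packing of the continuous state for the RK driver ---------------

pack_state <- function(st) c(st$P, st$E, st$props)

unpack_into <- function(st, y) {
  n <- nrow(st$P); G <- ncol(st$E)
  st$P <- matrix(y[seq_len(3 * n)], n, 3)
  st$E <- matrix(y[3 * n + seq_len(n * G)], n, G)
  st$props <- matrix(y[3 * n + n * G + seq_len(6 * n)], n, 6)
  st
}

# compiled RK4 stepper bound to a (state topology, mechanism, config)
make_stepper <- function(st, ar, clamp, cfg, frozen) {
  n <- nrow(st$P)
  G <- ncol(st$E)
  function(y, dt) {
    cpp_rk4_step(y, dt, n, G, st$kind, st$partner, ar$T, ar$deg, ar$D,
                 ar$cp_gene, ar$cp_code, ar$cp_strength, clamp,
                 cfg$k_rep, cfg$k_adh, cfg$k_spring, cfg$k_bend,
                 cfg$k_tors, frozen)
  }
}

# one adaptive step: classical RK4 with step-doubling error control
adaptive_step <- function(y, dt, step_fn, cfg) {
  repeat {
    y_full <- step_fn(y, dt)
    y_half <- step_fn(step_fn(y, dt / 2), dt / 2)
    err <- max(abs(y_half - y_full))
    if (!is.finite(err)) {
      dt <- dt / 4
      if (dt < cfg$dt_min) abort("integration diverged (non-finite state)")
      next
    }
    if (err <= cfg$rk_tolerance || dt <= cfg$dt_min) {
      fac <- if (err > 0) 0.9 * (cfg$rk_tolerance / err)^0.2 else 2
      dt_next <- min(max(dt * min(max(fac, 0.2), 2), cfg$dt_min), cfg$dt_max)
      return(list(y = y_half, dt_used = dt, dt_next = dt_next, err = err))
    }
    dt <- max(dt * max(0.9 * (cfg$rk_tolerance / err)^0.25, 0.2), cfg$dt_min)
  }
}

clamp_state <- function(st, cfg) {
  st$E[st$E < 0] <- 0
  st$props[, 2] <- pmax(st$props[, 2], 0.05)            # p_EQD floor
  st$props[, 1] <- pmax(st$props[, 1], st$props[, 2])   # p_ADD >= p_EQD
  st$props[, 3] <- pmax(st$props[, 3], 0.05)
  st$props[, 4] <- pmax(st$props[, 4], 0)
  st$props[, 5] <- pmax(st$props[, 5], 0)
  st$props[, 6] <- pmax(st$props[, 6], 0)
  st
}

# per-cell view: list of node-index vectors keyed by cell label, in label order
cells_of_state <- function(st) {
  keep <- st$kind != 4L
  split(which(keep), st$label[keep])
}

cell_rate <- function(st, mech, target) {
  cpl <- mech$couplings[mech$couplings$target == target, ]
  if (!nrow(cpl)) return(setNames(numeric(0), character(0)))
  cells <- cells_of_state(st)
  vapply(cells, function(idx) {
    sum(cpl$strength * colMeans(st$E[idx, cpl$gene, drop = FALSE]))
  }, numeric(1))
}

rand_unit_inplane <- function(axis) {
  # random unit vector perpendicular to axis
  phi_ang <- runif(1, 0, 2 * pi)
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  cos(phi_ang) * e1 + sin(phi_ang) * e2
}

rand_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

add_rows <- function(st, P, E, props, kind, label, partner, phase) {
  st$P <- rbind(st$P, P)
  st$E <- rbind(st$E, E)
  st$props <- rbind(st$props, props)
  st$kind <- c(st$kind, kind)
  st$label <- c(st$label, label)
  st$partner <- c(st$partner, partner)
  st$phase <- c(st$phase, phase)
  st
}

drop_rows <- function(st, idx) {
  if (!length(idx)) return(st)
  keep <- setdiff(seq_along(st$kind), idx)
  remap <- match(seq_along(st$kind), keep)
  st$P <- st$P[keep, , drop = FALSE]
  st$E <- st$E[keep, , drop = FALSE]
  st$props <- st$props[keep, , drop = FALSE]
  st$kind <- st$kind[keep]
  st$label <- st$label[keep]
  st$phase <- st$phase[keep]
  pt <- st$partner[keep]
  st$partner <- ifelse(pt == 0L, 0L, remap[pt])
  st$partner[is.na(st$partner)] <- 0L
  st
}

# developmental noise: isotropic Gaussian displacement of every cell node,
# centered per step (zero mean over cells) so fluctuations perturb relative
# positions without a net random walk of the whole embryo
add_position_noise <- function(st, cfg) {
  if (cfg$noise_amplitude <= 0) return(st)
  cells <- st$kind != 4L
  eps <- matrix(rnorm(length(st$kind) * 3, 0, cfg$noise_amplitude), ncol = 3)
  if (sum(cells) > 1) {
    eps[cells, ] <- sweep(eps[cells, , drop = FALSE], 2,
                          colMeans(eps[cells, , drop = FALSE]))
  }
  eps[!cells, ] <- 0
  st$P <- st$P + eps
  st
}

# discrete behavior events for one accepted step of length dt (operates on
# the internal state; RNG draws happen in deterministic cell-label order)
apply_behaviors_state <- function(st, mech, dt, cfg) {
  noncell <- st$kind == 4L
  # cell-cycle phase always accumulates (default rate + regulated p_PHA)
  st$phase <- st$phase + (mech$default_division_rate + st$props[, 6]) * dt *
    as.numeric(!noncell)
  has_emt <- any(mech$couplings$target == "emt")
  has_sec <- any(mech$couplings$target == "ecm_secretion")
  any_dead <- any(st$props[!noncell, 2] <= cfg$min_radius)
  any_div <- any(st$phase >= 1)
  if (!has_emt && !has_sec && !any_dead && !any_div) return(st)

  # apoptosis completion: cells shrunk to the minimal radius are eliminated
  cells <- cells_of_state(st)
  if (any_dead) {
    dead <- names(cells)[vapply(cells, function(idx) {
      mean(st$props[idx, 2]) <= cfg$min_radius
    }, logical(1))]
    if (length(dead)) {
      st <- drop_rows(st, unlist(cells[dead], use.names = FALSE))
      cells <- cells_of_state(st)
    }
  }

  # epithelial-mesenchymal transition
  emt_rate <- if (has_emt) cell_rate(st, mech, "emt") else numeric(0)
  emt_rate <- emt_rate[emt_rate > 0]
  if (length(emt_rate)) {
    for (lab in names(emt_rate)) {
      if (runif(1) < 1 - exp(-emt_rate[[lab]] * dt)) {
        idx <- cells[[lab]]
        if (is.null(idx) || st$kind[idx[1]] > 2L) next
        center <- colMeans(st$P[idx, , drop = FALSE])
        E <- colMeans(st$E[idx, , drop = FALSE])
        props <- colMeans(st$props[idx, , drop = FALSE])
        st <- drop_rows(st, idx)
        st <- add_rows(st, matrix(center, 1), matrix(E, 1), matrix(props, 1),
                       3L, as.integer(lab), 0L, 0)
        cells <- cells_of_state(st)
      }
    }
  }

  # ECM secretion
  sec_rate <- if (has_sec) cell_rate(st, mech, "ecm_secretion") else numeric(0)
  sec_rate <- sec_rate[sec_rate > 0]
  if (length(sec_rate)) {
    for (lab in names(sec_rate)) {
      if (runif(1) < 1 - exp(-sec_rate[[lab]] * dt)) {
        idx <- cells[[lab]]
        if (is.null(idx)) next
        if (st$kind[idx[1]] <= 2L) {
          bas <- idx[st$kind[idx] == 2L][1]
          axis <- axis_of(st$P, st$kind, st$partner, bas)
          pos <- st$P[bas, ] - axis * (st$props[bas, 2] + cfg$ecm_radius)
        } else {
          pos <- st$P[idx[1], ] + rand_unit() *
            (st$props[idx[1], 2] + cfg$ecm_radius)
        }
        props <- c(cfg$ecm_add, cfg$ecm_radius, 0.05, 0, 0, 0)
        st <- add_rows(st, matrix(pos, 1),
                       matrix(0, 1, ncol(st$E)), matrix(props, 1),
                       4L, NA_integer_, 0L, 0)
      }
    }
  }

  # cell division: a cell divides when its mean cell-cycle phase reaches 1
  if (!any(st$phase >= 1)) return(st)
  cells <- cells_of_state(st)
  for (lab in names(cells)) {
    idx <- cells[[lab]]
    ph <- mean(st$phase[idx])
    if (ph >= 1) {
      st$phase[idx] <- 0
      labs <- assign_division_labels(as.integer(lab), st$next_label)
      st$next_label <- labs$next_label
      st$label[idx] <- labs$first
      n0 <- length(st$kind)
      if (st$kind[idx[1]] <= 2L) {
        ap <- idx[st$kind[idx] == 1L][1]
        off <- rand_unit_inplane(axis_of(st$P, st$kind, st$partner, ap)) *
          cfg$division_offset
        newP <- st$P[idx, , drop = FALSE] +
          matrix(off, length(idx), 3, byrow = TRUE)
        st <- add_rows(st, newP, st$E[idx, , drop = FALSE],
                       st$props[idx, , drop = FALSE], st$kind[idx],
                       rep(labs$second, length(idx)), rep(0L, length(idx)),
                       rep(0, length(idx)))
        # wire the partners of the new apical/basal pair
        new_idx <- n0 + seq_along(idx)
        ap_new <- new_idx[st$kind[new_idx] == 1L]
        ba_new <- new_idx[st$kind[new_idx] == 2L]
        st$partner[ap_new] <- ba_new
        st$partner[ba_new] <- ap_new
      } else {
        off <- rand_unit() * cfg$division_offset
        st <- add_rows(st, matrix(st$P[idx, ] + off, 1),
                       st$E[idx, , drop = FALSE],
                       st$props[idx, , drop = FALSE], 3L,
                       labs$second, 0L, 0)
      }
    }
  }
  st
}

#' Apply discrete cell behaviors for one time step
#'
#' Executes the gene-regulated discrete behaviors on a morphology for a step
#' of length `dt`: completion of apoptosis (cells shrunk below the minimal
#' radius are eliminated), epithelial-mesenchymal transition, ECM secretion,
#' and cell division (phase accumulates at the default rate plus the
#' regulated `p_PHA`; daughters are displaced by a small random in-plane
#' offset and labelled via [assign_division_labels()]), followed by the
#' per-step positional noise.  Continuous behavior effects (contraction,
#' adhesion and stiffness regulation, apoptotic shrinking) act through the
#' property dynamics of the integrator, not here.
#'
#' @param m A `morphology`.
#' @param mech A `dev_mechanism`.
#' @param dt Time step.
#' @param config A [sim_config()].
#' @return The updated morphology.
#' @export
apply_behaviors <- function(m, mech, dt, config = sim_config()) {
  stopifnot(dt > 0)
  st <- morph_to_state(m)
  st <- apply_behaviors_state(st, mech, dt, config)
  ncell <- sum(st$kind != 4L)
  st <- add_position_noise(st, config)
  st$time <- st$time + dt
  if (ncell > config$max_nodes) {
    attr(st, "over_cap") <- TRUE
  }
  state_to_morph(st)
}

#' Detect aberrant morphologies
#'
#' Flags morphologies a screen would discard: a broken epithelium (the
#' same-side epithelial contact graph splits into disconnected components),
#' an over-stretched apical-basal spring (length beyond `rupture_multiple`
#' times its rest length), or contacting neighbor cells whose apical-basal
#' axes anti-align below `antialign_threshold` (a proxy for epithelial
#' self-intersection).
#'
#' @param m A `morphology`.
#' @param config A [sim_config()].
#' @return List with elements `aberrant` (flag) and `reason` (`NA` or one of
#'   `"broken_epithelium"`, `"ruptured_spring"`, `"folded_axes"`).
#' @export
detect_aberrant <- function(m, config = sim_config()) {
  detect_aberrant_state(morph_to_state(m), config)
}

# union-find component count for an undirected edge list on 1..n
n_components <- function(n, i, j) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_along(i)) {
    ri <- find(i[e]); rj <- find(j[e])
    if (ri != rj) parent[ri] <- rj
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

detect_aberrant_state <- function(st, cfg) {
  ap <- which(st$kind == 1L)
  n <- length(ap)
  if (n == 0) return(list(aberrant = FALSE, reason = NA_character_))
  ba <- st$partner[ap]
  spring <- sqrt(rowSums((st$P[ap, , drop = FALSE] -
                            st$P[ba, , drop = FALSE])^2))
  rest <- st$props[ap, 3] + st$props[ba, 3]
  if (any(spring > cfg$rupture_multiple * rest)) {
    return(list(aberrant = TRUE, reason = "ruptured_spring"))
  }
  if (n >= 2) {
    ei <- ej <- integer(0)
    deep <- logical(0)
    for (side in list(ap, ba)) {
      P <- st$P[side, , drop = FALSE]
      dmat <- as.matrix(stats::dist(P))
      thr <- outer(st$props[side, 1], st$props[side, 1], "+")
      core <- outer(st$props[side, 2], st$props[side, 2], "+")
      hit <- which(dmat < thr & upper.tri(dmat), arr.ind = TRUE)
      ei <- c(ei, hit[, 1])
      ej <- c(ej, hit[, 2])
      deep <- c(deep, dmat[hit] < 0.75 * core[hit])
    }
    if (n_components(n, ei, ej) > 1) {
      return(list(aberrant = TRUE, reason = "broken_epithelium"))
    }
    if (any(deep)) {
      # interpenetration proxy: anti-aligned axes deep inside the
      # repulsion core of a same-side pair
      U <- st$P[ap, , drop = FALSE] - st$P[ba, , drop = FALSE]
      U <- U / sqrt(rowSums(U^2))
      dots <- rowSums(U[ei[deep], , drop = FALSE] *
                        U[ej[deep], , drop = FALSE])
      if (any(dots < cfg$antialign_threshold)) {
        return(list(aberrant = TRUE, reason = "folded_axes"))
      }
    }
  }
  list(aberrant = FALSE, reason = NA_character_)
}

# pairs of epithelial cells in lateral contact (apical-apical or
# basal-basal within summed adhesion radii); i, j are row indices into
# epithelial_cells(m)
cell_contact_pairs <- function(m) {
  nd <- m$nodes
  out <- list()
  cells <- epithelial_cells(m)
  for (side in c("epithelial_apical", "epithelial_basal")) {
    sub <- nd[nd$kind == side, ]
    sub <- sub[match(cells$label, sub$cell_label), ]
    P <- as.matrix(sub[, c("x", "y", "z")])
    dmat <- as.matrix(stats::dist(P))
    thr <- outer(sub$p_ADD, sub$p_ADD, "+")
    hit <- which(dmat < thr & upper.tri(dmat), arr.ind = TRUE)
    if (nrow(hit)) {
      out[[side]] <- tibble::tibble(i = hit[, 1], j = hit[, 2])
    }
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) return(tibble::tibble(i = integer(), j = integer()))
  dplyr::distinct(res)
}

#' Simulate development of a mechanism
#'
#' Integrates the coupled dynamics of a developmental mechanism from an
#' initial morphology: positions move under the pair and epithelial forces
#' (overdamped: velocity proportional to force), expression follows gene
#' regulation and extracellular diffusion, and mechanical properties follow
#' their gene couplings.  The continuous variables advance by classical RK4
#' with step-doubling error control (`rk_tolerance`); between accepted steps
#' the discrete behaviors (division, EMT, ECM secretion, apoptosis removal)
#' fire, and seeded isotropic Gaussian noise perturbs cell positions.
#' Integration halts at `max_steps`, when the node count reaches
#' `max_nodes`, when the morphology becomes aberrant, or when a steady state
#' (negligible deterministic motion and expression change over a window) is
#' reached.
#'
#' @param mech A `dev_mechanism`.
#' @param initial Initial `morphology` (defaults to the standard flat sheet
#'   of `config$sheet_rings` rings).
#' @param config A [sim_config()]; `config$seed` seeds all randomness unless
#'   `seed` is given.
#' @param seed Optional seed overriding `config$seed`.
#' @param signaling_only If `TRUE`, freeze all motion, property dynamics,
#'   behaviors and noise: only gene regulation and diffusion run.
#' @return A `trajectory`: list with `final` (morphology), `snapshots`
#'   (list of morphologies, if `snapshot_every > 0`), `termination_reason`
#'   (`"max_steps"`, `"max_nodes"`, `"aberrant"` or `"steady"`),
#'   `aberrant_reason`, `steps`, `time`, and `seed`.
#' @export
run_development <- function(mech, initial = NULL, config = sim_config(),
                            seed = NULL, signaling_only = FALSE) {
  if (is.null(initial)) {
    initial <- build_initial_morphology(config$sheet_rings,
                                        mech$gradient_gene, mech$n_genes)
  }
  if (is.null(seed)) seed <- config$seed
  stopifnot(n_genes_of(initial) == mech$n_genes)
  ar <- mech_arrays(mech)
  clamp <- if (config$maintained_gradient) mech$gradient_gene else 0L
  st <- morph_to_state(initial)
  with_seed(seed, {
    snapshots <- list()
    reason <- "max_steps"
    ab_reason <- NA_character_
    dt <- config$dt_init
    quiet_run <- 0L
    step <- 0L
    stepper <- make_stepper(st, ar, clamp, config, signaling_only)
    n_nodes_last <- length(st$kind)
    while (step < config$max_steps) {
      step <- step + 1L
      if (length(st$kind) != n_nodes_last) {
        stepper <- make_stepper(st, ar, clamp, config, signaling_only)
        n_nodes_last <- length(st$kind)
      }
      y <- pack_state(st)
      # step-doubling error control every control_every-th step; plain RK4
      # with the last accepted step size in between
      if ((step - 1L) %% config$control_every == 0L) {
        res <- adaptive_step(y, dt, stepper, config)
        dt_used <- res$dt_used
        dt <- res$dt_next
        ynew <- res$y
      } else {
        dt_used <- dt
        ynew <- stepper(y, dt)
        if (!all(is.finite(ynew))) {
          res <- adaptive_step(y, dt / 2, stepper, config)
          dt_used <- res$dt_used
          dt <- res$dt_next
          ynew <- res$y
        }
      }
      st_new <- unpack_into(st, ynew)
      dpos <- max(abs(st_new$P - st$P))
      dexpr <- max(abs(st_new$E - st$E))
      st <- clamp_state(st_new, config)
      st$time <- st$time + dt_used

      if (!signaling_only) {
        st <- apply_behaviors_state(st, mech, dt_used, config)
        if (config$noise_amplitude > 0) {
          st <- add_position_noise(st, config)
        }
      }

      if (sum(st$kind != 4L) >= config$max_nodes) {
        reason <- "max_nodes"
        break
      }
      if (!signaling_only && step %% 10L == 0L) {
        ab <- detect_aberrant_state(st, config)
        if (ab$aberrant) {
          reason <- "aberrant"
          ab_reason <- ab$reason
          break
        }
      }
      quiet <- dexpr < config$steady_expr_tol &&
        (signaling_only || dpos < config$steady_pos_tol)
      quiet_run <- if (quiet) quiet_run + 1L else 0L
      if (quiet_run >= config$steady_window) {
        reason <- "steady"
        break
      }
      if (config$snapshot_every > 0 && step %% config$snapshot_every == 0L) {
        snapshots[[length(snapshots) + 1L]] <- state_to_morph(st)
      }
    }
    final <- state_to_morph(st)
    if (reason != "aberrant") {
      ab <- detect_aberrant(final, config)
      if (ab$aberrant) {
        reason <- "aberrant"
        ab_reason <- ab$reason
      }
    }
    structure(
      list(final = final, snapshots = snapshots,
           termination_reason = reason, aberrant_reason = ab_reason,
           steps = step, time = st$time, seed = seed),
      class = "trajectory")
  })
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %d steps, t = %.3g, terminated: %s%s; final: ",
    x$steps, x$time, x$termination_reason,
    if (!is.na(x$aberrant_reason)) paste0(" (", x$aberrant_reason, ")") else ""))
  print(x$final)
  invisible(x)
}

#' Tidy a trajectory into a node table over time
#'
#' @param x A `trajectory`.
#' @param ... Unused.
#' @return Node tibble with a `time` column, stacking any snapshots and the
#'   final morphology.
#' @export
tidy.trajectory <- function(x, ...) {
  snaps <- c(x$snapshots, list(x$final))
  dplyr::bind_rows(lapply(snaps, function(m) {
    dplyr::mutate(m$nodes, time = m$time, .before = 1)
  }))
}
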