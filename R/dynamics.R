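coupling_code <- function(target) {
  match(target, COUPLING_TARGETS)
}

mech_arrays <- function(mech) {
  list(
    T = mech$T,
    deg = mech$gene_specs$degradation_rate,
    D = ifelse(mech$gene_specs$diffusible, mech$gene_specs$diffusion_rate, 0),
    cp_gene = as.integer(mech$couplings$gene),
    cp_code = as.integer(coupling_code(mech$couplings$target)),
    cp_strength = as.numeric(mech$couplings$strength)
  )
}

rk4_matrix <- function(y, dt, f) {
  k1 <- f(y)
  k2 <- f(y + dt / 2 * k1)
  k3 <- f(y + dt / 2 * k2)
  k4 <- f(y + dt * k3)
  y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Advance gene regulation by one time step
#'
#' Per node `i` and gene `k`, expression follows
#' `dg_ik/dt = phi(sum_l t_lk * g_il) - mu_k * g_ik`, where `phi` is the
#' non-negative saturating activation `phi(x) = max(0, x) / (1 + max(0, x))`.
#' One classical RK4 step of size `dt` is taken on the regulation dynamics
#' alone; expression is clamped at zero (the continuous dynamics cannot
#' cross zero, but a discrete step can slightly undershoot).  The maintained
#' gradient gene, if configured, is held fixed.
#'
#' @param m A `morphology`.
#' @param mech A `dev_mechanism`.
#' @param dt Time step (> 0).
#' @param config A [sim_config()].
#' @return The morphology with updated expression.
#' @export
regulation_step <- function(m, mech, dt, config = sim_config()) {
  stopifnot(dt > 0)
  st <- morph_to_state(m)
  ar <- mech_arrays(mech)
  clamp <- if (config$maintained_gradient) mech$gradient_gene else 0L
  E <- rk4_matrix(st$E, dt, function(E) {
    cpp_regulation_deriv(E, ar$T, ar$deg, st$kind, clamp)
  })
  st$E <- pmax(E, 0)
  st$time <- st$time + dt
  state_to_morph(st)
}

#' Advance extracellular diffusion by one time step
#'
#' For each diffusible gene product, concentrations exchange over the
#' node-contact graph (pairs closer than their summed adhesion radii) by a
#' discrete Laplacian weighted by the diffusion rate and the inverse squared
#' pair distance.  The exchange is antisymmetric per pair, so the total
#' amount is conserved up to degradation (which this step does not apply).
#' ECM nodes carry no gene products and are excluded.
#'
#' @inheritParams regulation_step
#' @return The morphology with updated expression.
#' @export
diffusion_step <- function(m, mech, dt, config = sim_config()) {
  stopifnot(dt > 0)
  st <- morph_to_state(m)
  ar <- mech_arrays(mech)
  clamp <- if (config$maintained_gradient) mech$gradient_gene else 0L
  E <- rk4_matrix(st$E, dt, function(E) {
    cpp_diffusion_deriv(st$P, E, st$props, st$kind, ar$D, clamp)
  })
  st$E <- pmax(E, 0)
  st$time <- st$time + dt
  state_to_morph(st)
}
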