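#' Sphere-sphere pair forces
#'
#' Computes the adhesion/repulsion force field over all unordered node pairs
#' in contact.  Two nodes interact when their distance `d` is below the sum
#' of their adhesion radii (`d_ADD`); they repel below the sum of their
#' equilibrium radii (`d_EQD`) and attract between `d_EQD` and `d_ADD`.  The
#' force law is piecewise in `d`: repulsion `k_rep * (d_EQD - d)`, adhesion
#' `k_adh * (d - d_EQD) * (d_ADD - d) / (d_ADD - d_EQD)` (zero at both ends
#' and continuous at `d_EQD`; see [pair_potential()]).  The force acts
#' center-to-center for sphere pairs, parallel to the apical-basal axis for
#' face contacts with an epithelial node, and perpendicular to it for
#' lateral epithelial contacts.  Pair contributions are equal and opposite.
#'
#' @param m A `morphology`.
#' @param config A [sim_config()] (supplies the stiffness constants).
#' @return Tibble with columns `id`, `fx`, `fy`, `fz`.
#' @export
pair_forces <- function(m, config = sim_config()) {
  st <- morph_to_state(m)
  if (any(!is.finite(st$P))) abort("non-finite node positions")
  F <- cpp_pair_forces(st$P, st$props, st$kind, st$partner,
                       config$k_rep, config$k_adh)
  tibble::tibble(id = m$nodes$id, fx = F[, 1], fy = F[, 2], fz = F[, 3])
}

#' Epithelium-specific forces
#'
#' Adds the three cylinder forces: (i) the unbreakable apical-basal spring
#' with rest length `d_EQS` (sum of the two `p_EQS`), restoring along the
#' spring axis; (ii) a bending force, scaled by `p_ERP`, that drives each
#' same-side neighbor connection vector toward a right angle with the
#' apical-basal axis (applied along the axis, i.e. normal to the local
#' surface); and (iii) a torsional force along the same-side connection
#' vector, scaled by `p_EST`, that penalizes shear between the apical and
#' basal spacing of neighboring cells.
#'
#' @inheritParams pair_forces
#' @return Tibble with columns `id`, `fx`, `fy`, `fz`.
#' @export
epithelial_forces <- function(m, config = sim_config()) {
  st <- morph_to_state(m)
  F <- cpp_epithelial_forces(st$P, st$props, st$kind, st$partner,
                             config$k_spring, config$k_bend, config$k_tors)
  tibble::tibble(id = m$nodes$id, fx = F[, 1], fy = F[, 2], fz = F[, 3])
}

#' Pair interaction potential
#'
#' The scalar potential whose negative derivative in the pair distance is
#' the sphere-sphere force magnitude: quadratic repulsion below `d_EQD`,
#' and a smooth adhesion well between `d_EQD` and `d_ADD` obtained by
#' integrating the tent-shaped attraction.  Constant (zero) beyond `d_ADD`.
#'
#' @param d Pair distance(s).
#' @param d_eqd Summed equilibrium radii of the pair.
#' @param d_add Summed adhesion radii of the pair.
#' @param k_rep,k_adh Stiffness constants.
#' @return Potential energy value(s).
#' @export
pair_potential <- function(d, d_eqd, d_add, k_rep = 5, k_adh = 5) {
  w <- d_add - d_eqd
  # adhesion branch: U(d) = -k_adh/w * integral (s-d_eqd)(d_add-s) ds,
  # measured from d_add so that U(d_add) = 0
  adh_int <- function(x) {
    s <- x - d_eqd
    (w * s^2 / 2 - s^3 / 3) / w
  }
  U <- numeric(length(d))
  well <- -k_adh * adh_int(d_add)  # depth at d_eqd relative to zero at d_add
  rep_br <- d < d_eqd
  mid <- d >= d_eqd & d < d_add
  U[rep_br] <- k_rep * (d_eqd - d[rep_br])^2 / 2 + well
  U[mid] <- -k_adh * (adh_int(d_add) - adh_int(d[mid]))
  U[d >= d_add] <- 0
  U
}

#' Total bending energy of an epithelium
#'
#' The energy functional whose (axis-frozen) gradient is the bending and
#' torsional force field of [epithelial_forces()]: for each same-side
#' contacting neighbor pair, a quadratic penalty on the out-of-plane
#' component of the connection vector (scaled by `p_ERP`) plus a quadratic
#' penalty on the apical-basal spacing difference (scaled by `p_EST`).
#'
#' @inheritParams pair_forces
#' @return Scalar energy.
#' @export
bending_energy <- function(m, config = sim_config()) {
  st <- morph_to_state(m)
  P <- st$P
  kind <- st$kind
  partner <- st$partner
  total <- 0
  epi <- which(kind <= 2L)
  for (i in epi) {
    ai <- axis_of(P, kind, partner, i)
    for (j in epi[epi > i]) {
      if (kind[j] != kind[i] || partner[i] == j) next
      r <- P[j, ] - P[i, ]
      if (sum(r^2) >= (st$props[i, 1] + st$props[j, 1])^2) next
      aj <- axis_of(P, kind, partner, j)
      total <- total +
        config$k_bend * st$props[i, 4] * sum(r * ai)^2 / 2 +
        config$k_bend * st$props[j, 4] * sum(r * aj)^2 / 2
      if (kind[i] == 1L) {
        q <- P[partner[j], ] - P[partner[i], ]
        kt <- config$k_tors * (st$props[i, 5] + st$props[j, 5]) / 2
        total <- total + kt * (sqrt(sum(r^2)) - sqrt(sum(q^2)))^2 / 2
      }
    }
  }
  total
}

# basal->apical unit axis of the cell owning epithelial node i
axis_of <- function(P, kind, partner, i) {
  sgn <- if (kind[i] == 1L) 1 else -1
  a <- sgn * (P[i, ] - P[partner[i], ])
  a / sqrt(sum(a^2))
}
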