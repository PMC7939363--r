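// Derivative evaluations for the cell-center developmental model.
//
// Nodes are spheres (mesenchymal, ECM) or halves of epithelial cylinders
// (apical/basal pairs).  Kind codes: 1 apical, 2 basal, 3 mesenchymal,
// 4 ECM.  `partner` holds the 1-based row of the other node of the same
// epithelial cell (0 otherwise).  Property columns: 0 p_ADD, 1 p_EQD,
// 2 p_EQS, 3 p_ERP, 4 p_EST, 5 p_PHA.
//
// Matrices are accessed through raw column-major pointers in the inner
// loops; the basal->apical unit axes are precomputed once per evaluation.

#include <Rcpp.h>
using namespace Rcpp;

static const double COS45 = 0.70710678118654752;

// precompute basal->apical unit axes; ok[i] false for non-epithelial or
// degenerate nodes
static void all_axes(const double* P, int n, const int* kind,
                     const int* partner, std::vector<double>& A,
                     std::vector<char>& ok) {
  A.assign(3 * n, 0.0);
  ok.assign(n, 0);
  for (int i = 0; i < n; ++i) {
    int k = kind[i];
    if (k > 2 || partner[i] == 0) continue;
    int p = partner[i] - 1;
    double sgn = (k == 1) ? 1.0 : -1.0;
    double ax = sgn * (P[i] - P[p]);
    double ay = sgn * (P[i + n] - P[p + n]);
    double az = sgn * (P[i + 2 * n] - P[p + 2 * n]);
    double nn = std::sqrt(ax * ax + ay * ay + az * az);
    if (nn < 1e-12) continue;
    A[3 * i] = ax / nn;
    A[3 * i + 1] = ay / nn;
    A[3 * i + 2] = az / nn;
    ok[i] = 1;
  }
}

static void pair_forces_impl(const double* P, const double* props, int n,
                             const int* kind, const int* partner,
                             double k_rep, double k_adh, double* F) {
  std::vector<double> A;
  std::vector<char> okv;
  all_axes(P, n, kind, partner, A, okv);
  const double* ADD = props;          // column 0
  const double* EQD = props + n;      // column 1
  for (int i = 0; i < n; ++i) {
    double xi = P[i], yi = P[i + n], zi = P[i + 2 * n];
    for (int j = i + 1; j < n; ++j) {
      if (partner[i] == j + 1) continue;  // same cell: handled by the spring
      double rx = xi - P[j], ry = yi - P[j + n], rz = zi - P[j + 2 * n];
      double dADD = ADD[i] + ADD[j];
      double d2 = rx * rx + ry * ry + rz * rz;
      if (d2 >= dADD * dADD) continue;
      double d = std::sqrt(d2);
      if (d < 1e-12) continue;
      if (!R_finite(d)) stop("non-finite node positions");
      double dEQD = EQD[i] + EQD[j];
      double m;
      if (d < dEQD) {
        m = k_rep * (dEQD - d);  // repulsion
      } else {
        double w = dADD - dEQD;
        if (w < 1e-12) continue;
        m = -k_adh * (d - dEQD) * (dADD - d) / w;  // adhesion
      }
      double ux = rx / d, uy = ry / d, uz = rz / d;
      double dx = ux, dy = uy, dz = uz;
      bool ei = okv[i], ej = okv[j];
      if (ei || ej) {
        double amx, amy, amz;
        if (ei && ej) {
          const double* ai = &A[3 * i];
          const double* aj = &A[3 * j];
          double dot = ai[0] * aj[0] + ai[1] * aj[1] + ai[2] * aj[2];
          double s = (dot < 0) ? -1.0 : 1.0;
          amx = ai[0] + s * aj[0];
          amy = ai[1] + s * aj[1];
          amz = ai[2] + s * aj[2];
          double nm = std::sqrt(amx * amx + amy * amy + amz * amz);
          if (nm < 1e-9) { amx = ai[0]; amy = ai[1]; amz = ai[2]; }
          else { amx /= nm; amy /= nm; amz /= nm; }
        } else {
          const double* a1 = ei ? &A[3 * i] : &A[3 * j];
          amx = a1[0]; amy = a1[1]; amz = a1[2];
        }
        double c = ux * amx + uy * amy + uz * amz;
        bool lateral;
        if (ei && ej && kind[i] == kind[j]) {
          lateral = true;   // same-side epithelial contact
        } else if (ei && ej) {
          lateral = false;  // apical-vs-basal face contact
        } else {
          lateral = std::fabs(c) <= COS45;  // sphere vs epithelial node
        }
        if (lateral) {
          double tx = ux - c * amx, ty = uy - c * amy, tz = uz - c * amz;
          double nt = std::sqrt(tx * tx + ty * ty + tz * tz);
          if (nt > 1e-9) { dx = tx / nt; dy = ty / nt; dz = tz / nt; }
        } else {
          double s = (c < 0) ? -1.0 : 1.0;
          dx = s * amx; dy = s * amy; dz = s * amz;
        }
      }
      F[i] += m * dx; F[i + n] += m * dy; F[i + 2 * n] += m * dz;
      F[j] -= m * dx; F[j + n] -= m * dy; F[j + 2 * n] -= m * dz;
    }
  }
}

static void epithelial_forces_impl(const double* P, const double* props,
                                   int n, const int* kind,
                                   const int* partner, double k_spring,
                                   double k_bend, double k_tors, double* F) {
  std::vector<double> A;
  std::vector<char> okv;
  all_axes(P, n, kind, partner, A, okv);
  const double* ADD = props;
  const double* EQS = props + 2 * n;
  const double* ERP = props + 3 * n;
  const double* EST = props + 4 * n;
  // apical-basal springs (unbreakable)
  for (int i = 0; i < n; ++i) {
    int p = partner[i] - 1;
    if (p <= i) continue;
    double rx = P[i] - P[p], ry = P[i + n] - P[p + n],
           rz = P[i + 2 * n] - P[p + 2 * n];
    double d = std::sqrt(rx * rx + ry * ry + rz * rz);
    if (d < 1e-12) continue;
    double m = -k_spring * (d - (EQS[i] + EQS[p])) / d;
    F[i] += m * rx; F[i + n] += m * ry; F[i + 2 * n] += m * rz;
    F[p] -= m * rx; F[p + n] -= m * ry; F[p + 2 * n] -= m * rz;
  }
  // bending + torsion between same-side epithelial neighbors in contact
  for (int i = 0; i < n; ++i) {
    if (kind[i] > 2) continue;
    for (int j = i + 1; j < n; ++j) {
      if (kind[j] != kind[i] || partner[i] == j + 1) continue;
      double rx = P[j] - P[i], ry = P[j + n] - P[i + n],
             rz = P[j + 2 * n] - P[i + 2 * n];
      double dADD = ADD[i] + ADD[j];
      double d2 = rx * rx + ry * ry + rz * rz;
      if (d2 >= dADD * dADD) continue;
      // surface-flattening: drive the neighbor connection vector toward a
      // right angle with each apical-basal axis
      if (okv[i]) {
        const double* ai = &A[3 * i];
        double s = rx * ai[0] + ry * ai[1] + rz * ai[2];
        double f = k_bend * ERP[i] * s;
        F[j] -= f * ai[0]; F[j + n] -= f * ai[1]; F[j + 2 * n] -= f * ai[2];
        F[i] += f * ai[0]; F[i + n] += f * ai[1]; F[i + 2 * n] += f * ai[2];
      }
      if (okv[j]) {
        const double* aj = &A[3 * j];
        double s = -(rx * aj[0] + ry * aj[1] + rz * aj[2]);
        double f = k_bend * ERP[j] * s;
        F[i] -= f * aj[0]; F[i + n] -= f * aj[1]; F[i + 2 * n] -= f * aj[2];
        F[j] += f * aj[0]; F[j + n] += f * aj[1]; F[j + 2 * n] += f * aj[2];
      }
      // torsional (shear) force along the same-side connection: penalize a
      // difference between apical-pair and basal-pair spacing (counted
      // once, from the apical side)
      if (kind[i] == 1 && partner[i] > 0 && partner[j] > 0) {
        int pi = partner[i] - 1, pj = partner[j] - 1;
        double qx = P[pj] - P[pi], qy = P[pj + n] - P[pi + n],
               qz = P[pj + 2 * n] - P[pi + 2 * n];
        double ds = std::sqrt(d2);
        double dq = std::sqrt(qx * qx + qy * qy + qz * qz);
        if (ds > 1e-12 && dq > 1e-12) {
          double kt = k_tors * 0.5 * (EST[i] + EST[j]);
          double delta = ds - dq;
          double gs = kt * delta / ds, gq = kt * delta / dq;
          F[i] -= gs * (-rx); F[i + n] -= gs * (-ry); F[i + 2 * n] -= gs * (-rz);
          F[j] += gs * (-rx); F[j + n] += gs * (-ry); F[j + 2 * n] += gs * (-rz);
          F[pi] += gq * (-qx); F[pi + n] += gq * (-qy); F[pi + 2 * n] += gq * (-qz);
          F[pj] -= gq * (-qx); F[pj + n] -= gq * (-qy); F[pj + 2 * n] -= gq * (-qz);
        }
      }
    }
  }
}

static inline double phi(double x) { return (x > 0) ? x / (1.0 + x) : 0.0; }

static void regulation_impl(const double* E, int n, int G, const double* T,
                            const double* deg, const int* kind,
                            int clamp_gene, double* dE) {
  for (int i = 0; i < n; ++i) {
    if (kind[i] == 4) continue;  // ECM carries no gene dynamics
    for (int k = 0; k < G; ++k) {
      if (k + 1 == clamp_gene) continue;  // maintained input gene
      double h = 0;
      const double* Tk = T + (size_t)k * G;
      for (int l = 0; l < G; ++l) h += Tk[l] * E[i + (size_t)l * n];
      dE[i + (size_t)k * n] = phi(h) - deg[k] * E[i + (size_t)k * n];
    }
  }
}

static void diffusion_impl(const double* P, const double* E,
                           const double* props, int n, int G,
                           const int* kind, const double* D, int clamp_gene,
                           double* dE) {
  std::vector<int> dg;
  for (int k = 0; k < G; ++k) {
    if (D[k] > 0 && k + 1 != clamp_gene) dg.push_back(k);
  }
  if (dg.empty()) return;
  const double* ADD = props;
  for (int i = 0; i < n; ++i) {
    if (kind[i] == 4) continue;
    double xi = P[i], yi = P[i + n], zi = P[i + 2 * n];
    for (int j = i + 1; j < n; ++j) {
      if (kind[j] == 4) continue;
      double rx = xi - P[j], ry = yi - P[j + n], rz = zi - P[j + 2 * n];
      double dADD = ADD[i] + ADD[j];
      double d2 = rx * rx + ry * ry + rz * rz;
      if (d2 >= dADD * dADD || d2 < 1e-24) continue;
      for (size_t q = 0; q < dg.size(); ++q) {
        int k = dg[q];
        double flux = D[k] * (E[j + (size_t)k * n] - E[i + (size_t)k * n]) / d2;
        dE[i + (size_t)k * n] += flux;
        dE[j + (size_t)k * n] -= flux;
      }
    }
  }
}

// coupling target codes (match COUPLING_TARGETS order on the R side):
// 1 division, 2 apoptosis, 3 contraction_apical, 4 contraction_basal,
// 5 contraction_mesenchymal, 6 adhesion, 7 eqs, 8 erp, 9 est
// (10 emt, 11 ecm_secretion: discrete only)
static void property_impl(const double* E, int n, const int* kind,
                          int ncp, const int* cp_gene, const int* cp_code,
                          const double* cp_strength, double* dp) {
  for (int c = 0; c < ncp; ++c) {
    int g = cp_gene[c] - 1, code = cp_code[c];
    double s = cp_strength[c];
    const double* Eg = E + (size_t)g * n;
    for (int i = 0; i < n; ++i) {
      if (kind[i] == 4) continue;
      double v = s * Eg[i];
      switch (code) {
      case 1: dp[i + 5 * n] += v; break;                 // division -> p_PHA
      case 2: dp[i + n] -= v; break;                     // apoptosis shrink
      case 3: if (kind[i] == 1) dp[i + n] += v; break;
      case 4: if (kind[i] == 2) dp[i + n] += v; break;
      case 5: if (kind[i] == 3) dp[i + n] += v; break;
      case 6: dp[i] += v; break;                         // adhesion -> p_ADD
      case 7: if (kind[i] <= 2) dp[i + 2 * n] += v; break;
      case 8: if (kind[i] <= 2) dp[i + 3 * n] += v; break;
      case 9: if (kind[i] <= 2) dp[i + 4 * n] += v; break;
      default: break;
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_pair_forces(const NumericMatrix& P,
                              const NumericMatrix& props,
                              const IntegerVector& kind,
                              const IntegerVector& partner,
                              double k_rep, double k_adh) {
  int n = P.nrow();
  NumericMatrix F(n, 3);
  pair_forces_impl(P.begin(), props.begin(), n, kind.begin(),
                   partner.begin(), k_rep, k_adh, F.begin());
  return F;
}

// [[Rcpp::export]]
NumericMatrix cpp_epithelial_forces(const NumericMatrix& P,
                                    const NumericMatrix& props,
                                    const IntegerVector& kind,
                                    const IntegerVector& partner,
                                    double k_spring, double k_bend,
                                    double k_tors) {
  int n = P.nrow();
  NumericMatrix F(n, 3);
  epithelial_forces_impl(P.begin(), props.begin(), n, kind.begin(),
                         partner.begin(), k_spring, k_bend, k_tors,
                         F.begin());
  return F;
}

// [[Rcpp::export]]
NumericMatrix cpp_regulation_deriv(const NumericMatrix& E,
                                   const NumericMatrix& T,
                                   const NumericVector& deg,
                                   const IntegerVector& kind,
                                   int clamp_gene) {
  int n = E.nrow(), G = E.ncol();
  NumericMatrix dE(n, G);
  regulation_impl(E.begin(), n, G, T.begin(), deg.begin(), kind.begin(),
                  clamp_gene, dE.begin());
  return dE;
}

// [[Rcpp::export]]
NumericMatrix cpp_diffusion_deriv(const NumericMatrix& P,
                                  const NumericMatrix& E,
                                  const NumericMatrix& props,
                                  const IntegerVector& kind,
                                  const NumericVector& D,
                                  int clamp_gene) {
  int n = P.nrow(), G = E.ncol();
  NumericMatrix dE(n, G);
  diffusion_impl(P.begin(), E.begin(), props.begin(), n, G, kind.begin(),
                 D.begin(), clamp_gene, dE.begin());
  return dE;
}

// [[Rcpp::export]]
NumericMatrix cpp_property_deriv(const NumericMatrix& E,
                                 const IntegerVector& kind,
                                 const IntegerVector& cp_gene,
                                 const IntegerVector& cp_code,
                                 const NumericVector& cp_strength) {
  int n = E.nrow();
  NumericMatrix dp(n, 6);
  property_impl(E.begin(), n, kind.begin(), cp_gene.size(),
                cp_gene.begin(), cp_code.begin(), cp_strength.begin(),
                dp.begin());
  return dp;
}

// combined derivative of the flat state vector c(P, E, props); operating on
// plain vectors avoids repacking overhead in the RK driver
// [[Rcpp::export]]
NumericVector cpp_state_derivs(const NumericVector& y, int n, int G,
                               const IntegerVector& kind,
                               const IntegerVector& partner,
                               const NumericMatrix& T,
                               const NumericVector& deg,
                               const NumericVector& D,
                               const IntegerVector& cp_gene,
                               const IntegerVector& cp_code,
                               const NumericVector& cp_strength,
                               int clamp_gene, double k_rep, double k_adh,
                               double k_spring, double k_bend, double k_tors,
                               bool frozen) {
  const double* P = y.begin();
  const double* E = P + 3 * (size_t)n;
  const double* props = E + (size_t)n * G;
  NumericVector dy(y.size());  // zero-initialized
  double* dP = dy.begin();
  double* dE = dP + 3 * (size_t)n;
  double* dp = dE + (size_t)n * G;
  regulation_impl(E, n, G, T.begin(), deg.begin(), kind.begin(), clamp_gene,
                  dE);
  diffusion_impl(P, E, props, n, G, kind.begin(), D.begin(), clamp_gene, dE);
  if (!frozen) {
    pair_forces_impl(P, props, n, kind.begin(), partner.begin(), k_rep,
                     k_adh, dP);
    epithelial_forces_impl(P, props, n, kind.begin(), partner.begin(),
                           k_spring, k_bend, k_tors, dP);
    property_impl(E, n, kind.begin(), cp_gene.size(), cp_gene.begin(),
                  cp_code.begin(), cp_strength.begin(), dp);
  }
  return dy;
}

// classical RK4 step on the flat state
// [[Rcpp::export]]
NumericVector cpp_rk4_step(const NumericVector& y, double dt, int n, int G,
                           const IntegerVector& kind,
                           const IntegerVector& partner,
                           const NumericMatrix& T, const NumericVector& deg,
                           const NumericVector& D,
                           const IntegerVector& cp_gene,
                           const IntegerVector& cp_code,
                           const NumericVector& cp_strength, int clamp_gene,
                           double k_rep, double k_adh, double k_spring,
                           double k_bend, double k_tors, bool frozen) {
  size_t m = y.size();
  NumericVector k1 = cpp_state_derivs(y, n, G, kind, partner, T, deg, D,
                                      cp_gene, cp_code, cp_strength,
                                      clamp_gene, k_rep, k_adh, k_spring,
                                      k_bend, k_tors, frozen);
  NumericVector tmp(m);
  for (size_t i = 0; i < m; ++i) tmp[i] = y[i] + dt / 2 * k1[i];
  NumericVector k2 = cpp_state_derivs(tmp, n, G, kind, partner, T, deg, D,
                                      cp_gene, cp_code, cp_strength,
                                      clamp_gene, k_rep, k_adh, k_spring,
                                      k_bend, k_tors, frozen);
  for (size_t i = 0; i < m; ++i) tmp[i] = y[i] + dt / 2 * k2[i];
  NumericVector k3 = cpp_state_derivs(tmp, n, G, kind, partner, T, deg, D,
                                      cp_gene, cp_code, cp_strength,
                                      clamp_gene, k_rep, k_adh, k_spring,
                                      k_bend, k_tors, frozen);
  for (size_t i = 0; i < m; ++i) tmp[i] = y[i] + dt * k3[i];
  NumericVector k4 = cpp_state_derivs(tmp, n, G, kind, partner, T, deg, D,
                                      cp_gene, cp_code, cp_strength,
                                      clamp_gene, k_rep, k_adh, k_spring,
                                      k_bend, k_tors, frozen);
  NumericVector out(m);
  for (size_t i = 0; i < m; ++i) {
    out[i] = y[i] + dt / 6 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
  }
  return out;
}

// symmetrized mean nearest-node distance between two point clouds
// [[Rcpp::export]]
double cpp_emd(const NumericMatrix& A, const NumericMatrix& B) {
  int n1 = A.nrow(), n2 = B.nrow();
  double total = 0;
  for (int i = 0; i < n1; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < n2; ++j) {
      double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1),
             dz = A(i, 2) - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    total += std::sqrt(best);
  }
  for (int j = 0; j < n2; ++j) {
    double best = R_PosInf;
    for (int i = 0; i < n1; ++i) {
      double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1),
             dz = A(i, 2) - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    total += std::sqrt(best);
  }
  return total / (n1 + n2);
}
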