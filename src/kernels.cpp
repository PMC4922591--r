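#include <Rcpp.h>
using namespace Rcpp;

// Surrogate potential used by the fallback relaxation backend:
//   * harmonic pseudo-bonds between sequential CA atoms of one chain,
//     at reference distances r0 (k_bond per A^2)
//   * quadratic soft-sphere repulsion k_rep*(sigma-d)^2 between heavy
//     atoms of residues >= 2 apart in sequence (or different chains)
// Coordinates are a flat vector (x1,y1,z1,x2,...). Returns energy and,
// if grad = true, the analytic gradient on the same layout.
// [[Rcpp::export]]
List surrogate_eval(NumericVector xyz,
                    IntegerVector ca_i, IntegerVector ca_j,
                    NumericVector r0,
                    IntegerVector heavy_idx,
                    IntegerVector res_of_heavy,
                    IntegerVector chain_of_heavy,
                    double k_bond, double k_rep, double sigma,
                    bool grad) {
  const int n = xyz.size() / 3;
  double energy = 0.0;
  NumericVector g(grad ? xyz.size() : 0);

  // pseudo-bond terms
  for (int b = 0; b < ca_i.size(); ++b) {
    int i = ca_i[b], j = ca_j[b];
    double dx = xyz[3*j] - xyz[3*i];
    double dy = xyz[3*j+1] - xyz[3*i+1];
    double dz = xyz[3*j+2] - xyz[3*i+2];
    double d = std::sqrt(dx*dx + dy*dy + dz*dz);
    double dev = d - r0[b];
    energy += k_bond * dev * dev;
    if (grad && d > 1e-12) {
      double c = 2.0 * k_bond * dev / d;
      g[3*i]   -= c * dx; g[3*i+1] -= c * dy; g[3*i+2] -= c * dz;
      g[3*j]   += c * dx; g[3*j+1] += c * dy; g[3*j+2] += c * dz;
    }
  }

  // soft-sphere repulsion over heavy-atom pairs with residue sep >= 2
  const int nh = heavy_idx.size();
  const double sig2 = sigma * sigma;
  for (int a = 0; a < nh; ++a) {
    int ia = heavy_idx[a];
    double ax = xyz[3*ia], ay = xyz[3*ia+1], az = xyz[3*ia+2];
    int ra = res_of_heavy[a], ca = chain_of_heavy[a];
    for (int b = a + 1; b < nh; ++b) {
      if (chain_of_heavy[b] == ca && std::abs(res_of_heavy[b] - ra) < 2)
        continue;
      int ib = heavy_idx[b];
      double dx = xyz[3*ib] - ax;
      double dy = xyz[3*ib+1] - ay;
      double dz = xyz[3*ib+2] - az;
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 >= sig2) continue;
      double d = std::sqrt(d2);
      double dev = sigma - d;
      energy += k_rep * dev * dev;
      if (grad && d > 1e-12) {
        double c = -2.0 * k_rep * dev / d;  // dE/dd = -2 k dev
        g[3*ia]   -= c * dx; g[3*ia+1] -= c * dy; g[3*ia+2] -= c * dz;
        g[3*ib]   += c * dx; g[3*ib+1] += c * dy; g[3*ib+2] += c * dz;
      }
    }
  }
  if (grad) return List::create(_["energy"] = energy, _["gradient"] = g);
  return List::create(_["energy"] = energy);
}

// Contact-count weights for the elastic network: for each residue pair
// (i < j), the number of heavy-atom pairs (one atom in each residue)
// within the cutoff. Returns a triplet list over pairs with count >= 1.
// [[Rcpp::export]]
List contact_counts(NumericMatrix xyz, IntegerVector res_index,
                    double cutoff) {
  const int n = xyz.nrow();
  const double c2 = cutoff * cutoff;
  std::map<std::pair<int,int>, int> counts;
  for (int a = 0; a < n; ++a) {
    double ax = xyz(a,0), ay = xyz(a,1), az = xyz(a,2);
    int ra = res_index[a];
    for (int b = a + 1; b < n; ++b) {
      int rb = res_index[b];
      if (rb == ra) continue;
      double dx = xyz(b,0) - ax, dy = xyz(b,1) - ay, dz = xyz(b,2) - az;
      if (dx*dx + dy*dy + dz*dz <= c2) {
        std::pair<int,int> key = ra < rb ? std::make_pair(ra, rb)
                                         : std::make_pair(rb, ra);
        counts[key] += 1;
      }
    }
  }
  const int m = counts.size();
  IntegerVector ii(m), jj(m), ww(m);
  int k = 0;
  for (std::map<std::pair<int,int>, int>::iterator it = counts.begin();
       it != counts.end(); ++it, ++k) {
    ii[k] = it->first.first;
    jj[k] = it->first.second;
    ww[k] = it->second;
  }
  return List::create(_["i"] = ii, _["j"] = jj, _["count"] = ww);
}

// Neighbor pair list for the soft-sphere term: heavy-atom pairs with
// residue separation >= 2 (or different chains) currently within
// sigma + margin. Rebuilt by the caller when atoms drift.
// [[Rcpp::export]]
List surrogate_pairs(NumericVector xyz,
                     IntegerVector heavy_idx,
                     IntegerVector res_of_heavy,
                     IntegerVector chain_of_heavy,
                     double sigma, double margin) {
  const int nh = heavy_idx.size();
  const double lim2 = (sigma + margin) * (sigma + margin);
  std::vector<int> pi, pj;
  for (int a = 0; a < nh; ++a) {
    int ia = heavy_idx[a];
    double ax = xyz[3*ia], ay = xyz[3*ia+1], az = xyz[3*ia+2];
    int ra = res_of_heavy[a], ca = chain_of_heavy[a];
    for (int b = a + 1; b < nh; ++b) {
      if (chain_of_heavy[b] == ca && std::abs(res_of_heavy[b] - ra) < 2)
        continue;
      int ib = heavy_idx[b];
      double dx = xyz[3*ib] - ax, dy = xyz[3*ib+1] - ay,
             dz = xyz[3*ib+2] - az;
      if (dx*dx + dy*dy + dz*dz <= lim2) { pi.push_back(ia); pj.push_back(ib); }
    }
  }
  return List::create(_["i"] = wrap(pi), _["j"] = wrap(pj));
}

// Surrogate energy + gradient over an explicit repulsion pair list.
// [[Rcpp::export]]
List surrogate_eval_pairs(NumericVector xyz,
                          IntegerVector ca_i, IntegerVector ca_j,
                          NumericVector r0,
                          IntegerVector rep_i, IntegerVector rep_j,
                          double k_bond, double k_rep, double sigma,
                          bool grad) {
  double energy = 0.0;
  NumericVector g(grad ? xyz.size() : 0);
  for (int b = 0; b < ca_i.size(); ++b) {
    int i = ca_i[b], j = ca_j[b];
    double dx = xyz[3*j] - xyz[3*i];
    double dy = xyz[3*j+1] - xyz[3*i+1];
    double dz = xyz[3*j+2] - xyz[3*i+2];
    double d = std::sqrt(dx*dx + dy*dy + dz*dz);
    double dev = d - r0[b];
    energy += k_bond * dev * dev;
    if (grad && d > 1e-12) {
      double c = 2.0 * k_bond * dev / d;
      g[3*i]   -= c * dx; g[3*i+1] -= c * dy; g[3*i+2] -= c * dz;
      g[3*j]   += c * dx; g[3*j+1] += c * dy; g[3*j+2] += c * dz;
    }
  }
  const double sig2 = sigma * sigma;
  for (int p = 0; p < rep_i.size(); ++p) {
    int ia = rep_i[p], ib = rep_j[p];
    double dx = xyz[3*ib] - xyz[3*ia];
    double dy = xyz[3*ib+1] - xyz[3*ia+1];
    double dz = xyz[3*ib+2] - xyz[3*ia+2];
    double d2 = dx*dx + dy*dy + dz*dz;
    if (d2 >= sig2) continue;
    double d = std::sqrt(d2);
    double dev = sigma - d;
    energy += k_rep * dev * dev;
    if (grad && d > 1e-12) {
      double c = -2.0 * k_rep * dev / d;
      g[3*ia]   -= c * dx; g[3*ia+1] -= c * dy; g[3*ia+2] -= c * dz;
      g[3*ib]   += c * dx; g[3*ib+1] += c * dy; g[3*ib+2] += c * dz;
    }
  }
  if (grad) return List::create(_["energy"] = energy, _["gradient"] = g);
  return List::create(_["energy"] = energy);
}

// --- quaternion (Horn) least-squares superposition -------------------
// Jacobi eigendecomposition of a symmetric 4x4 matrix.
static void jacobi4(double A[4][4], double V[4][4], double d[4]) {
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) V[i][j] = (i == j) ? 1.0 : 0.0;
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off = 0.0;
    for (int p = 0; p < 3; ++p)
      for (int q = p + 1; q < 4; ++q) off += A[p][q] * A[p][q];
    if (off < 1e-22) break;
    for (int p = 0; p < 3; ++p)
      for (int q = p + 1; q < 4; ++q) {
        if (std::fabs(A[p][q]) < 1e-18) continue;
        double theta = (A[q][q] - A[p][p]) / (2.0 * A[p][q]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int k = 0; k < 4; ++k) {
          double Apk = A[p][k], Aqk = A[q][k];
          A[p][k] = c * Apk - s * Aqk;
          A[q][k] = s * Apk + c * Aqk;
        }
        for (int k = 0; k < 4; ++k) {
          double Akp = A[k][p], Akq = A[k][q];
          A[k][p] = c * Akp - s * Akq;
          A[k][q] = s * Akp + c * Akq;
        }
        for (int k = 0; k < 4; ++k) {
          double Vkp = V[k][p], Vkq = V[k][q];
          V[k][p] = c * Vkp - s * Vkq;
          V[k][q] = s * Vkp + c * Vkq;
        }
      }
  }
  for (int i = 0; i < 4; ++i) d[i] = A[i][i];
}

// Least-squares rigid superposition of paired point sets (rows).
// Returns rotation R (for row vectors: fitted = mobile * R + t),
// translation t and the residual RMSD. Quaternion formulation gives a
// proper rotation for any non-degenerate input.
// [[Rcpp::export]]
List kabsch_fit(NumericMatrix mobile, NumericMatrix reference) {
  const int n = mobile.nrow();
  double cm[3] = {0,0,0}, cr[3] = {0,0,0};
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      cm[k] += mobile(i,k); cr[k] += reference(i,k);
    }
  for (int k = 0; k < 3; ++k) { cm[k] /= n; cr[k] /= n; }
  double M[3][3] = {{0,0,0},{0,0,0},{0,0,0}};
  double Sa = 0.0, Sb = 0.0;
  for (int i = 0; i < n; ++i) {
    double a[3], b[3];
    for (int k = 0; k < 3; ++k) {
      a[k] = mobile(i,k) - cm[k];
      b[k] = reference(i,k) - cr[k];
      Sa += a[k]*a[k]; Sb += b[k]*b[k];
    }
    for (int p = 0; p < 3; ++p)
      for (int q = 0; q < 3; ++q) M[p][q] += a[p]*b[q];
  }
  double Sxx=M[0][0], Sxy=M[0][1], Sxz=M[0][2];
  double Syx=M[1][0], Syy=M[1][1], Syz=M[1][2];
  double Szx=M[2][0], Szy=M[2][1], Szz=M[2][2];
  double K[4][4] = {
    {Sxx+Syy+Szz, Syz-Szy,      Szx-Sxz,      Sxy-Syx},
    {Syz-Szy,     Sxx-Syy-Szz,  Sxy+Syx,      Szx+Sxz},
    {Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz,  Syz+Szy},
    {Sxy-Syx,     Szx+Sxz,      Syz+Szy,     -Sxx-Syy+Szz}
  };
  double V[4][4], d[4];
  jacobi4(K, V, d);
  int best = 0;
  for (int i = 1; i < 4; ++i) if (d[i] > d[best]) best = i;
  double q0 = V[0][best], q1 = V[1][best], q2 = V[2][best],
         q3 = V[3][best];
  // rotation matrix (column convention: b = Rm a); for row vectors we
  // return its transpose
  double Rm[3][3] = {
    {q0*q0+q1*q1-q2*q2-q3*q3, 2*(q1*q2-q0*q3),         2*(q1*q3+q0*q2)},
    {2*(q1*q2+q0*q3),         q0*q0-q1*q1+q2*q2-q3*q3, 2*(q2*q3-q0*q1)},
    {2*(q1*q3-q0*q2),         2*(q2*q3+q0*q1),         q0*q0-q1*q1-q2*q2+q3*q3}
  };
  NumericMatrix R(3,3);
  for (int p = 0; p < 3; ++p)
    for (int q = 0; q < 3; ++q) R(p,q) = Rm[q][p];
  NumericVector t(3);
  for (int k = 0; k < 3; ++k) {
    double s = 0.0;
    for (int p = 0; p < 3; ++p) s += cm[p] * R(p,k);
    t[k] = cr[k] - s;
  }
  double msd = (Sa + Sb - 2.0 * d[best]) / n;
  if (msd < 0) msd = 0;
  return List::create(_["rotation"] = R, _["translation"] = t,
                      _["rmsd"] = std::sqrt(msd));
}

// RMSD-only fast path.
// [[Rcpp::export]]
double kabsch_rmsd(NumericMatrix mobile, NumericMatrix reference) {
  List r = kabsch_fit(mobile, reference);
  return as<double>(r["rmsd"]);
}
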