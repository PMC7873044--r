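// Metropolis Monte Carlo engine for tethered-domain bead systems.
//
// Energy model (kT units): harmonic virtual bonds, hard-sphere exclusion
// between nonbonded beads of different rigid units, square-well "sticky"
// attractions between declared bead pairs, optional screened Coulomb, and
// an optional hard spherical confinement wall. Moves: single-bead Gaussian
// displacement on flexible beads, pivot rotations of chain subtrees, and
// rigid-body translation/rotation of mobile bodies. All proposals are
// symmetric, so plain Metropolis acceptance samples the Boltzmann
// distribution. Random numbers come from R's generator, so results are
// reproducible with set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double d2(const double* a, const double* b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

// Rodrigues rotation of v about unit axis u by angle th, in place
static inline void rotate(double* v, const double* u, double c, double s) {
  double dot = u[0] * v[0] + u[1] * v[1] + u[2] * v[2];
  double cx = u[1] * v[2] - u[2] * v[1];
  double cy = u[2] * v[0] - u[0] * v[2];
  double cz = u[0] * v[1] - u[1] * v[0];
  double r0 = v[0] * c + cx * s + u[0] * dot * (1.0 - c);
  double r1 = v[1] * c + cy * s + u[1] * dot * (1.0 - c);
  double r2 = v[2] * c + cz * s + u[2] * dot * (1.0 - c);
  v[0] = r0; v[1] = r1; v[2] = r2;
}

static inline void rand_axis(double* u) {
  double n2 = 0.0;
  do {
    u[0] = norm_rand(); u[1] = norm_rand(); u[2] = norm_rand();
    n2 = u[0] * u[0] + u[1] * u[1] + u[2] * u[2];
  } while (n2 < 1e-12);
  double inv = 1.0 / std::sqrt(n2);
  u[0] *= inv; u[1] *= inv; u[2] *= inv;
}

// [[Rcpp::export]]
List mc_run_cpp(NumericMatrix coords0, IntegerVector kind, IntegerVector unit,
                IntegerMatrix bonds, NumericVector bond_b0,
                NumericVector bond_k, IntegerMatrix sticky,
                NumericVector sticky_eps, NumericVector sticky_w,
                NumericVector charge, double bjerrum, double debye,
                double hard_core, double confine_radius, List bodies,
                List segments, IntegerVector seg_npivot, int n_steps,
                int record_interval, int n_equil, double temp,
                double step_disp, double step_trans, double step_rot,
                double step_pivot) {
  const int n = coords0.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords0(i, d);

  const int nb = bonds.nrow();
  std::vector<int> bi(nb), bj(nb);
  for (int b = 0; b < nb; ++b) { bi[b] = bonds(b, 0) - 1; bj[b] = bonds(b, 1) - 1; }
  std::vector<char> bonded((size_t)n * n, 0);
  for (int b = 0; b < nb; ++b) {
    bonded[(size_t)bi[b] * n + bj[b]] = 1;
    bonded[(size_t)bj[b] * n + bi[b]] = 1;
  }

  const int ns = sticky.nrow();
  std::vector<int> si(ns), sj(ns);
  for (int s = 0; s < ns; ++s) { si[s] = sticky(s, 0) - 1; sj[s] = sticky(s, 1) - 1; }

  bool any_charge = false;
  for (int i = 0; i < n; ++i) if (charge[i] != 0.0) { any_charge = true; break; }

  // mover table: type 0 = flex bead, 1 = body, 2 = segment pivot
  std::vector<int> mtype, mref;
  for (int i = 0; i < n; ++i)
    if (kind[i] == 1) { mtype.push_back(0); mref.push_back(i); }
  for (int b = 0; b < bodies.size(); ++b) { mtype.push_back(1); mref.push_back(b); }
  for (int s = 0; s < segments.size(); ++s)
    if (seg_npivot[s] > 0) { mtype.push_back(2); mref.push_back(s); }
  const int nmov = (int)mtype.size();
  if (nmov == 0) stop("system has no movable degrees of freedom");

  std::vector<std::vector<int> > bodyv(bodies.size()), segv(segments.size());
  for (int b = 0; b < bodies.size(); ++b) {
    IntegerVector v = bodies[b];
    for (int k2 = 0; k2 < v.size(); ++k2) bodyv[b].push_back(v[k2] - 1);
  }
  for (int s = 0; s < segments.size(); ++s) {
    IntegerVector v = segments[s];
    for (int k2 = 0; k2 < v.size(); ++k2) segv[s].push_back(v[k2] - 1);
  }

  const double hc2 = hard_core > 0 ? hard_core * hard_core : -1.0;
  const double conf2 = confine_radius > 0 ? confine_radius * confine_radius : -1.0;

  std::vector<char> inS(n, 0);
  std::vector<int> S;
  std::vector<double> newpos;
  S.reserve(n); newpos.reserve(3 * n);

  const int nrec = n_steps / record_interval;
  NumericVector frames((R_xlen_t)nrec * n * 3);
  long long accepted = 0, attempted = 0;
  int rec = 0;
  const long long total = (long long)n_equil + n_steps;

  for (long long step = 1; step <= total; ++step) {
    // ---- propose ----
    int m = (int)(unif_rand() * nmov); if (m >= nmov) m = nmov - 1;
    S.clear(); newpos.clear();
    if (mtype[m] == 0) {
      int i = mref[m];
      S.push_back(i);
      for (int d = 0; d < 3; ++d)
        newpos.push_back(x[3 * i + d] + step_disp * norm_rand());
    } else if (mtype[m] == 1) {
      const std::vector<int>& bd = bodyv[mref[m]];
      double c[3] = {0, 0, 0};
      for (size_t k2 = 0; k2 < bd.size(); ++k2)
        for (int d = 0; d < 3; ++d) c[d] += x[3 * bd[k2] + d];
      for (int d = 0; d < 3; ++d) c[d] /= (double)bd.size();
      double u[3]; rand_axis(u);
      double th = step_rot * norm_rand();
      double cth = std::cos(th), sth = std::sin(th);
      double t[3];
      for (int d = 0; d < 3; ++d) t[d] = step_trans * norm_rand();
      for (size_t k2 = 0; k2 < bd.size(); ++k2) {
        int i = bd[k2];
        double v[3] = {x[3 * i] - c[0], x[3 * i + 1] - c[1], x[3 * i + 2] - c[2]};
        rotate(v, u, cth, sth);
        S.push_back(i);
        for (int d = 0; d < 3; ++d) newpos.push_back(v[d] + c[d] + t[d]);
      }
    } else {
      const std::vector<int>& sg = segv[mref[m]];
      int npiv = seg_npivot[mref[m]];
      int p = (int)(unif_rand() * npiv); if (p >= npiv) p = npiv - 1;
      const double* c = &x[3 * sg[p]];
      double cc[3] = {c[0], c[1], c[2]};
      double u[3]; rand_axis(u);
      double th = step_pivot * norm_rand();
      double cth = std::cos(th), sth = std::sin(th);
      for (size_t k2 = p + 1; k2 < sg.size(); ++k2) {
        int i = sg[k2];
        double v[3] = {x[3 * i] - cc[0], x[3 * i + 1] - cc[1], x[3 * i + 2] - cc[2]};
        rotate(v, u, cth, sth);
        S.push_back(i);
        for (int d = 0; d < 3; ++d) newpos.push_back(v[d] + cc[d]);
      }
      if (S.empty()) { continue; }
    }
    for (size_t k2 = 0; k2 < S.size(); ++k2) inS[S[k2]] = 1;
    ++attempted;

    // ---- energy difference ----
    bool reject = false;
    double dE = 0.0;

    if (conf2 > 0) {
      for (size_t k2 = 0; k2 < S.size() && !reject; ++k2) {
        const double* p2 = &newpos[3 * k2];
        if (p2[0] * p2[0] + p2[1] * p2[1] + p2[2] * p2[2] > conf2) reject = true;
      }
    }

    // nonbonded: hard core + screened Coulomb, moved vs unmoved
    for (size_t k2 = 0; k2 < S.size() && !reject; ++k2) {
      int i = S[k2];
      const double* pi = &newpos[3 * k2];
      const double* oi = &x[3 * i];
      for (int j = 0; j < n; ++j) {
        if (inS[j]) continue;
        if (bonded[(size_t)i * n + j]) continue;
        if (unit[i] > 0 && unit[i] == unit[j]) continue;
        double dn2 = d2(pi, &x[3 * j]);
        if (hc2 > 0 && dn2 < hc2) { reject = true; break; }
        if (any_charge && charge[i] != 0.0 && charge[j] != 0.0) {
          double rn = std::sqrt(dn2), ro = std::sqrt(d2(oi, &x[3 * j]));
          double qq = bjerrum * charge[i] * charge[j];
          dE += qq * (std::exp(-rn / debye) / rn - std::exp(-ro / debye) / ro);
        }
      }
    }

    if (!reject) {
      // bonds with exactly one endpoint moved
      for (int b = 0; b < nb; ++b) {
        int i = bi[b], j = bj[b];
        bool mi = inS[i], mj = inS[j];
        if (mi == mj) continue;
        int mv = mi ? i : j, fx = mi ? j : i;
        size_t pos = 0;
        for (size_t k2 = 0; k2 < S.size(); ++k2) if (S[k2] == mv) { pos = k2; break; }
        double rn = std::sqrt(d2(&newpos[3 * pos], &x[3 * fx]));
        double ro = std::sqrt(d2(&x[3 * mv], &x[3 * fx]));
        double an = rn - bond_b0[b], ao = ro - bond_b0[b];
        dE += bond_k[b] * (an * an - ao * ao);
      }
      // sticky square wells with exactly one endpoint moved
      for (int s = 0; s < ns; ++s) {
        int i = si[s], j = sj[s];
        bool mi = inS[i], mj = inS[j];
        if (mi == mj) continue;
        int mv = mi ? i : j, fx = mi ? j : i;
        size_t pos = 0;
        for (size_t k2 = 0; k2 < S.size(); ++k2) if (S[k2] == mv) { pos = k2; break; }
        double w2 = sticky_w[s] * sticky_w[s];
        double dn2 = d2(&newpos[3 * pos], &x[3 * fx]);
        double do2 = d2(&x[3 * mv], &x[3 * fx]);
        if (dn2 <= w2) dE -= sticky_eps[s];
        if (do2 <= w2) dE += sticky_eps[s];
      }
    }

    // ---- accept / reject ----
    bool accept = false;
    if (!reject) {
      double dEt = dE / temp;
      accept = (dEt <= 0.0) || (unif_rand() < std::exp(-dEt));
    }
    if (accept) {
      ++accepted;
      for (size_t k2 = 0; k2 < S.size(); ++k2)
        for (int d = 0; d < 3; ++d) x[3 * S[k2] + d] = newpos[3 * k2 + d];
    }
    for (size_t k2 = 0; k2 < S.size(); ++k2) inS[S[k2]] = 0;

    if (step > n_equil && (step - n_equil) % record_interval == 0 && rec < nrec) {
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          frames[(R_xlen_t)rec + (R_xlen_t)nrec * (i + (R_xlen_t)n * d)] = x[3 * i + d];
      ++rec;
    }
  }

  frames.attr("dim") = IntegerVector::create(nrec, n, 3);
  return List::create(_["frames"] = frames,
                      _["accepted"] = (double)accepted,
                      _["attempted"] = (double)attempted);
}
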