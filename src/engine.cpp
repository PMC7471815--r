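// Lattice tumor growth engine. Implements exactly the per-iteration rule
// sequence of the R-level tumor_step()/immune_step() composition, consuming
// the R RNG stream (unif_rand) draw-for-draw in the same order, so a given
// seed yields the identical event trajectory from either implementation.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// State codes (must match CELL_STATES / IMMUNE_STATES on the R side)
static const int NA0 = 0, NA11 = 1, NA12 = 2, NA2 = 3, NA3 = 4;
static const int IA_NONE = 0, IA0 = 1;

static const int OFF_R[8] = {-1, -1, -1, 0, 0, 1, 1, 1};  // row-major order
static const int OFF_C[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

static inline bool is_tumor(int s) { return s >= NA11 && s <= NA3; }
static inline bool is_prolif(int s) { return s == NA11 || s == NA12; }

// Replicates R's mean() for doubles: long-double sum + one refinement pass.
static double mean_r(const std::vector<double>& x) {
  const size_t n = x.size();
  long double s = 0.0L;
  for (size_t i = 0; i < n; ++i) s += x[i];
  s /= (long double)n;
  long double t = 0.0L;
  for (size_t i = 0; i < n; ++i) t += (x[i] - s);
  s += t / (long double)n;
  return (double)s;
}

struct Geometry { double Rt, Rn, Wp; bool empty; };

// Mean distance (in mm) from `centroid` (1-based coords) to the boundary
// cells of `mask`, accumulated in ascending column-major order as R does.
// Boundary: mask cell with an out-of-bounds or non-mask Moore neighbor.
static double mean_boundary_radius(const std::vector<char>& mask, int n,
                                   double cr, double cc, double pitch) {
  std::vector<double> d;
  for (int c = 0; c < n; ++c) {
    for (int r = 0; r < n; ++r) {
      if (!mask[r + c * n]) continue;
      bool boundary = false;
      for (int k = 0; k < 8 && !boundary; ++k) {
        int rr = r + OFF_R[k], cz = c + OFF_C[k];
        if (rr < 0 || rr >= n || cz < 0 || cz >= n || !mask[rr + cz * n])
          boundary = true;
      }
      if (boundary) {
        double dr = (r + 1) - cr, dc = (c + 1) - cc;
        d.push_back(std::sqrt(dr * dr + dc * dc));
      }
    }
  }
  if (d.empty()) return 0.0;
  return pitch * mean_r(d);
}

static void mask_centroid(const std::vector<char>& mask, int n,
                          double& cr, double& cc) {
  long double sr = 0.0L, sc = 0.0L;
  long cnt = 0;
  for (int c = 0; c < n; ++c)
    for (int r = 0; r < n; ++r)
      if (mask[r + c * n]) { sr += r + 1; sc += c + 1; ++cnt; }
  cr = (double)(sr / cnt);
  cc = (double)(sc / cnt);
}

static Geometry geometry(const std::vector<int>& st, int n, double pitch) {
  Geometry g = {0.0, 0.0, 0.0, true};
  std::vector<char> tumor(n * n), necro(n * n), inner(n * n);
  bool anyT = false, anyN = false, anyI = false;
  for (int i = 0; i < n * n; ++i) {
    tumor[i] = is_tumor(st[i]);
    necro[i] = st[i] == NA3;
    inner[i] = tumor[i] && !is_prolif(st[i]);
    anyT |= tumor[i]; anyN |= necro[i]; anyI |= inner[i];
  }
  if (!anyT) return g;
  g.empty = false;
  double cr, cc;
  mask_centroid(tumor, n, cr, cc);
  g.Rt = mean_boundary_radius(tumor, n, cr, cc, pitch);
  if (anyN) {
    double nr, nc;
    mask_centroid(necro, n, nr, nc);
    g.Rn = mean_boundary_radius(necro, n, nr, nc, pitch);
  }
  if (anyI) {
    double wi = mean_boundary_radius(inner, n, cr, cc, pitch);
    g.Wp = std::max(0.0, g.Rt - wi);
  } else {
    g.Wp = g.Rt;
  }
  return g;
}

// Exact squared Euclidean distance (cell units) from every site to the
// nearest non-tumor site. BIG when no non-tumor site exists.
static const double BIG = 1e15;

static void edt_sq(const std::vector<char>& tumor, int n,
                   std::vector<double>& out) {
  std::vector<double> d1(n * n);
  // stage 1: squared distance to nearest non-tumor site within the column
  for (int c = 0; c < n; ++c) {
    double run = BIG;
    for (int r = 0; r < n; ++r) {
      run = tumor[r + c * n] ? (run >= BIG ? BIG : run + 1.0) : 0.0;
      d1[r + c * n] = run;
    }
    run = BIG;
    for (int r = n - 1; r >= 0; --r) {
      run = tumor[r + c * n] ? (run >= BIG ? BIG : run + 1.0) : 0.0;
      double m = std::min(d1[r + c * n], run);
      d1[r + c * n] = (m >= BIG) ? BIG : m * m;
    }
  }
  // stage 2: parabola lower envelope along each row
  std::vector<int> v(n);
  std::vector<double> z(n + 1), f(n);
  for (int r = 0; r < n; ++r) {
    for (int c = 0; c < n; ++c) f[c] = d1[r + c * n];
    int k = 0;
    v[0] = 0;
    z[0] = -std::numeric_limits<double>::infinity();
    z[1] = std::numeric_limits<double>::infinity();
    for (int q = 1; q < n; ++q) {
      double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
                 (2.0 * q - 2.0 * v[k]);
      while (s <= z[k]) {
        --k;
        s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
            (2.0 * q - 2.0 * v[k]);
      }
      ++k;
      v[k] = q;
      z[k] = s;
      z[k + 1] = std::numeric_limits<double>::infinity();
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
      while (z[k + 1] < q) ++k;
      double dc = (double)(q - v[k]);
      out[r + q * n] = dc * dc + f[v[k]];
    }
  }
}

// Fisher-Yates permutation of 0..n-1; n-1 uniforms (matches fy_permute).
static void fy_permute(std::vector<int>& p) {
  const int n = (int)p.size();
  for (int i = 0; i < n; ++i) p[i] = i;
  for (int i = n - 1; i >= 1; --i) {
    int j = (int)(unif_rand() * (i + 1));
    std::swap(p[i], p[j]);
  }
}

// [[Rcpp::export]]
List absm_engine_cpp(IntegerMatrix states0, IntegerMatrix immune0,
                     IntegerMatrix age0, int m0, int v0, int f0, int nBI0,
                     double pitch, List par, int n_steps) {
  const int n = states0.nrow();
  std::vector<int> st(states0.begin(), states0.end());
  std::vector<int> im(immune0.begin(), immune0.end());
  std::vector<int> ag(age0.begin(), age0.end());

  const double p01 = par["p01"], p02 = par["p02"], Nmm = par["Nmm"];
  const int age_max = as<int>(par["age_max"]);
  const double a = par["a"], b = par["b"], R_max = par["R_max"];
  const double K_dT = par["K_dT"], K_dI = par["K_dI"];
  const double rho_t = par["rho_t"], rho_I = par["rho_I"];
  const double recruit_rate = par["recruit_rate"];
  const double activation_nf = par["activation_nf"];
  const double rim_exponent = par["rim_exponent"];
  const int na12_code = as<int>(par["na12_code"]);
  const int expiry_code = as<int>(par["expiry_code"]);

  int m = m0, v = v0, f = f0;
  int n_BI_last = nBI0;

  const int NMET = 24;
  NumericMatrix met(n_steps + 1, NMET);
  std::vector<double> depth2(n * n);
  std::vector<char> tumor(n * n);

  auto record = [&](int row, double divisions, double quiescences,
                    double necroses, double moved, double kills,
                    double losses) {
    int nT = 0, nPT = 0, c11 = 0, c12 = 0, c2 = 0, c3 = 0, nIA = 0;
    for (int i = 0; i < n * n; ++i) {
      if (is_tumor(st[i])) ++nT;
      if (is_prolif(st[i])) ++nPT;
      if (st[i] == NA11) ++c11;
      else if (st[i] == NA12) ++c12;
      else if (st[i] == NA2) ++c2;
      else if (st[i] == NA3) ++c3;
      if (im[i] != IA_NONE) ++nIA;
    }
    Geometry g = geometry(st, n, pitch);
    // column layout mirrors the R metrics data.frame
    met(row, 0) = m; met(row, 1) = nT; met(row, 2) = nPT;
    met(row, 3) = c11; met(row, 4) = c12; met(row, 5) = c2; met(row, 6) = c3;
    met(row, 7) = (double)nT / ((double)n * n);
    met(row, 8) = nT ? (double)nPT / nT : 0.0;
    met(row, 9) = nT ? (double)c3 / nT : 0.0;
    met(row, 10) = g.Rt; met(row, 11) = g.Rn; met(row, 12) = g.Wp;
    met(row, 13) = nIA; met(row, 14) = n_BI_last;
    met(row, 15) = v; met(row, 16) = f;
    met(row, 17) = nT == 0 ? 1.0 : 0.0;
    met(row, 18) = divisions; met(row, 19) = quiescences;
    met(row, 20) = necroses; met(row, 21) = moved;
    met(row, 22) = kills; met(row, 23) = losses;
  };

  record(0, 0, 0, 0, 0, 0, 0);

  std::vector<int> sites, perm, cand;
  sites.reserve(n * n);
  cand.reserve(8);

  for (int step = 1; step <= n_steps; ++step) {
    // ---- tumor phase ----
    Geometry g0 = geometry(st, n, pitch);
    const double Rt = g0.Rt;
    const double pressure = std::max(0.0, 1.0 - Rt / R_max);

    // age accrues only while a proliferating cell is denied the opportunity
    // to divide (no NA_0 Moore neighbor); division resets it
    sites.clear();
    for (int i = 0; i < n * n; ++i) {
      if (!is_prolif(st[i])) continue;
      const int r = i % n, c = i / n;
      bool blocked = true;
      for (int k = 0; k < 8 && blocked; ++k) {
        int rr = r + OFF_R[k], cz = c + OFF_C[k];
        if (rr >= 0 && rr < n && cz >= 0 && cz < n && st[rr + cz * n] == NA0)
          blocked = false;
      }
      if (blocked) ++ag[i];
      sites.push_back(i);
    }
    int divisions = 0;
    if (!sites.empty()) {
      perm.resize(sites.size());
      fy_permute(perm);
      for (size_t t = 0; t < perm.size(); ++t) {
        const int idx = sites[perm[t]];
        const int r = idx % n, c = idx / n;
        const int s = st[idx];
        double rho;
        if (s == NA11) {
          rho = p01 * pressure;
        } else {
          int nfree = 0;
          for (int k = 0; k < 8; ++k) {
            int rr = r + OFF_R[k], cz = c + OFF_C[k];
            if (rr >= 0 && rr < n && cz >= 0 && cz < n &&
                st[rr + cz * n] == NA0)
              ++nfree;
          }
          rho = p02 * pressure * nfree / 8.0;
        }
        rho = std::min(std::max(rho, 0.0), 1.0);
        if (unif_rand() >= rho) continue;
        cand.clear();
        for (int k = 0; k < 8; ++k) {
          int rr = r + OFF_R[k], cz = c + OFF_C[k];
          if (rr >= 0 && rr < n && cz >= 0 && cz < n &&
              st[rr + cz * n] == NA0)
            cand.push_back(rr + cz * n);
        }
        if (cand.empty()) continue;
        const int d = cand[(int)(unif_rand() * cand.size())];
        int dtype;
        if (s == NA11) {
          dtype = (unif_rand() < Nmm) ? NA12 : NA11;
        } else {
          dtype = na12_code;
        }
        st[d] = dtype;
        ag[idx] = 0;
        ag[d] = 0;
        ++divisions;
      }
    }

    const double root2 = std::sqrt(2.0);
    const double delta_p = std::max(b * std::pow(Rt, rim_exponent),
                                    pitch * root2);
    const double delta_n = std::max(a * std::pow(Rt, rim_exponent),
                                    pitch * root2);
    for (int i = 0; i < n * n; ++i) tumor[i] = is_tumor(st[i]);
    edt_sq(tumor, n, depth2);

    int quiescences = 0, necroses = 0;
    for (int i = 0; i < n * n; ++i) {
      if (!is_prolif(st[i])) continue;
      const double depth = pitch * std::sqrt(depth2[i]);
      const bool over_age = ag[i] >= age_max;
      const bool too_deep = depth > delta_p;
      if (over_age) {
        st[i] = expiry_code;
        ag[i] = 0;
        ++quiescences;
      } else if (too_deep) {
        st[i] = NA2;
        ag[i] = 0;
        ++quiescences;
      }
    }
    for (int i = 0; i < n * n; ++i) {
      if (st[i] == NA2 && pitch * std::sqrt(depth2[i]) > delta_n) {
        st[i] = NA3;
        ++necroses;
      }
    }
    ++m;

    // ---- immune phase ----
    int nPT = 0, nT = 0, c3 = 0;
    for (int i = 0; i < n * n; ++i) {
      if (is_prolif(st[i])) ++nPT;
      if (is_tumor(st[i])) ++nT;
      if (st[i] == NA3) ++c3;
    }
    const int n_BI = (int)std::floor(recruit_rate * nPT + 0.5);
    n_BI_last = n_BI;
    if (n_BI > 0) {
      std::vector<int> free;
      for (int i = 0; i < n * n; ++i)
        if (st[i] == NA0 && im[i] == IA_NONE) free.push_back(i);
      const int K = (int)free.size();
      const int k = std::min(n_BI, K);
      for (int i = 0; i < k; ++i) {
        int j = i + (int)(unif_rand() * (K - i));
        std::swap(free[i], free[j]);
        im[free[i]] = IA0;
      }
    }

    const double NF = nT ? (double)c3 / nT : 0.0;
    int moved = 0;
    if (NF >= activation_nf) {
      std::vector<int> agents;
      for (int i = 0; i < n * n; ++i)
        if (im[i] != IA_NONE) agents.push_back(i);
      if (!agents.empty()) {
        perm.resize(agents.size());
        fy_permute(perm);
        for (size_t t = 0; t < perm.size(); ++t) {
          const int idx = agents[perm[t]];
          const int r = idx % n, c = idx / n;
          cand.clear();
          for (int k = 0; k < 8; ++k) {
            int rr = r + OFF_R[k], cz = c + OFF_C[k];
            if (rr >= 0 && rr < n && cz >= 0 && cz < n &&
                st[rr + cz * n] == NA0 && im[rr + cz * n] == IA_NONE)
              cand.push_back(rr + cz * n);
          }
          if (cand.empty()) continue;
          const int dest = cand[(int)(unif_rand() * cand.size())];
          im[dest] = im[idx];
          im[idx] = IA_NONE;
          ++moved;
        }
      }
    }

    int kills = 0, losses = 0;
    for (int i = 0; i < n * n; ++i) {
      if (im[i] == IA_NONE) continue;
      const int r = i % n, c = i / n;
      cand.clear();
      for (int k = 0; k < 8; ++k) {
        int rr = r + OFF_R[k], cz = c + OFF_C[k];
        if (rr >= 0 && rr < n && cz >= 0 && cz < n &&
            is_prolif(st[rr + cz * n]))
          cand.push_back(rr + cz * n);
      }
      if (cand.empty()) continue;
      const int tgt = cand[(int)(unif_rand() * cand.size())];
      if (unif_rand() < rho_I * K_dT) {
        st[tgt] = NA0;
        ag[tgt] = 0;
        ++v;
        ++kills;
      } else if (unif_rand() < rho_t * K_dI) {
        im[i] = IA_NONE;
        ++f;
        ++losses;
      }
    }

    record(step, divisions, quiescences, necroses, moved, kills, losses);
  }

  IntegerMatrix statesOut(n, n), immuneOut(n, n), ageOut(n, n);
  std::copy(st.begin(), st.end(), statesOut.begin());
  std::copy(im.begin(), im.end(), immuneOut.begin());
  std::copy(ag.begin(), ag.end(), ageOut.begin());
  return List::create(
    _["states"] = statesOut, _["immune"] = immuneOut, _["age"] = ageOut,
    _["m"] = m, _["v"] = v, _["f"] = f, _["n_BI"] = n_BI_last,
    _["metrics"] = met);
}
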