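// Mesoscale patchy-particle engine.
//
// State is kept in unwrapped coordinates (periodic mode) or absolute
// coordinates (hard-wall mode). Clusters are a union-find partition:
// association is permanent, so the partition is an exact summary of every
// edge ever formed. All randomness comes from R's RNG (draw order: clusters
// in ascending min-member-id order; dx, dy, dtheta per cluster), so a run is
// reproducible from set.seed() alone.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>

using namespace Rcpp;

namespace {

inline double wrap360(double a) {
  a -= 360.0 * std::floor(a / 360.0);
  if (a >= 360.0) a -= 360.0;
  if (a < 0.0) a = 0.0;  // guard FP edge cases
  return a;
}

inline double wrap_box(double v, double L) {
  double w = v - L * std::floor(v / L);
  if (w >= L) w -= L;
  if (w < 0.0) w = 0.0;
  return w;
}

// minimum-image component difference (periodic) or plain difference
inline double delta(double a, double b, double L, bool periodic) {
  double d = b - a;
  if (periodic) d -= L * std::nearbyint(d / L);
  return d;
}

struct PatchSet {
  // one row per patch: start, end (degrees, may wrap across 360)
  std::vector<double> start, end;
  bool contains(double a) const {
    for (size_t k = 0; k < start.size(); ++k) {
      double s = start[k], e = end[k];
      if (s <= e) {
        if (a >= s && a <= e) return true;
      } else {
        if (a >= s || a <= e) return true;
      }
    }
    return false;
  }
};

struct UnionFind {
  std::vector<int> parent;
  std::vector<std::vector<int> > memb;  // valid at roots only
  explicit UnionFind(const IntegerVector& labels) {
    int n = labels.size();
    parent.resize(n);
    memb.assign(n, std::vector<int>());
    // map arbitrary labels to a representative (first index with that label)
    std::map<int, int> rep;
    for (int i = 0; i < n; ++i) {
      std::map<int, int>::iterator it = rep.find(labels[i]);
      if (it == rep.end()) {
        rep[labels[i]] = i;
        parent[i] = i;
      } else {
        parent[i] = it->second;
      }
    }
    for (int i = 0; i < n; ++i) memb[find(i)].push_back(i);
  }
  int find(int i) {
    while (parent[i] != i) {
      parent[i] = parent[parent[i]];
      i = parent[i];
    }
    return i;
  }
};

struct Pair {
  int i, j;
  double d;
};

// collect all pairs with centre distance <= maxr (minimum image if periodic)
void scan_pairs(const std::vector<double>& x, const std::vector<double>& y,
                double Lx, double Ly, bool periodic, double maxr,
                std::vector<Pair>& out) {
  out.clear();
  int n = (int)x.size();
  int ncx = (int)std::floor(Lx / maxr);
  int ncy = (int)std::floor(Ly / maxr);
  // keep the grid O(n) cells: oversized sparse boxes would otherwise cost
  // more to sweep than the particles themselves
  int cap = (int)std::ceil(std::sqrt(4.0 * n)) + 1;
  if (ncx > cap) ncx = cap;
  if (ncy > cap) ncy = cap;
  if (ncx < 3 || ncy < 3 || n < 64) {
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double wxi = periodic ? wrap_box(x[i], Lx) : x[i];
        double wyi = periodic ? wrap_box(y[i], Ly) : y[i];
        double wxj = periodic ? wrap_box(x[j], Lx) : x[j];
        double wyj = periodic ? wrap_box(y[j], Ly) : y[j];
        double dx = delta(wxi, wxj, Lx, periodic);
        double dy = delta(wyi, wyj, Ly, periodic);
        double d = std::sqrt(dx * dx + dy * dy);
        if (d <= maxr) {
          Pair p; p.i = i; p.j = j; p.d = d; out.push_back(p);
        }
      }
    }
    return;
  }
  double csx = Lx / ncx, csy = Ly / ncy;  // >= maxr by construction
  std::vector<std::vector<int> > cells(ncx * ncy);
  std::vector<double> wx(n), wy(n);
  for (int i = 0; i < n; ++i) {
    wx[i] = periodic ? wrap_box(x[i], Lx) : x[i];
    wy[i] = periodic ? wrap_box(y[i], Ly) : y[i];
    int cx = (int)(wx[i] / csx); if (cx >= ncx) cx = ncx - 1; if (cx < 0) cx = 0;
    int cy = (int)(wy[i] / csy); if (cy >= ncy) cy = ncy - 1; if (cy < 0) cy = 0;
    cells[cy * ncx + cx].push_back(i);
  }
  // half-neighbourhood offsets avoid double counting
  const int offs[5][2] = {{0, 0}, {1, 0}, {1, 1}, {0, 1}, {-1, 1}};
  for (int cy = 0; cy < ncy; ++cy) {
    for (int cx = 0; cx < ncx; ++cx) {
      const std::vector<int>& a = cells[cy * ncx + cx];
      if (a.empty()) continue;
      for (int o = 0; o < 5; ++o) {
        int nx = cx + offs[o][0], ny = cy + offs[o][1];
        if (periodic) {
          nx = (nx + ncx) % ncx;
          ny = (ny + ncy) % ncy;
        } else if (nx < 0 || nx >= ncx || ny < 0 || ny >= ncy) {
          continue;
        }
        const std::vector<int>& b = cells[ny * ncx + nx];
        bool same = (o == 0);
        for (size_t ia = 0; ia < a.size(); ++ia) {
          size_t jb0 = same ? ia + 1 : 0;
          for (size_t jb = jb0; jb < b.size(); ++jb) {
            int i = a[ia], j = b[jb];
            double dx = delta(wx[i], wx[j], Lx, periodic);
            double dy = delta(wy[i], wy[j], Ly, periodic);
            double d = std::sqrt(dx * dx + dy * dy);
            if (d <= maxr) {
              Pair p;
              p.i = i < j ? i : j;
              p.j = i < j ? j : i;
              p.d = d;
              out.push_back(p);
            }
          }
        }
      }
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".meso_run_cpp")]]
List meso_run_cpp(NumericVector x0, NumericVector y0, NumericVector th0,
                  IntegerVector cluster0, IntegerVector species0,
                  NumericVector A_t, NumericVector b_t,
                  NumericVector A_r, NumericVector b_r,
                  NumericVector std_min, List patch_list,
                  double Lx, double Ly, bool periodic,
                  double cutoff, double clash_frac, bool specific_interfaces,
                  int n_steps, int save_every) {
  int n = x0.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> th(th0.begin(), th0.end());
  for (int i = 0; i < n; ++i) th[i] = wrap360(th[i]);
  std::vector<int> spec(species0.begin(), species0.end());  // 0-based

  int n_species = A_t.size();
  std::vector<PatchSet> patches(n_species);
  for (int s = 0; s < n_species; ++s) {
    NumericMatrix pm = patch_list[s];
    for (int k = 0; k < pm.nrow(); ++k) {
      patches[s].start.push_back(wrap360(pm(k, 0)));
      patches[s].end.push_back(wrap360(pm(k, 1)));
    }
  }

  UnionFind uf(cluster0);
  double clash_dist = clash_frac * cutoff;

  // merge clusters a,b bonded through proteins i (in a's cluster) and j;
  // in periodic mode the absorbed cluster is shifted by whole box lengths so
  // member unwrapped coordinates stay mutually consistent
  // (lambda-free for portability)
  std::vector<Pair> pairs;

  int n_frames = n_steps / std::max(1, save_every) + 1 +
                 ((n_steps % std::max(1, save_every)) ? 1 : 0);
  std::vector<int> rec_step; rec_step.reserve(n_frames);
  std::vector<double> rec_x, rec_y, rec_th;
  std::vector<int> rec_wx, rec_wy, rec_cl;
  rec_x.reserve((size_t)n_frames * n);
  rec_y.reserve((size_t)n_frames * n);
  rec_th.reserve((size_t)n_frames * n);
  rec_wx.reserve((size_t)n_frames * n);
  rec_wy.reserve((size_t)n_frames * n);
  rec_cl.reserve((size_t)n_frames * n);

  std::vector<double> xs(n), ys(n), ths(n);  // start-of-step snapshot
  std::vector<int> roots, minid(n), order(n);
  std::vector<char> reverted(n);

  // record helper state: cluster id = min member id (1-based for R)
  // (defined inline where used)

  for (int step = 0; step <= n_steps; ++step) {
    if (step > 0) {
      // ---- enumerate clusters in ascending min-id order ----
      roots.clear();
      std::vector<int> seen(n, 0);
      for (int i = 0; i < n; ++i) {
        int r = uf.find(i);
        if (!seen[r]) { seen[r] = 1; roots.push_back(r); minid[r] = i; }
      }
      // ascending i of first occurrence == ascending min member id

      xs = x; ys = y; ths = th;

      // ---- sample and apply rigid moves ----
      for (size_t c = 0; c < roots.size(); ++c) {
        int r = roots[c];
        const std::vector<int>& m = uf.memb[r];
        int csz = (int)m.size();
        int sp = spec[minid[r]];
        double st = A_t[sp] * std::pow((double)csz, -b_t[sp]);
        double sr = A_r[sp] * std::pow((double)csz, -b_r[sp]);
        if (st < std_min[sp]) st = std_min[sp];
        if (sr < std_min[sp]) sr = std_min[sp];
        double dx = st > 0 ? R::rnorm(0.0, st) : 0.0;
        double dy = st > 0 ? R::rnorm(0.0, st) : 0.0;
        double dth = sr > 0 ? R::rnorm(0.0, sr) : 0.0;
        double comx = 0.0, comy = 0.0;
        for (size_t k = 0; k < m.size(); ++k) { comx += x[m[k]]; comy += y[m[k]]; }
        comx /= csz; comy /= csz;
        double cr = std::cos(dth * M_PI / 180.0), sn = std::sin(dth * M_PI / 180.0);
        for (size_t k = 0; k < m.size(); ++k) {
          int i = m[k];
          double rx = x[i] - comx, ry = y[i] - comy;
          x[i] = comx + cr * rx - sn * ry + dx;
          y[i] = comy + sn * rx + cr * ry + dy;
          th[i] = wrap360(th[i] + dth);
        }
      }

      std::fill(reverted.begin(), reverted.end(), 0);

      // ---- hard wall: reject any cluster with a member outside the box ----
      if (!periodic) {
        for (size_t c = 0; c < roots.size(); ++c) {
          int r = roots[c];
          const std::vector<int>& m = uf.memb[r];
          bool out = false;
          for (size_t k = 0; k < m.size() && !out; ++k) {
            int i = m[k];
            if (x[i] < 0.0 || x[i] > Lx || y[i] < 0.0 || y[i] > Ly) out = true;
          }
          if (out) {
            for (size_t k = 0; k < m.size(); ++k) {
              int i = m[k];
              x[i] = xs[i]; y[i] = ys[i]; th[i] = ths[i];
            }
            reverted[r] = 1;
          }
        }
      }

      // ---- clash cascade: revert both clusters of every clashing pair,
      //      iterate to a fixed point (start state is clash-free) ----
      int max_rounds = (int)roots.size() + 2;
      int round = 0;
      for (;;) {
        scan_pairs(x, y, Lx, Ly, periodic, clash_dist, pairs);
        std::vector<int> to_revert;
        for (size_t p = 0; p < pairs.size(); ++p) {
          if (pairs[p].d < clash_dist) {  // strict: d == clash_dist is legal
            int ra = uf.find(pairs[p].i), rb = uf.find(pairs[p].j);
            if (!reverted[ra]) to_revert.push_back(ra);
            if (!reverted[rb]) to_revert.push_back(rb);
          }
        }
        if (to_revert.empty()) break;
        for (size_t q = 0; q < to_revert.size(); ++q) {
          int r = to_revert[q];
          if (reverted[r]) continue;
          reverted[r] = 1;
          const std::vector<int>& m = uf.memb[r];
          for (size_t k = 0; k < m.size(); ++k) {
            int i = m[k];
            x[i] = xs[i]; y[i] = ys[i]; th[i] = ths[i];
          }
        }
        if (++round > max_rounds)
          stop("clash cascade failed to terminate (internal error)");
      }

      // ---- re-cluster: union newly interacting pairs ----
      scan_pairs(x, y, Lx, Ly, periodic, cutoff, pairs);
      for (size_t p = 0; p < pairs.size(); ++p) {
        double d = pairs[p].d;
        if (!(d > clash_dist && d <= cutoff)) continue;
        int i = pairs[p].i, j = pairs[p].j;
        int ra = uf.find(i), rb = uf.find(j);
        if (ra == rb) continue;
        if (specific_interfaces) {
          double wxi = periodic ? wrap_box(x[i], Lx) : x[i];
          double wyi = periodic ? wrap_box(y[i], Ly) : y[i];
          double wxj = periodic ? wrap_box(x[j], Lx) : x[j];
          double wyj = periodic ? wrap_box(y[j], Ly) : y[j];
          double dx = delta(wxi, wxj, Lx, periodic);
          double dy = delta(wyi, wyj, Ly, periodic);
          double bearing = std::atan2(dy, dx) * 180.0 / M_PI;
          double a1 = wrap360(bearing - th[i]);
          double a2 = wrap360(bearing + 180.0 - th[j]);
          if (!(patches[spec[i]].contains(a1) && patches[spec[j]].contains(a2)))
            continue;
        }
        // absorb rb's members into ra; in periodic mode shift the absorbed
        // cluster by whole box lengths so its unwrapped coordinates are
        // consistent with ra's frame through the bonding pair (i, j)
        if (periodic) {
          double wxi = wrap_box(x[i], Lx), wyi = wrap_box(y[i], Ly);
          double wxj = wrap_box(x[j], Lx), wyj = wrap_box(y[j], Ly);
          double tx = x[i] + delta(wxi, wxj, Lx, true);
          double ty = y[i] + delta(wyi, wyj, Ly, true);
          double shx = std::nearbyint((tx - x[j]) / Lx) * Lx;
          double shy = std::nearbyint((ty - y[j]) / Ly) * Ly;
          if (shx != 0.0 || shy != 0.0) {
            const std::vector<int>& mb = uf.memb[rb];
            for (size_t k = 0; k < mb.size(); ++k) {
              x[mb[k]] += shx;
              y[mb[k]] += shy;
            }
          }
        }
        uf.memb[ra].insert(uf.memb[ra].end(), uf.memb[rb].begin(),
                           uf.memb[rb].end());
        std::vector<int>().swap(uf.memb[rb]);
        uf.parent[rb] = ra;
      }
    }

    // ---- record frame ----
    bool record = (step == 0) || (step == n_steps) ||
                  (save_every > 0 && step % save_every == 0);
    if (record) {
      rec_step.push_back(step);
      // cluster id = min member id (1-based)
      std::vector<int> minmem(n, -1);
      for (int i = 0; i < n; ++i) {
        int r = uf.find(i);
        if (minmem[r] < 0) minmem[r] = i;  // ascending i => first is min
      }
      for (int i = 0; i < n; ++i) {
        int wx = 0, wy = 0;
        double ox = x[i], oy = y[i];
        if (periodic) {
          wx = (int)std::floor(x[i] / Lx);
          wy = (int)std::floor(y[i] / Ly);
          ox = x[i] - wx * Lx;
          oy = y[i] - wy * Ly;
        }
        rec_x.push_back(ox);
        rec_y.push_back(oy);
        rec_th.push_back(th[i]);
        rec_wx.push_back(wx);
        rec_wy.push_back(wy);
        rec_cl.push_back(minmem[uf.find(i)] + 1);
      }
    }
  }

  // final state (unwrapped coordinates + partition labels)
  IntegerVector final_cl(n);
  for (int i = 0; i < n; ++i) final_cl[i] = uf.find(i) + 1;

  return List::create(
      _["rec_step"] = wrap(rec_step),
      _["x"] = wrap(rec_x), _["y"] = wrap(rec_y), _["theta"] = wrap(rec_th),
      _["wind_x"] = wrap(rec_wx), _["wind_y"] = wrap(rec_wy),
      _["cluster_id"] = wrap(rec_cl),
      _["final_x"] = wrap(std::vector<double>(x.begin(), x.end())),
      _["final_y"] = wrap(std::vector<double>(y.begin(), y.end())),
      _["final_theta"] = wrap(std::vector<double>(th.begin(), th.end())),
      _["final_cluster"] = final_cl);
}
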