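#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Modified ant-colony walk on a resistance raster restricted to a search
// region. Improvements over the plain ant system:
//  * direction rule: the angle between consecutive steps is <= 90 degrees
//    (dot product of step vectors >= 0), which stops ants from milling;
//  * jump rule: when every admissible 8-neighbour is "high resistance"
//    (above the jump cut-off) or already visited, the ant may jump to any
//    unvisited region cell within a Chebyshev radius, resetting its
//    direction memory;
//  * global pheromone update: evaporation once per iteration, then each
//    successful ant deposits Q / L over its visited cells, L being its
//    accumulated step cost.
// Randomness comes from R's RNG, so a set.seed() in R fixes every draw.

// [[Rcpp::export]]
List aco_run_cpp(NumericMatrix res, LogicalMatrix region,
                 int start_r, int start_c, int end_r, int end_c,
                 int n_ants, int n_iter,
                 double alpha, double beta, double rho, double deposit,
                 int jump_radius, double jump_cut,
                 int max_steps, double cell_size, double tau0) {
  const int nr = res.nrow(), nc = res.ncol();
  NumericMatrix tau(nr, nc), visits(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (region(i, j)) tau(i, j) = tau0;

  const int drs[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dcs[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  std::vector<int> stamp(static_cast<size_t>(nr) * nc, 0);
  int cur_stamp = 0;
  NumericVector success_frac(n_iter);

  std::vector<int> cand_r, cand_c;
  std::vector<double> cand_w;
  std::vector<int> path;
  // per-iteration deposit buffer (global update after all ants walked)
  std::vector<double> dep_buf(static_cast<size_t>(nr) * nc, 0.0);

  for (int iter = 0; iter < n_iter; ++iter) {
    std::fill(dep_buf.begin(), dep_buf.end(), 0.0);
    int n_success = 0;

    for (int ant = 0; ant < n_ants; ++ant) {
      ++cur_stamp;
      int r = start_r, c = start_c;
      int pdr = 0, pdc = 0;            // previous step direction (0,0 = none)
      double L = 0.0;
      bool success = false;
      path.clear();
      path.push_back(c * nr + r);
      stamp[c * nr + r] = cur_stamp;

      for (int step = 0; step < max_steps; ++step) {
        if (std::abs(r - end_r) <= 1 && std::abs(c - end_c) <= 1) {
          success = true;
          break;
        }
        cand_r.clear(); cand_c.clear(); cand_w.clear();
        bool any_low = false;
        for (int k = 0; k < 8; ++k) {
          int rr = r + drs[k], cc = c + dcs[k];
          if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
          if (!region(rr, cc)) continue;
          if (stamp[cc * nr + rr] == cur_stamp) continue;
          if (pdr != 0 || pdc != 0) {
            if (pdr * drs[k] + pdc * dcs[k] < 0) continue;  // > 90 degrees back
          }
          cand_r.push_back(rr); cand_c.push_back(cc);
          if (res(rr, cc) <= jump_cut) any_low = true;
        }
        bool jumped = false;
        if (cand_r.empty() || !any_low) {
          // jump: any unvisited region cell within the Chebyshev radius
          cand_r.clear(); cand_c.clear();
          for (int dr = -jump_radius; dr <= jump_radius; ++dr)
            for (int dc = -jump_radius; dc <= jump_radius; ++dc) {
              if (dr == 0 && dc == 0) continue;
              int rr = r + dr, cc = c + dc;
              if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
              if (!region(rr, cc)) continue;
              if (stamp[cc * nr + rr] == cur_stamp) continue;
              cand_r.push_back(rr); cand_c.push_back(cc);
            }
          jumped = true;
        }
        if (cand_r.empty()) break;     // trapped: abandon this ant

        double tot = 0.0;
        cand_w.resize(cand_r.size());
        for (size_t k = 0; k < cand_r.size(); ++k) {
          double t = tau(cand_r[k], cand_c[k]);
          double h = 1.0 / res(cand_r[k], cand_c[k]);
          double w = std::pow(t, alpha) * std::pow(h, beta);
          cand_w[k] = w; tot += w;
        }
        size_t pick = 0;
        if (tot <= 0.0) {
          pick = static_cast<size_t>(unif_rand() * cand_r.size());
          if (pick >= cand_r.size()) pick = cand_r.size() - 1;
        } else {
          double u = unif_rand() * tot, acc = 0.0;
          for (size_t k = 0; k < cand_w.size(); ++k) {
            acc += cand_w[k];
            if (u <= acc) { pick = k; break; }
            pick = k;
          }
        }
        int rr = cand_r[pick], cc = cand_c[pick];
        double dr = rr - r, dc = cc - c;
        double dist = std::sqrt(dr * dr + dc * dc) * cell_size;
        L += dist * (res(r, c) + res(rr, cc)) / 2.0;
        if (jumped) { pdr = 0; pdc = 0; }
        else { pdr = rr - r; pdc = cc - c; }
        r = rr; c = cc;
        stamp[c * nr + r] = cur_stamp;
        path.push_back(c * nr + r);
      }
      if (!success &&
          std::abs(r - end_r) <= 1 && std::abs(c - end_c) <= 1)
        success = true;

      for (size_t k = 0; k < path.size(); ++k)
        visits[path[k]] += 1.0;
      if (success && L > 0.0) {
        ++n_success;
        double q = deposit / L;
        for (size_t k = 0; k < path.size(); ++k) dep_buf[path[k]] += q;
      }
    }

    // global update: evaporate, then add this iteration's deposits
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i)
        if (region(i, j))
          tau(i, j) = (1.0 - rho) * tau(i, j) + dep_buf[j * nr + i];
    success_frac[iter] = static_cast<double>(n_success) / n_ants;
  }

  return List::create(_["tau"] = tau, _["visits"] = visits,
                      _["success_frac"] = success_frac);
}
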