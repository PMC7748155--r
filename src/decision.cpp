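#include <Rcpp.h>
using namespace Rcpp;

// Farm-plot scoring kernel: computes the linear-expansion utility
// sum_f presence_f * subscore_f(plot) over a candidate set and returns the
// argmax (first maximum, i.e. lowest (y, x) since candidates arrive in
// ascending canonical order). Mirrors the reference R implementation in
// factors.R / rules.R; the R path is kept as the test oracle.
//
// presence follows the canonical factor order:
//   0 Dist, 1 Dry, 2 Qual, 3 Yield, 4 Water, 5 Soc, 6 HAge, 7 HAgri, 8 Mig

static void minmax01(std::vector<double>& x) {
  double lo = R_PosInf, hi = R_NegInf;
  for (double v : x) { if (v < lo) lo = v; if (v > hi) hi = v; }
  if (!(hi - lo >= 1e-12)) { std::fill(x.begin(), x.end(), 0.5); return; }
  for (double& v : x) v = (v - lo) / (hi - lo);
}

// [[Rcpp::export]]
int select_plot_cpp(IntegerVector cand, NumericVector presence,
                    IntegerVector xs, IntegerVector ys,
                    IntegerVector zone, NumericVector quality,
                    NumericVector dry_raw, NumericVector last_yield,
                    NumericVector water_cnt, NumericVector soc_grid,
                    int self_x, int self_y, int self_zone,
                    int self_dwell_x, int self_dwell_y, bool self_in_grid,
                    double self_age, double self_corn,
                    NumericVector hh_x, NumericVector hh_y,
                    NumericVector hh_age, NumericVector hh_corn,
                    double social_radius, bool dist_farther) {
  const int m = cand.size();
  if (m == 0) return NA_INTEGER;
  const int nh = hh_x.size();
  const double r2 = social_radius * social_radius;

  // local plain buffers: candidate coordinates and household attributes
  std::vector<double> cx(m), cy(m);
  std::vector<int> ci(m);
  for (int i = 0; i < m; ++i) {
    ci[i] = cand[i] - 1;
    cx[i] = xs[ci[i]];
    cy[i] = ys[ci[i]];
  }
  std::vector<double> hx(nh), hy(nh), hage(nh), hcorn(nh);
  for (int j = 0; j < nh; ++j) {
    hx[j] = hh_x[j]; hy[j] = hh_y[j]; hage[j] = hh_age[j]; hcorn[j] = hh_corn[j];
  }

  std::vector<double> score(m, 0.0), raw(m);

  for (int f = 0; f < 9; ++f) {
    const double p = presence[f];
    if (p == 0.0) continue;
    if (f == 8) { // Mig: binary, not normalized
      for (int i = 0; i < m; ++i) {
        score[i] += p * ((zone[ci[i]] != self_zone) ? 1.0 : 0.0);
      }
      continue;
    }
    switch (f) {
    case 0: // Dist
      for (int i = 0; i < m; ++i) {
        const double dx = cx[i] - self_x, dy = cy[i] - self_y;
        const double d = std::sqrt(dx * dx + dy * dy);
        raw[i] = dist_farther ? d : -d;
      }
      break;
    case 1: for (int i = 0; i < m; ++i) raw[i] = dry_raw[ci[i]]; break;
    case 2: for (int i = 0; i < m; ++i) raw[i] = quality[ci[i]]; break;
    case 3: for (int i = 0; i < m; ++i) raw[i] = last_yield[ci[i]]; break;
    case 4: for (int i = 0; i < m; ++i) raw[i] = water_cnt[ci[i]]; break;
    case 5: // Soc: grid counts every dwelling; discount the decider's own
      for (int i = 0; i < m; ++i) {
        double v = soc_grid[ci[i]];
        if (self_in_grid) {
          const double dx = cx[i] - self_dwell_x, dy = cy[i] - self_dwell_y;
          if (dx * dx + dy * dy <= r2) v -= 1.0;
        }
        raw[i] = v;
      }
      break;
    case 6: case 7: { // homophily: -mean |attribute difference| in radius
      const std::vector<double>& val = (f == 6) ? hage : hcorn;
      const double self_val = (f == 6) ? self_age : self_corn;
      double worst = R_PosInf;
      std::vector<char> none(m, 0);
      bool all_none = true;
      for (int i = 0; i < m; ++i) {
        double s = 0.0; int cnt = 0;
        for (int j = 0; j < nh; ++j) {
          const double dx = cx[i] - hx[j], dy = cy[i] - hy[j];
          if (dx * dx + dy * dy <= r2) { s += std::fabs(val[j] - self_val); ++cnt; }
        }
        if (cnt > 0) {
          raw[i] = -s / cnt;
          all_none = false;
          if (raw[i] < worst) worst = raw[i];
        } else {
          none[i] = 1;
        }
      }
      if (all_none) { std::fill(raw.begin(), raw.end(), 0.0); }
      else { for (int i = 0; i < m; ++i) if (none[i]) raw[i] = worst; }
      break;
    }
    }
    minmax01(raw);
    for (int i = 0; i < m; ++i) score[i] += p * raw[i];
  }

  int best = 0;
  for (int i = 1; i < m; ++i) if (score[i] > score[best]) best = i;
  return cand[best];
}
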