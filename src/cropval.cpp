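#include <Rcpp.h>
using namespace Rcpp;

// First-order two-state rain occurrence chain. p_wet is the stationary
// wet-day probability per day, persistence r the chain's lag-1 correlation:
// P(wet|wet) = p + r(1-p), P(wet|dry) = p(1-r). u are U(0,1) draws from the
// caller (keeps all randomness in R's RNG).
// [[Rcpp::export]]
IntegerVector markov_occurrence_cpp(NumericVector p_wet, double persistence,
                                    NumericVector u) {
  int n = p_wet.size();
  if (u.size() != n) stop("u and p_wet must have equal length");
  IntegerVector wet(n);
  int prev = 0;
  for (int i = 0; i < n; ++i) {
    double p = p_wet[i];
    double pc;
    if (i == 0) {
      pc = p;
    } else if (prev == 1) {
      pc = p + persistence * (1.0 - p);
    } else {
      pc = p * (1.0 - persistence);
    }
    wet[i] = (u[i] < pc) ? 1 : 0;
    prev = wet[i];
  }
  return wet;
}

// Daily water-bucket sorghum proxy, batched over design/environment
// combinations (rows of `combos`) and weather traces (columns of the
// weather matrices). Weather matrices are day x trace, aligned to the
// sowing date in row 0.
//
// combos columns: 0 pawc (mm), 1 isw_frac, 2 runoff_frac, 3 evap_coeff
//   (mm/day at full bucket, bare soil), 4 tt_target (degCd), 5 till_mult,
//   6 density (pl/m2), 7 row_factor, 8 n_rate (kg N/ha)
// pp (scalar proxy params): 0 t_base, 1 tt_cover_frac, 2 d0 (mm/day),
//   3 dens_ref, 4 dens_exp, 5 kl, 6 runoff_thresh (mm), 7 te (t/ha per mm),
//   8 hi, 9 n_max (t/ha biomass ceiling scale), 10 kn, 11 y_pot (t/ha),
//   12 fail_thresh (t/ha)
// [[Rcpp::export]]
List simulate_crop_batch_cpp(NumericMatrix rain, NumericMatrix maxt,
                             NumericMatrix mint, NumericMatrix combos,
                             NumericVector pp) {
  int n_days = rain.nrow(), n_tr = rain.ncol(), n_cb = combos.nrow();
  if (maxt.nrow() != n_days || mint.nrow() != n_days ||
      maxt.ncol() != n_tr || mint.ncol() != n_tr)
    stop("weather matrices must share dimensions");
  if (pp.size() < 13) stop("proxy parameter vector too short");

  const double t_base = pp[0], tt_cover_frac = pp[1], d0 = pp[2],
               dens_ref = pp[3], dens_exp = pp[4], kl = pp[5],
               runoff_thresh = pp[6], te = pp[7], hi = pp[8], n_max = pp[9],
               kn = pp[10], y_pot = pp[11], fail_thresh = pp[12];

  NumericMatrix yield(n_cb, n_tr), failed(n_cb, n_tr),
                sum_runoff(n_cb, n_tr), sum_evap(n_cb, n_tr),
                sum_transp(n_cb, n_tr), sum_rain(n_cb, n_tr),
                final_sw(n_cb, n_tr), days(n_cb, n_tr), mature(n_cb, n_tr);

  for (int tr = 0; tr < n_tr; ++tr) {
    for (int cb = 0; cb < n_cb; ++cb) {
      const double pawc = combos(cb, 0), isw = combos(cb, 1),
                   rfrac = combos(cb, 2), e0 = combos(cb, 3),
                   tt_target = combos(cb, 4), till = combos(cb, 5),
                   dens = combos(cb, 6), rowf = combos(cb, 7),
                   n_rate = combos(cb, 8);
      const double dens_f = std::pow(dens / dens_ref, dens_exp);
      const double tt_full = tt_cover_frac * tt_target;

      double sw = isw * pawc;
      double tt = 0.0, biomass = 0.0;
      double s_ro = 0.0, s_ev = 0.0, s_tr = 0.0, s_rn = 0.0;
      int d = 0;
      for (; d < n_days; ++d) {
        double tmean = 0.5 * (maxt(d, tr) + mint(d, tr));
        double dtt = tmean - t_base;
        if (dtt < 0.0) dtt = 0.0;
        tt += dtt;

        double rn = rain(d, tr);
        s_rn += rn;
        // surface runoff of intense rain, then infiltration
        double ro = (rn > runoff_thresh) ? (rn - runoff_thresh) * rfrac : 0.0;
        sw += rn - ro;
        if (sw > pawc) { ro += sw - pawc; sw = pawc; }  // drainage
        // first-stage-like soil evaporation, shaded by canopy
        double cover = tt / tt_full;
        if (cover > 1.0) cover = 1.0;
        double ev = e0 * (sw / pawc) * (1.0 - 0.5 * cover);
        if (ev > sw) ev = sw;
        sw -= ev;
        // transpiration: demand capped by extractable supply
        double demand = d0 * cover * dens_f * till * rowf;
        double supply = kl * sw;
        double tp = (demand < supply) ? demand : supply;
        if (tp > sw) tp = sw;
        sw -= tp;
        biomass += te * tp;
        s_ro += ro; s_ev += ev; s_tr += tp;

        if (tt >= tt_target) { ++d; break; }
      }

      double ceiling = n_max * n_rate / (n_rate + kn);
      double b_eff = (biomass < ceiling) ? biomass : ceiling;
      double y = hi * b_eff;
      if (y > y_pot) y = y_pot;
      if (y < 0.0) y = 0.0;

      yield(cb, tr) = y;
      failed(cb, tr) = (y < fail_thresh) ? 1.0 : 0.0;
      sum_runoff(cb, tr) = s_ro;
      sum_evap(cb, tr) = s_ev;
      sum_transp(cb, tr) = s_tr;
      sum_rain(cb, tr) = s_rn;
      final_sw(cb, tr) = sw;
      days(cb, tr) = d;
      mature(cb, tr) = (tt >= tt_target) ? 1.0 : 0.0;
    }
  }

  return List::create(_["yield"] = yield, _["failed"] = failed,
                      _["runoff"] = sum_runoff, _["soil_evap"] = sum_evap,
                      _["transpiration"] = sum_transp, _["rain"] = sum_rain,
                      _["final_sw"] = final_sw, _["days"] = days,
                      _["mature"] = mature);
}
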