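#include <Rcpp.h>
using namespace Rcpp;

// Modified-Gillespie simulation of an ensemble of myosin heads interacting
// with a single thin filament. Two head states only (bound / unbound).
// Draw order per step is fixed (u_time, u_choice, [z_strain]) and mirrored
// exactly by the pure-R gillespie_step(), so both routes produce identical
// trajectories from the same RNG seed.
//
// mode: 0 = isometric (filament fixed, calcium regulation active)
//       1 = motility  (no regulation, filament repositions to zero net force)
//
// om_detach_const: 1 -> drug-bound heads detach at constant rate om_rate;
//                  0 -> Bell equation with (om_k0, om_d).

// [[Rcpp::export]]
List gillespie_run_cpp(int n_heads, double spacing, LogicalVector om_flags,
                       int n_steps, int mode,
                       double pi_free, double pi_om,
                       double eps_max, double eps_min_ca, double lambda,
                       double kappa, double kT,
                       double step_free, double step_om,
                       double k0, double d,
                       int om_detach_const, double om_rate,
                       double om_k0, double om_d) {
  std::vector<int> bound(n_heads, 0);
  std::vector<double> strain(n_heads, 0.0);
  std::vector<double> pos(n_heads);
  for (int i = 0; i < n_heads; ++i) pos[i] = i * spacing;

  double t = 0.0, filament = 0.0;
  // force and occupancy are averaged weighted by sojourn time; the force
  // window covers the final 50% of steps
  double force_time_sum = 0.0, force_time = 0.0;
  double bound_time_sum = 0.0, om_bound_time_sum = 0.0, occ_time = 0.0;
  double max_imbalance = 0.0;
  int absorbed = 0;
  const double RATE_CAP = 1e6;

  std::vector<double> rates(n_heads);

  for (int step = 0; step < n_steps; ++step) {
    // nearest-bound-head distance for every head (two sweeps)
    std::vector<double> dnear(n_heads, R_PosInf);
    double last = R_NegInf;
    for (int i = 0; i < n_heads; ++i) {
      if (bound[i]) last = pos[i];
      else if (R_finite(last)) dnear[i] = pos[i] - last;
    }
    last = R_PosInf;
    for (int i = n_heads - 1; i >= 0; --i) {
      if (bound[i]) last = pos[i];
      else if (R_finite(last) && last - pos[i] < dnear[i])
        dnear[i] = last - pos[i];
    }

    double R = 0.0;
    for (int i = 0; i < n_heads; ++i) {
      double r;
      if (!bound[i]) {
        double f_head = om_flags[i] ? pi_om : pi_free;
        double eps;
        if (mode == 1) {
          eps = eps_max;
        } else {
          double coop = R_finite(dnear[i]) ? eps_max * std::exp(-dnear[i] / lambda)
                                           : 0.0;
          eps = std::max(eps_min_ca, coop);
        }
        r = f_head * eps;
      } else {
        if (om_flags[i]) {
          if (om_detach_const) {
            r = om_rate;
          } else {
            double F = kappa * strain[i];
            r = om_k0 * std::exp(-F * om_d / kT);
          }
        } else {
          double F = kappa * strain[i];
          r = k0 * std::exp(-F * d / kT);
        }
        if (r > RATE_CAP) r = RATE_CAP;
      }
      rates[i] = r;
      R += r;
    }

    if (R <= 0.0) { absorbed = 1; break; }

    double u1 = unif_rand();
    double dt = -std::log(u1) / R;
    t += dt;

    // the pre-transition state persists for dt: accumulate its summaries
    {
      int nb = 0, nbo = 0; double ftot = 0.0;
      for (int i = 0; i < n_heads; ++i) {
        if (bound[i]) {
          nb++;
          if (om_flags[i]) nbo++;
          ftot += kappa * strain[i];
        }
      }
      bound_time_sum += dt * nb / n_heads;
      om_bound_time_sum += dt * nbo / n_heads;
      occ_time += dt;
      if (step >= n_steps / 2) { force_time_sum += dt * ftot; force_time += dt; }
    }

    double u2 = unif_rand();
    double target = u2 * R, acc = 0.0;
    int pick = n_heads - 1;
    for (int i = 0; i < n_heads; ++i) {
      acc += rates[i];
      if (target <= acc) { pick = i; break; }
    }

    if (!bound[pick]) {
      double z = norm_rand();
      double s = z * std::sqrt(kT / kappa);
      s += om_flags[pick] ? step_om : step_free;
      bound[pick] = 1;
      strain[pick] = s;
    } else {
      bound[pick] = 0;
      strain[pick] = 0.0;
    }

    if (mode == 1) {
      // unloaded quasi-static balance: shift filament so net force is zero
      int nb = 0; double ssum = 0.0;
      for (int i = 0; i < n_heads; ++i) if (bound[i]) { nb++; ssum += strain[i]; }
      if (nb > 0) {
        double delta = ssum / nb;
        for (int i = 0; i < n_heads; ++i) if (bound[i]) strain[i] -= delta;
        filament += delta;
        double resid = 0.0;
        for (int i = 0; i < n_heads; ++i) if (bound[i]) resid += kappa * strain[i];
        if (std::fabs(resid) > max_imbalance) max_imbalance = std::fabs(resid);
      }
    }

  }

  return List::create(
    _["time"] = t,
    _["filament_pos"] = filament,
    _["mean_force_last_half"] =
        force_time > 0 ? force_time_sum / force_time : 0.0,
    _["bound_fraction"] = occ_time > 0 ? bound_time_sum / occ_time : 0.0,
    _["om_bound_fraction"] = occ_time > 0 ? om_bound_time_sum / occ_time : 0.0,
    _["max_force_imbalance"] = max_imbalance,
    _["absorbed"] = absorbed
  );
}
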