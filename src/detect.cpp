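// Permeation-event scan.
//
// Zones along the membrane normal (z already centred on the protein CoM and
// wrapped into the primary cell):
//   OUT- : z <= -D/2 - d          (bulk beyond the lower compartment)
//   IC-  : -D/2 - d < z < -D/2    (lower entry/exit compartment, thickness d)
//   MID  : |z| <= D/2             (between the two detection planes)
//   IC+  :  D/2 < z < D/2 + d     (upper compartment)
//   OUT+ : z >= D/2 + d
// with D the plane separation (Delta) and d the compartment thickness
// (delta).  A molecule is "armed" by a compartment visit; a later visit to
// the opposite compartment emits one event with t* the last frame in the
// source compartment and tau the time to the first frame in the destination
// compartment.  Entering the opposite OUT zone disarms, which is what
// excludes apparent crossings caused by periodic wrapping through the bulk.
// The confined flag is true when every frame strictly between t* and t*+tau
// stayed in MID, i.e. within (-Delta/2, Delta/2).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
DataFrame cpp_detect_events(NumericMatrix z, NumericVector times,
                            double half_delta, double delta_small) {
  const int nmol = z.nrow(), nf = z.ncol();
  std::vector<int> mol; std::vector<double> tstar, tau;
  std::vector<int> dir; std::vector<bool> conf;

  for (int i = 0; i < nmol; ++i) {
    int armed = 0;          // -1: lower compartment, +1: upper, 0: none
    int t_arm = -1;         // frame index of last source-compartment visit
    int nonmid = 0;         // frames outside MID since t_arm
    for (int t = 0; t < nf; ++t) {
      double zz = z(i, t);
      int zone;
      if (zz <= -half_delta - delta_small) zone = -2;
      else if (zz < -half_delta) zone = -1;
      else if (zz <= half_delta) zone = 0;
      else if (zz < half_delta + delta_small) zone = 1;
      else zone = 2;

      if (zone == -1) {
        if (armed == 1) {
          mol.push_back(i + 1); tstar.push_back(times[t_arm]);
          tau.push_back(times[t] - times[t_arm]);
          dir.push_back(-1); conf.push_back(nonmid == 0);
        }
        armed = -1; t_arm = t; nonmid = 0;
      } else if (zone == 1) {
        if (armed == -1) {
          mol.push_back(i + 1); tstar.push_back(times[t_arm]);
          tau.push_back(times[t] - times[t_arm]);
          dir.push_back(1); conf.push_back(nonmid == 0);
        }
        armed = 1; t_arm = t; nonmid = 0;
      } else if (zone == -2) {
        if (armed == 1) armed = 0;
        ++nonmid;
      } else if (zone == 2) {
        if (armed == -1) armed = 0;
        ++nonmid;
      }
      // zone 0 (MID): nothing to update
    }
  }
  return DataFrame::create(_["molecule"] = mol, _["t_star"] = tstar,
                           _["tau"] = tau, _["direction"] = dir,
                           _["confined"] = conf);
}
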