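#include <Rcpp.h>
using namespace Rcpp;

// Assign candidate-run ids to a sequence of RR intervals.
//
// An interval participates only if nn_ok (N labels at both endpoints). Within
// a run, each interval must lie strictly inside (prev*(1-a), prev*(1+a)) of
// the previously accepted interval. On a violation the offending interval is
// discarded (id 0) and the next acceptable interval seeds a fresh run with no
// baseline comparison. Label breaks likewise end the current run.
// Minimum-run filtering happens on the R side.
// [[Rcpp::export]]
IntegerVector nn_run_ids(NumericVector rr, LogicalVector nn_ok, double a) {
  int n = rr.size();
  IntegerVector id(n, 0);
  double last = 0.0;
  bool have_last = false;
  int run = 0;
  for (int i = 0; i < n; i++) {
    if (!nn_ok[i]) { have_last = false; continue; }
    if (!have_last) {
      run++;
      id[i] = run;
      last = rr[i];
      have_last = true;
    } else {
      double lo = last * (1.0 - a), hi = last * (1.0 + a);
      if (rr[i] > lo && rr[i] < hi) {
        id[i] = run;
        last = rr[i];
      } else {
        have_last = false;  // violator dropped; next interval seeds afresh
      }
    }
  }
  return id;
}
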