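#include <Rcpp.h>
using namespace Rcpp;

// Parameter layout shared by all entry points; must match .par_order in R.
struct GatedPars {
  double dLp, dLm, lLp, lLm;
  double dTpp, dTpm, dTmp, dTmm;
  double lTp, lTm;
  double dCp, dCm;
  double w, bias, lapR, lapL;
};

static GatedPars unpack(const NumericVector& par) {
  if (par.size() != 16) stop("parameter vector must have length 16");
  for (int i = 0; i < 16; ++i)
    if (NumericVector::is_na(par[i])) stop("NaN/NA in parameter vector");
  GatedPars p;
  p.dLp = par[0];  p.dLm = par[1];  p.lLp = par[2];  p.lLm = par[3];
  p.dTpp = par[4]; p.dTpm = par[5]; p.dTmp = par[6]; p.dTmm = par[7];
  p.lTp = par[8];  p.lTm = par[9];  p.dCp = par[10]; p.dCm = par[11];
  p.w = par[12];   p.bias = par[13]; p.lapR = par[14]; p.lapL = par[15];
  return p;
}

static inline double clip01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// One trial of the latent dynamics, applied after observing (r, o) at the
// current trial. o is 1 for correct, 0 for error; prev_resp is 0 on the
// first trial of a session (no transition update then).
static inline void update_state(const GatedPars& p, int r, int o,
                                int prev_resp, int prev_out,
                                double& zL, double& zT, double& cT) {
  double dL = o ? p.dLp : p.dLm;
  double lL = o ? p.lLp : p.lLm;
  zL = (1.0 - lL) * zL + dL * r;
  if (prev_resp != 0) {
    double T = (r == prev_resp) ? 1.0 : -1.0;
    double dT = prev_out ? (o ? p.dTpp : p.dTpm) : (o ? p.dTmp : p.dTmm);
    double lT = o ? p.lTp : p.lTm;
    zT = (1.0 - lT) * zT + dT * T;
  }
  cT = clip01(cT + (o ? p.dCp : p.dCm));
}

static inline double choice_prob(const GatedPars& p, double stim,
                                 double zL, double zT, double cT,
                                 int prev_resp) {
  double gT = (prev_resp != 0) ? cT * zT * prev_resp : 0.0;
  double y = p.w * stim + zL + gT + p.bias;
  return p.lapR + (1.0 - p.lapR - p.lapL) * R::pnorm(y, 0.0, 1.0, 1, 0);
}

// Teacher-forced latent trace. Row t holds the state *entering* trial t
// (before observing the trial's response): zL, zT, cT, gammaL, gammaT and
// the model probability of a rightward response. `valid` marks trials that
// enter the recursion; invalid trials leave the state untouched.
// [[Rcpp::export]]
NumericMatrix latent_trace_cpp(IntegerVector resp, IntegerVector correct,
                               NumericVector stim, LogicalVector new_session,
                               LogicalVector valid, NumericVector par) {
  GatedPars p = unpack(par);
  int n = resp.size();
  NumericMatrix out(n, 6);
  colnames(out) = CharacterVector::create("z_L", "z_T", "c_T",
                                          "gamma_L", "gamma_T", "p_right");
  double zL = 0.0, zT = 0.0, cT = 1.0;
  int prev_resp = 0, prev_out = 1;
  for (int t = 0; t < n; ++t) {
    if (new_session[t]) { zL = 0.0; zT = 0.0; cT = 1.0; prev_resp = 0; prev_out = 1; }
    double gT = (prev_resp != 0) ? cT * zT * prev_resp : 0.0;
    out(t, 0) = zL; out(t, 1) = zT; out(t, 2) = cT;
    out(t, 3) = zL; out(t, 4) = gT;
    out(t, 5) = choice_prob(p, stim[t], zL, zT, cT, prev_resp);
    if (!valid[t]) continue;
    int r = resp[t], o = correct[t];
    update_state(p, r, o, prev_resp, prev_out, zL, zT, cT);
    prev_resp = r; prev_out = o;
  }
  return out;
}

// Exact sequential negative log-likelihood of the observed responses
// (latents are deterministic given parameters and history).
// [[Rcpp::export]]
double negloglik_cpp(IntegerVector resp, IntegerVector correct,
                     NumericVector stim, LogicalVector new_session,
                     LogicalVector valid, NumericVector par) {
  GatedPars p = unpack(par);
  int n = resp.size();
  double zL = 0.0, zT = 0.0, cT = 1.0, nll = 0.0;
  int prev_resp = 0, prev_out = 1;
  const double eps = 1e-12;
  for (int t = 0; t < n; ++t) {
    if (new_session[t]) { zL = 0.0; zT = 0.0; cT = 1.0; prev_resp = 0; prev_out = 1; }
    if (!valid[t]) continue;
    double pr = choice_prob(p, stim[t], zL, zT, cT, prev_resp);
    double lik = (resp[t] == 1) ? pr : 1.0 - pr;
    nll -= std::log(lik < eps ? eps : lik);
    int r = resp[t], o = correct[t];
    update_state(p, r, o, prev_resp, prev_out, zL, zT, cT);
    prev_resp = r; prev_out = o;
  }
  return nll;
}

// Closed-loop simulation: choices are sampled from the model using the
// pre-drawn uniforms u (one per trial) so that all randomness lives in R's
// RNG stream. Outcome is correct iff the sampled response matches category.
// [[Rcpp::export]]
List simulate_cpp(IntegerVector category, NumericVector stim,
                  LogicalVector new_session, NumericVector u,
                  NumericVector par) {
  GatedPars p = unpack(par);
  int n = category.size();
  IntegerVector resp(n), correct(n);
  NumericMatrix trace(n, 6);
  colnames(trace) = CharacterVector::create("z_L", "z_T", "c_T",
                                            "gamma_L", "gamma_T", "p_right");
  double zL = 0.0, zT = 0.0, cT = 1.0;
  int prev_resp = 0, prev_out = 1;
  for (int t = 0; t < n; ++t) {
    if (new_session[t]) { zL = 0.0; zT = 0.0; cT = 1.0; prev_resp = 0; prev_out = 1; }
    double gT = (prev_resp != 0) ? cT * zT * prev_resp : 0.0;
    double pr = choice_prob(p, stim[t], zL, zT, cT, prev_resp);
    trace(t, 0) = zL; trace(t, 1) = zT; trace(t, 2) = cT;
    trace(t, 3) = zL; trace(t, 4) = gT; trace(t, 5) = pr;
    int r = (u[t] < pr) ? 1 : -1;
    int o = (r == category[t]) ? 1 : 0;
    resp[t] = r; correct[t] = o;
    update_state(p, r, o, prev_resp, prev_out, zL, zT, cT);
    prev_resp = r; prev_out = o;
  }
  return List::create(_["response"] = resp, _["correct"] = correct,
                      _["trace"] = trace);
}
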