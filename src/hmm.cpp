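#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for one branch of the two-state import HMM.
// States: 0 = clonal, 1 = import. Observations x[t] in {0, 1, NA (=-1)}:
// 1 = a parsimony-assigned substitution event at that alignment column.
// Emission P(x=1) is pC in the clonal state and pI inside an import tract;
// missing columns emit probability 1 in both states (marginalized).
// Returns the log-likelihood, posterior-weighted event/occupancy sums over
// observed columns, expected transition counts and the per-column posterior
// probability of the import state.
// [[Rcpp::export(name = ".hmm_forward_backward")]]
List hmm_forward_backward(IntegerVector x, double pC, double pI,
                          double a, double b) {
  const int L = x.size();
  const double tCC = 1.0 - a, tCI = a, tIC = b, tII = 1.0 - b;
  // uniform initial distribution: it contributes one column's worth of
  // prior and keeps the M-step an exact maximizer (monotone EM); a
  // stationary start would couple every parameter through the first term
  const double piC = 0.5, piI = 0.5;

  NumericVector aC(L), aI(L), scale(L);
  auto emit = [&](int t, double &eC, double &eI) {
    if (x[t] == NA_INTEGER || x[t] < 0) { eC = 1.0; eI = 1.0; }
    else if (x[t] == 1) { eC = pC; eI = pI; }
    else { eC = 1.0 - pC; eI = 1.0 - pI; }
  };

  double eC, eI;
  emit(0, eC, eI);
  aC[0] = piC * eC; aI[0] = piI * eI;
  scale[0] = aC[0] + aI[0];
  if (scale[0] <= 0) scale[0] = 1e-300;
  aC[0] /= scale[0]; aI[0] /= scale[0];
  for (int t = 1; t < L; ++t) {
    emit(t, eC, eI);
    double c = (aC[t - 1] * tCC + aI[t - 1] * tIC) * eC;
    double i = (aC[t - 1] * tCI + aI[t - 1] * tII) * eI;
    double s = c + i;
    if (s <= 0) s = 1e-300;
    aC[t] = c / s; aI[t] = i / s; scale[t] = s;
  }

  double loglik = 0.0;
  for (int t = 0; t < L; ++t) loglik += std::log(scale[t]);

  NumericVector gI(L);
  double bC = 1.0, bI = 1.0;
  double gC_obs = 0, gI_obs = 0, gCx = 0, gIx = 0;
  double xCC = 0, xCI = 0, xIC = 0, xII = 0;
  // backward pass, accumulating sufficient statistics on the fly
  for (int t = L - 1; t >= 0; --t) {
    double gC_t = aC[t] * bC, gI_t = aI[t] * bI;
    double norm = gC_t + gI_t;
    if (norm <= 0) norm = 1e-300;
    gC_t /= norm; gI_t /= norm;
    gI[t] = gI_t;
    bool obs = !(x[t] == NA_INTEGER || x[t] < 0);
    if (obs) {
      gC_obs += gC_t; gI_obs += gI_t;
      if (x[t] == 1) { gCx += gC_t; gIx += gI_t; }
    }
    if (t > 0) {
      emit(t, eC, eI);
      double s = scale[t];
      double eCb = eC * bC / s, eIb = eI * bI / s;
      xCC += aC[t - 1] * tCC * eCb;
      xCI += aC[t - 1] * tCI * eIb;
      xIC += aI[t - 1] * tIC * eCb;
      xII += aI[t - 1] * tII * eIb;
      double nbC = tCC * eCb + tCI * eIb;
      double nbI = tIC * eCb + tII * eIb;
      bC = nbC; bI = nbI;
    }
  }

  return List::create(
    _["loglik"] = loglik, _["gC_obs"] = gC_obs, _["gI_obs"] = gI_obs,
    _["gCx"] = gCx, _["gIx"] = gIx, _["xCC"] = xCC, _["xCI"] = xCI,
    _["xIC"] = xIC, _["xII"] = xII, _["gammaI"] = gI);
}
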