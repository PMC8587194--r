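#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Simulated log-likelihood (and analytic score) of a mixed logit with
// independent normal coefficients on the random attributes, fixed
// coefficients on the remaining attributes, and alternative-specific
// surgeon effects.
//
// For cache locality the attribute matrices arrive TRANSPOSED:
// Qt is K x N and Xt is F x N (one contiguous column per data row).
// Rows must be grouped by patient; patPtr holds 0-based row offsets
// (length P+1).  chosenRow holds, per patient, the absolute 0-based
// index of the chosen row.  feIdx maps each row to an estimated
// fixed-effect index, with -1 for the reference surgeon.  Z holds
// standard-normal draws laid out attribute-fastest, then draw, then
// patient, so the draw block of patient i starts at Z[i * nDraws * K].
//
// The per-patient simulated probability is the average over draws of the
// conditional logit probability of the chosen row; probabilities below
// probFloor are floored (counted in n_floor) before taking logs.
// [[Rcpp::export]]
List mixl_eval_cpp(NumericVector mu, NumericVector sigma, NumericVector gamma,
                   NumericVector fe, NumericMatrix Qt, NumericMatrix Xt,
                   IntegerVector feIdx, IntegerVector patPtr,
                   IntegerVector chosenRow, NumericVector Z, int nDraws,
                   bool wantGrad, bool wantScores, double probFloor)
{
    const int K = Qt.nrow();
    const int F = Xt.nrow();
    const int N = Qt.ncol();
    const int P = patPtr.size() - 1;
    const int nFe = fe.size();
    const int npar = 2 * K + F + nFe;

    const double *qt = REAL(Qt);
    const double *xt = F > 0 ? REAL(Xt) : nullptr;
    const double *zp = REAL(Z);
    const int *fei = INTEGER(feIdx);

    // utility contribution that does not vary across draws
    std::vector<double> base(N);
    for (int n = 0; n < N; ++n) {
        double b = 0.0;
        if (F > 0) {
            const double *xr = xt + static_cast<size_t>(n) * F;
            for (int f = 0; f < F; ++f) b += xr[f] * gamma[f];
        }
        const int s = fei[n];
        if (s >= 0) b += fe[s];
        base[n] = b;
    }

    int maxJ = 1;
    for (int i = 0; i < P; ++i) maxJ = std::max(maxJ, patPtr[i + 1] - patPtr[i]);

    std::vector<double> u(maxJ), pr(maxJ), coef(K), qbar(K), xbar(F), gacc(npar);
    NumericVector grad(wantGrad ? npar : 0);
    NumericMatrix scores((wantGrad && wantScores) ? P : 0,
                         (wantGrad && wantScores) ? npar : 0);

    double ll = 0.0;
    int nFloor = 0;

    for (int i = 0; i < P; ++i) {
        const int a = patPtr[i], b = patPtr[i + 1], J = b - a;
        const int crow = chosenRow[i];
        const int crel = crow - a;
        double probSum = 0.0;
        if (wantGrad) std::fill(gacc.begin(), gacc.end(), 0.0);

        for (int r = 0; r < nDraws; ++r) {
            const double *z = zp + (static_cast<size_t>(i) * nDraws + r) * K;
            for (int k = 0; k < K; ++k) coef[k] = mu[k] + sigma[k] * z[k];

            double m = -INFINITY;
            for (int j = 0; j < J; ++j) {
                const double *qr = qt + static_cast<size_t>(a + j) * K;
                double uu = base[a + j];
                for (int k = 0; k < K; ++k) uu += qr[k] * coef[k];
                u[j] = uu;
                if (uu > m) m = uu;
            }
            double ssum = 0.0;
            for (int j = 0; j < J; ++j) {
                pr[j] = std::exp(u[j] - m);
                ssum += pr[j];
            }
            const double inv = 1.0 / ssum;
            const double pc = pr[crel] * inv;
            probSum += pc;

            if (wantGrad) {
                for (int k = 0; k < K; ++k) qbar[k] = 0.0;
                for (int f = 0; f < F; ++f) xbar[f] = 0.0;
                double *feg = gacc.data() + 2 * K + F;
                for (int j = 0; j < J; ++j) {
                    const double pj = pr[j] * inv;
                    const int row = a + j;
                    const double *qr = qt + static_cast<size_t>(row) * K;
                    for (int k = 0; k < K; ++k) qbar[k] += pj * qr[k];
                    if (F > 0) {
                        const double *xr = xt + static_cast<size_t>(row) * F;
                        for (int f = 0; f < F; ++f) xbar[f] += pj * xr[f];
                    }
                    const int s = fei[row];
                    if (s >= 0) feg[s] -= pc * pj;
                }
                const double *qc = qt + static_cast<size_t>(crow) * K;
                for (int k = 0; k < K; ++k) {
                    const double d = qc[k] - qbar[k];
                    gacc[k] += pc * d;
                    gacc[K + k] += pc * z[k] * d;
                }
                if (F > 0) {
                    const double *xc = xt + static_cast<size_t>(crow) * F;
                    for (int f = 0; f < F; ++f)
                        gacc[2 * K + f] += pc * (xc[f] - xbar[f]);
                }
                const int sc = fei[crow];
                if (sc >= 0) feg[sc] += pc;
            }
        }

        double prob = probSum / nDraws;
        if (prob < probFloor) { prob = probFloor; ++nFloor; }
        ll += std::log(prob);

        if (wantGrad) {
            const double w = 1.0 / (nDraws * prob);
            for (int t = 0; t < npar; ++t) {
                const double g = gacc[t] * w;
                grad[t] += g;
                if (wantScores) scores(i, t) = g;
            }
        }
    }

    List out = List::create(_["loglik"] = ll, _["n_floor"] = nFloor);
    if (wantGrad) {
        out["grad"] = grad;
        if (wantScores) out["scores"] = scores;
    }
    return out;
}
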