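#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

// Direct-method (Gillespie 1977) exact SSA for the two-state-promoter model
// with reversible mRNA folding.
//
// Species: d (promoter indicator, 1 = D1 active), Ru (unfolded mRNA),
//          Rf (folded mRNA), P (protein).
// Rate vector (in order): k_on, k_off, v_tx_u, v_tx_f, k_fold, k_unfold,
//                         k_tl, k_tl_fold, gamma_R, gamma_P
// where v_tx_u / v_tx_f split the transcription rate by the folding state of
// the nascent transcript (the R layer sets the split from `birth_state`).
//
// Reactions and propensities:
//   0  D0 -> D1            k_on      * (1-d)
//   1  D1 -> D0            k_off     * d
//   2  D1 -> D1 + Ru       v_tx_u    * d
//   3  D1 -> D1 + Rf       v_tx_f    * d
//   4  Ru -> Rf            k_fold    * Ru
//   5  Rf -> Ru            k_unfold  * Rf
//   6  Ru -> Ru + P        k_tl      * Ru
//   7  Rf -> Rf + P        k_tl_fold * Rf   (reduced-rate variant, default 0)
//   8  Ru -> 0             gamma_R   * Ru
//   9  Rf -> 0             gamma_R   * Rf
//  10  P  -> 0             gamma_P   * P
//
// Uses R's RNG (unif_rand) so runs are reproducible under set.seed();
// Rcpp::export wraps the call in an RNGScope.
//
// record: 0 = final state only, 1 = every reaction event, 2 = grid step dt.

#define N_REACT 11

static inline void apply_reaction(int r, int &d, double &Ru, double &Rf,
                                  double &P) {
    switch (r) {
    case 0: d = 1; break;
    case 1: d = 0; break;
    case 2: Ru += 1; break;
    case 3: Rf += 1; break;
    case 4: Ru -= 1; Rf += 1; break;
    case 5: Rf -= 1; Ru += 1; break;
    case 6: P += 1; break;
    case 7: P += 1; break;
    case 8: Ru -= 1; break;
    case 9: Rf -= 1; break;
    case 10: P -= 1; break;
    }
}

// [[Rcpp::export]]
NumericMatrix ssa_run_cpp(NumericVector rates, NumericVector init,
                          double t0, double t_end, int record, double dt) {
    const double k_on = rates[0], k_off = rates[1],
        v_u = rates[2], v_f = rates[3],
        k_fold = rates[4], k_unfold = rates[5],
        k_tl = rates[6], k_tl_fold = rates[7],
        gR = rates[8], gP = rates[9];

    int d = (int) init[0];
    double Ru = init[1], Rf = init[2], P = init[3];
    double t = t0;

    std::vector<double> out;
    out.reserve(4096);
    auto push = [&](double tt) {
        out.push_back(tt); out.push_back((double) d);
        out.push_back(Ru); out.push_back(Rf); out.push_back(P);
    };

    double next_grid = t0;
    if (record == 1) push(t);
    if (record == 2) { push(t); next_grid = t0 + dt; }

    double a[N_REACT];
    for (;;) {
        a[0] = k_on * (1 - d);  a[1] = k_off * d;
        a[2] = v_u * d;         a[3] = v_f * d;
        a[4] = k_fold * Ru;     a[5] = k_unfold * Rf;
        a[6] = k_tl * Ru;       a[7] = k_tl_fold * Rf;
        a[8] = gR * Ru;         a[9] = gR * Rf;
        a[10] = gP * P;
        double a0 = 0.0;
        for (int i = 0; i < N_REACT; ++i) a0 += a[i];

        double t_next;
        if (a0 > 0.0) {
            double u = unif_rand();
            if (u <= 0.0) u = DBL_MIN;   // unif_rand() is open on (0,1)
            t_next = t - std::log(u) / a0;
        } else {
            t_next = R_PosInf;           // absorbing state
        }

        if (t_next > t_end) {
            if (record == 2) {
                while (next_grid <= t_end * (1 + 1e-15) + 1e-300) {
                    push(next_grid);
                    next_grid += dt;
                }
            }
            break;
        }

        if (record == 2) {
            while (next_grid < t_next) { push(next_grid); next_grid += dt; }
        }

        t = t_next;
        double u2 = unif_rand() * a0;
        int r = 0;
        double cum = a[0];
        while (u2 > cum && r < N_REACT - 1) { cum += a[++r]; }
        apply_reaction(r, d, Ru, Rf, P);
        if (record == 1) push(t);
    }

    if (record == 0) push(t_end);

    const int n = (int) (out.size() / 5);
    NumericMatrix m(n, 5);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < 5; ++j)
            m(i, j) = out[5 * i + j];
    colnames(m) = CharacterVector::create("time", "promoter", "R_u", "R_f", "P");
    return m;
}
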