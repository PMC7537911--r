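// Fixed-step explicit integrators for the stochastic fast-RyR model and the
// diffusively coupled lattice of stochastic units, plus a connected-component
// labeller for space-time wave detection.  The per-step uniform RyR noise has
// no step-size-independent continuum limit, so the step size is part of the
// model specification; callers record it in trace metadata.
#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Pars {
    double g, tau_i, g_up, K_s, K_o, k_p, k_m, v_i, v_sr, v_d,
        B_b, K_b, B_SQ, K_SQ, cT;
    double v() const { return v_i + v_sr + v_d; }
};

Pars unpack(const NumericVector &pv)
{
    if (pv.size() != 15) stop("parameter vector must have length 15");
    Pars p;
    p.g = pv[0]; p.tau_i = pv[1]; p.g_up = pv[2]; p.K_s = pv[3];
    p.K_o = pv[4]; p.k_p = pv[5]; p.k_m = pv[6]; p.v_i = pv[7];
    p.v_sr = pv[8]; p.v_d = pv[9]; p.B_b = pv[10]; p.K_b = pv[11];
    p.B_SQ = pv[12]; p.K_SQ = pv[13]; p.cT = pv[14];
    return p;
}

inline double free_sr(const Pars &p, double c_sr_tot)
{
    double b = c_sr_tot - p.K_SQ - p.B_SQ;
    return 0.5 * (b + std::sqrt(b * b + 4.0 * c_sr_tot * p.K_SQ));
}

// cytosolic free calcium given a per-unit load (clamped budget)
inline double cytosolic(const Pars &p, double cT, double c_d, double c_sr_tot)
{
    double R = (p.v() * cT - p.v_d * c_d - p.v_sr * c_sr_tot) / p.v_i;
    if (R <= 0.0) return 0.0;
    double b = R - p.K_b - p.B_b;
    return 0.5 * (b + std::sqrt(b * b + 4.0 * p.K_b * R));
}

inline double clamp01(double x) { return x < 0 ? 0 : (x > 1 ? 1 : x); }

} // namespace

// Stochastic (or, with sigma = 0, deterministic) fixed-step Euler integration
// of the fast-RyR model.  Noise: P_o = c_d^2/(K_o^2+c_d^2) + sigma*(U-0.5),
// U ~ Uniform(0,1) redrawn every step, P_o clamped to [0,1].
// Returns a matrix with columns t, c_d, c_sr_tot sampled every `thin` steps
// (the initial state is row 1).
extern "C" SEXP caosc_stoch_fast_ryr(SEXP y0_, SEXP parms_, SEXP sigma_,
                                     SEXP dt_, SEXP n_steps_, SEXP thin_)
{
BEGIN_RCPP
    NumericVector y0(y0_), pv(parms_);
    const Pars p = unpack(pv);
    const double sigma = as<double>(sigma_);
    const double dt = as<double>(dt_);
    const R_xlen_t n_steps = as<R_xlen_t>(n_steps_);
    const int thin = as<int>(thin_);
    if (y0.size() != 2) stop("y0 must be (c_d, c_sr_tot)");
    if (sigma < 0) stop("sigma must be nonnegative");
    if (dt <= 0 || thin < 1) stop("bad step settings");

    const R_xlen_t n_out = n_steps / thin + 1;
    NumericMatrix out(n_out, 3);
    double c_d = y0[0], c_sr_tot = y0[1];
    RNGScope scope;

    out(0, 0) = 0.0; out(0, 1) = c_d; out(0, 2) = c_sr_tot;
    R_xlen_t row = 1;
    for (R_xlen_t i = 1; i <= n_steps; ++i) {
        double c_sr = free_sr(p, c_sr_tot);
        double c_i = cytosolic(p, p.cT, c_d, c_sr_tot);
        double P_o = c_d * c_d / (p.K_o * p.K_o + c_d * c_d);
        if (sigma > 0) P_o = clamp01(P_o + sigma * (unif_rand() - 0.5));
        double J_rel = p.g * P_o * (c_sr - c_d);
        double J_up = p.g_up * c_i * c_i / (p.K_s * p.K_s + c_i * c_i);
        c_d += dt * (J_rel - (c_d - c_i) / p.tau_i);
        c_sr_tot += dt * ((p.v_i / p.v_sr) * J_up - (p.v_d / p.v_sr) * J_rel);
        if (c_d < 0) c_d = 0;
        if (c_sr_tot < 0) c_sr_tot = 0;
        if (i % thin == 0 && row < n_out) {
            out(row, 0) = i * dt;
            out(row, 1) = c_d;
            out(row, 2) = c_sr_tot;
            ++row;
        }
    }
    return out;
END_RCPP
}

// One-dimensional chain of stochastic fast-RyR units coupled by pairwise
// diffusive exchange of cytosolic (rate D_i) and free SR (rate D_sr)
// calcium.  Each unit keeps its own total-calcium load cT_n, which evolves
// only through the exchange terms; the pairwise antisymmetric form conserves
// the lattice total exactly.  No-flux boundaries.
// Returns list(t, ci, cd, csrtot, cT): matrices sample x unit.
extern "C" SEXP caosc_lattice(SEXP cd0_, SEXP csr0_, SEXP cT0_, SEXP parms_,
                              SEXP Di_, SEXP Dsr_, SEXP sigma_, SEXP dt_,
                              SEXP n_steps_, SEXP thin_)
{
BEGIN_RCPP
    NumericVector cd0(cd0_), csr0(csr0_), cT0(cT0_), pv(parms_);
    const Pars p = unpack(pv);
    const double Di = as<double>(Di_), Dsr = as<double>(Dsr_);
    const double sigma = as<double>(sigma_), dt = as<double>(dt_);
    const R_xlen_t n_steps = as<R_xlen_t>(n_steps_);
    const int thin = as<int>(thin_);
    const int n = cd0.size();
    if (csr0.size() != n || cT0.size() != n) stop("state vectors differ in length");
    if (dt <= 0 || thin < 1) stop("bad step settings");
    // explicit-exchange stability bound (2 neighbours)
    if (dt * 2.0 * std::max(Di, Dsr) >= 1.0)
        stop("exchange step unstable: require dt * 2 * max(D_i, D_sr) < 1; "
             "use dt < %g ms", 1.0 / (2.0 * std::max(Di, Dsr)));

    std::vector<double> cd(cd0.begin(), cd0.end());
    std::vector<double> csrtot(csr0.begin(), csr0.end());
    std::vector<double> cT(cT0.begin(), cT0.end());
    std::vector<double> ci(n), csr(n), ncd(n), ncsr(n), ncT(n);

    const R_xlen_t n_out = n_steps / thin + 1;
    NumericMatrix oci(n_out, n), ocd(n_out, n), ocsr(n_out, n), ocT(n_out, n);
    NumericVector ot(n_out);
    RNGScope scope;

    R_xlen_t row = 0;
    for (R_xlen_t i = 0; i <= n_steps; ++i) {
        for (int k = 0; k < n; ++k) {
            csr[k] = free_sr(p, csrtot[k]);
            ci[k] = cytosolic(p, cT[k], cd[k], csrtot[k]);
        }
        if (i % thin == 0 && row < n_out) {
            ot[row] = i * dt;
            for (int k = 0; k < n; ++k) {
                oci(row, k) = ci[k];
                ocd(row, k) = cd[k];
                ocsr(row, k) = csrtot[k];
                ocT(row, k) = cT[k];
            }
            ++row;
        }
        if (i == n_steps) break;
        for (int k = 0; k < n; ++k) {
            double P_o = cd[k] * cd[k] / (p.K_o * p.K_o + cd[k] * cd[k]);
            if (sigma > 0) P_o = clamp01(P_o + sigma * (unif_rand() - 0.5));
            double J_rel = p.g * P_o * (csr[k] - cd[k]);
            double J_up = p.g_up * ci[k] * ci[k] /
                          (p.K_s * p.K_s + ci[k] * ci[k]);
            ncd[k] = cd[k] + dt * (J_rel - (cd[k] - ci[k]) / p.tau_i);
            ncsr[k] = csrtot[k] +
                      dt * ((p.v_i / p.v_sr) * J_up - (p.v_d / p.v_sr) * J_rel);
            // diffusive exchange updates the per-unit load; pairwise
            // antisymmetric (right-neighbour flux added here, subtracted there)
            double ex = 0.0;
            if (k > 0)
                ex += Di * (p.v_i / p.v()) * (ci[k - 1] - ci[k]) +
                      Dsr * (p.v_sr / p.v()) * (csr[k - 1] - csr[k]);
            if (k < n - 1)
                ex += Di * (p.v_i / p.v()) * (ci[k + 1] - ci[k]) +
                      Dsr * (p.v_sr / p.v()) * (csr[k + 1] - csr[k]);
            ncT[k] = cT[k] + dt * ex;
            // SR exchange also moves SR content between neighbours
            double exsr = 0.0;
            if (k > 0) exsr += Dsr * (csr[k - 1] - csr[k]);
            if (k < n - 1) exsr += Dsr * (csr[k + 1] - csr[k]);
            ncsr[k] += dt * exsr;
            if (ncd[k] < 0) ncd[k] = 0;
            if (ncsr[k] < 0) ncsr[k] = 0;
        }
        cd.swap(ncd); csrtot.swap(ncsr); cT.swap(ncT);
    }
    return List::create(_["t"] = ot, _["ci"] = oci, _["cd"] = ocd,
                        _["csrtot"] = ocsr, _["cT"] = ocT);
END_RCPP
}

// 4-connected component labelling of a logical matrix (rows = time samples,
// columns = units).  Returns an integer matrix of labels, 0 = background.
extern "C" SEXP caosc_label_components(SEXP mask_)
{
BEGIN_RCPP
    LogicalMatrix mask(mask_);
    const int nr = mask.nrow(), nc = mask.ncol();
    IntegerMatrix lab(nr, nc);
    std::fill(lab.begin(), lab.end(), 0);
    int next = 0;
    std::vector<std::pair<int, int> > stack;
    for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
            if (!mask(i, j) || lab(i, j)) continue;
            ++next;
            stack.clear();
            stack.push_back(std::make_pair(i, j));
            lab(i, j) = next;
            while (!stack.empty()) {
                int r = stack.back().first, c = stack.back().second;
                stack.pop_back();
                const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
                for (int q = 0; q < 4; ++q) {
                    int rr = r + dr[q], cc = c + dc[q];
                    if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
                    if (mask(rr, cc) && !lab(rr, cc)) {
                        lab(rr, cc) = next;
                        stack.push_back(std::make_pair(rr, cc));
                    }
                }
            }
        }
    return lab;
END_RCPP
}
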