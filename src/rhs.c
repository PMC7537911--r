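/* Compiled right-hand sides of the minimal CaRU model variants, in the
 * deSolve compiled-code interface (initializer + derivative function per
 * variant).  Parameter vector layout (must match .parms_vector in R/params.R):
 *   0 g, 1 tau_i, 2 g_up, 3 K_s, 4 K_o, 5 k_p, 6 k_m,
 *   7 v_i, 8 v_sr, 9 v_d, 10 B_b, 11 K_b, 12 B_SQ, 13 K_SQ, 14 cT_bar
 * Output slots (nout = 3): c_sr, c_i, P_o.
 */
#include <R.h>
#include <math.h>

#define N_PARMS 15
static double parms[N_PARMS];

#define G      parms[0]
#define TAU_I  parms[1]
#define G_UP   parms[2]
#define K_S    parms[3]
#define K_O    parms[4]
#define K_P    parms[5]
#define K_M    parms[6]
#define V_I    parms[7]
#define V_SR   parms[8]
#define V_D    parms[9]
#define B_B    parms[10]
#define K_B    parms[11]
#define B_SQ   parms[12]
#define K_SQ   parms[13]
#define CT_BAR parms[14]

static double clamp01(double x) { return x < 0 ? 0 : (x > 1 ? 1 : x); }

/* free SR calcium from total (rapid CSQ buffer), nonnegative root */
static double free_sr(double c_sr_tot)
{
    double b = c_sr_tot - K_SQ - B_SQ;
    return 0.5 * (b + sqrt(b * b + 4.0 * c_sr_tot * K_SQ));
}

/* cytosolic free calcium from conservation of total calcium; the budget is
 * clamped at zero so transient solver excursions do not produce NaN */
static double cytosolic(double c_d, double c_sr_tot)
{
    double v = V_I + V_SR + V_D;
    double R = (v * CT_BAR - V_D * c_d - V_SR * c_sr_tot) / V_I;
    double b;
    if (R <= 0.0) return 0.0;
    b = R - K_B - B_B;
    return 0.5 * (b + sqrt(b * b + 4.0 * K_B * R));
}

void caosc_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

/* three-variable model: y = (c_d, c_sr_tot, P_o) */
void caosc_deriv_three_var(int *neq, double *t, double *y, double *ydot,
                           double *yout, int *ip)
{
    double c_d = y[0] > 0 ? y[0] : 0;
    double c_sr_tot = y[1] > 0 ? y[1] : 0;
    double P_o = clamp01(y[2]);
    double c_sr = free_sr(c_sr_tot);
    double c_i = cytosolic(c_d, c_sr_tot);
    double J_rel = G * P_o * (c_sr - c_d);
    double J_d = (c_d - c_i) / TAU_I;
    double J_up = G_UP * c_i * c_i / (K_S * K_S + c_i * c_i);

    ydot[0] = J_rel - J_d;
    ydot[1] = (V_I / V_SR) * J_up - (V_D / V_SR) * J_rel;
    ydot[2] = K_P * c_d * c_d * (1.0 - P_o) - K_M * P_o;
    if (*ip >= 3) {
        yout[0] = c_sr;
        yout[1] = c_i;
        yout[2] = P_o;
    }
}

/* fast-RyR reduction: y = (c_d, c_sr_tot), P_o slaved to c_d */
void caosc_deriv_fast_ryr(int *neq, double *t, double *y, double *ydot,
                          double *yout, int *ip)
{
    double c_d = y[0] > 0 ? y[0] : 0;
    double c_sr_tot = y[1] > 0 ? y[1] : 0;
    double P_o = c_d * c_d / (K_O * K_O + c_d * c_d);
    double c_sr = free_sr(c_sr_tot);
    double c_i = cytosolic(c_d, c_sr_tot);
    double J_rel = G * P_o * (c_sr - c_d);
    double J_d = (c_d - c_i) / TAU_I;
    double J_up = G_UP * c_i * c_i / (K_S * K_S + c_i * c_i);

    ydot[0] = J_rel - J_d;
    ydot[1] = (V_I / V_SR) * J_up - (V_D / V_SR) * J_rel;
    if (*ip >= 3) {
        yout[0] = c_sr;
        yout[1] = c_i;
        yout[2] = P_o;
    }
}

/* fast-dyadic reduction (requires B_SQ = 0, enforced by the R caller):
 * y = (c_sr_tot, P_o); c_d is slaved via the quasi-static dyad balance
 *   c_d = (a c_sr + c_i) / (1 + a),  a = tau_i g P_o,
 * and c_i solves the conservation quadratic with that substitution. */
void caosc_deriv_fast_dyadic(int *neq, double *t, double *y, double *ydot,
                             double *yout, int *ip)
{
    double c_sr_tot = y[0] > 0 ? y[0] : 0;
    double P_o = clamp01(y[1]);
    double c_sr = c_sr_tot; /* B_SQ = 0 */
    double a = TAU_I * G * P_o;
    double v = V_I + V_SR + V_D;
    double M = v * CT_BAR - V_SR * c_sr_tot - V_D * a * c_sr / (1.0 + a);
    double A = V_I + V_D / (1.0 + a);
    double c_i, c_d, J_rel, J_up, b;

    if (M <= 0.0) {
        c_i = 0.0;
    } else {
        b = (A * K_B + V_I * B_B - M) / A;
        c_i = 0.5 * (-b + sqrt(b * b + 4.0 * K_B * M / A));
    }
    c_d = (a * c_sr + c_i) / (1.0 + a);
    J_rel = G * P_o * (c_sr - c_d);
    J_up = G_UP * c_i * c_i / (K_S * K_S + c_i * c_i);

    ydot[0] = (V_I / V_SR) * J_up - (V_D / V_SR) * J_rel;
    ydot[1] = K_P * c_d * c_d * (1.0 - P_o) - K_M * P_o;
    if (*ip >= 3) {
        yout[0] = c_sr;
        yout[1] = c_i;
        yout[2] = c_d; /* for this variant the extra slot carries c_d */
    }
}
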