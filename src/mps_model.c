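/* Compiled right-hand side of the pancreas-liver MPS model.
 *
 * Mirrors the R reference implementation ode_rhs() exactly; parameter
 * order is fixed by .parm_vector() in R/parameters.R. State order:
 * NG_m_liver, NG_m_pancreas, NI_m_liver, NI_m_pancreas, G_int,
 * G_slow_pancreas, V_beta_islets, t_state.
 */
#include <R.h>

#define N_PARMS 23

static double parms[N_PARMS];

void mps_init(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void mps_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double Vl = parms[0], Vp = parms[1], Vh = parms[2], Q = parms[3];
    const double EG0 = parms[4], SI0 = parms[5], ImaxSi = parms[6],
        EC50Si = parms[7], EGP = parms[8], sigmax = parms[9],
        alpha = parms[10], EC50I = parms[11], kel = parms[12],
        Gnormo = parms[13];
    const double kv = parms[14], d0 = parms[15], r1 = parms[16],
        r2 = parms[17], tau = parms[18];
    const double ImaxAdd = parms[19], EC50Add = parms[20];
    const int hyp = (int) parms[21];   /* 1 = H1, 2 = H2, 3 = LOW_HCT */
    const double Gd = parms[22];

    const double Gl = y[0] / Vl, Gp = y[1] / Vp;
    const double Il = y[2] / Vl, Ip = y[3] / Vp;
    const double Gint = y[4], Gslow = y[5], Vb = y[6], ts = y[7];

    double SI = SI0 * (1.0 - ImaxSi * Gint / (EC50Si + Gint));
    if (hyp == 2)
        SI *= 1.0 - ImaxAdd * ts * ts / (EC50Add * EC50Add + ts * ts);
    const double sigma = (hyp == 3) ? sigmax
        : sigmax * (1.0 - ts * ts / (alpha + ts * ts));

    ydot[0] = Gd + Vh * EGP - Vh * (EG0 + SI * Il) * Gl + Q * (Gp - Gl);
    ydot[1] = Gd + Q * (Gl - Gp);
    ydot[2] = Q * (Ip - Il) - Vh * kel * Il;
    ydot[3] = Vb * sigma * (Gp * Gp) / (EC50I * EC50I + Gp * Gp)
        + Q * (Il - Ip);
    ydot[4] = (Gl > Gnormo) ? (Gl - Gnormo) : 0.0;
    ydot[5] = (Gp - Gslow) / tau;
    ydot[6] = kv * (-d0 + r1 * Gslow - r2 * Gslow * Gslow) * Vb;
    ydot[7] = 1.0;
}
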