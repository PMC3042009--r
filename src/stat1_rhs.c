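/* Right-hand side of the IFN-gamma -> STAT1 pathway ODE system for deSolve.
 *
 * State layout (monomer/dimer units as documented in R/model.R):
 *   y[0] IIr, y[1] SUc, y[2] SDc, y[3] SDn, y[4] SDnd, y[5] SUn,
 *   y[6] mSOCS1, y[7] mSTAT1,
 *   y[8 .. 8+n-1]        linear chain for delayed SOCS1 transcription (src SDnd)
 *   y[8+n .. 8+2n-1]     linear chain for delayed STAT1 transcription (src SDnd)
 *   y[8+2n .. 8+3n-1]    linear chain for delayed SOCS1 feedback (src mSOCS1)
 */
#include <R.h>

static double parms[19];

#define k_act     parms[0]
#define k_phos    parms[1]
#define k_inh     parms[2]
#define k_imp     parms[3]
#define k_bind    parms[4]
#define k_unbind  parms[5]
#define k_deph    parms[6]
#define k_shut    parms[7]
#define k_txS     parms[8]
#define k_degS    parms[9]
#define k_txT     parms[10]
#define k_degT    parms[11]
#define k_transl  parms[12]
#define tau_socs  parms[13]
#define tau_stat1 parms[14]
#define tau_fb    parms[15]
#define n_chain_d parms[16]
#define I_total   parms[17]
#define dose      parms[18]

void stat1_initmod(void (*odeparms)(int *, double *))
{
    int n = 19;
    odeparms(&n, parms);
}

static void chain_deriv(int n, double rate, double source,
                        const double *c, double *dc)
{
    dc[0] = rate * (source - c[0]);
    for (int j = 1; j < n; j++)
        dc[j] = rate * (c[j - 1] - c[j]);
}

void stat1_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    const int n = (int) n_chain_d;
    const double IIr = y[0], SUc = y[1], SDc = y[2], SDn = y[3],
                 SDnd = y[4], SUn = y[5], mSOCS1 = y[6], mSTAT1 = y[7];

    const double z_fb = y[8 + 3 * n - 1];           /* delayed feedback signal */
    const double v = k_phos * IIr * SUc / (1.0 + k_inh * z_fb);

    ydot[0] = k_act * dose * (I_total - IIr);
    ydot[1] = -v + k_shut * (SUn - SUc) + k_transl * mSTAT1;
    ydot[2] = 0.5 * v - k_imp * SDc;
    ydot[3] = k_imp * SDc - k_bind * SDn + k_unbind * SDnd - k_deph * SDn;
    ydot[4] = k_bind * SDn - k_unbind * SDnd;
    ydot[5] = 2.0 * k_deph * SDn - k_shut * (SUn - SUc);
    ydot[6] = k_txS * y[8 + n - 1] - k_degS * mSOCS1;
    ydot[7] = k_txT * y[8 + 2 * n - 1] - k_degT * mSTAT1;

    chain_deriv(n, n / tau_socs,  SDnd,   y + 8,         ydot + 8);
    chain_deriv(n, n / tau_stat1, SDnd,   y + 8 + n,     ydot + 8 + n);
    chain_deriv(n, n / tau_fb,    mSOCS1, y + 8 + 2 * n, ydot + 8 + 2 * n);
}
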