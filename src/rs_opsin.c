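/* Right-hand side of the regular-spiking cortical neuron (leak + transient
 * Na + delayed-rectifier K + slow M-type K, threshold-shifted Traub kinetics)
 * coupled to the double two-state opsin model, in the deSolve compiled-code
 * convention. Time in ms, potentials in mV, conductances in mS/cm^2,
 * currents in uA/cm^2. Within one integration segment the irradiance is
 * constant, so the irradiance parts of the opsin rates are precomputed in R
 * and passed as parameters; only the voltage parts are evaluated here.
 *
 * State: y = (V, m, h, n, p, O, R).
 */

#include <R.h>
#include <math.h>

static double parms[28];

#define CM        parms[0]
#define GLEAK     parms[1]
#define ELEAK     parms[2]
#define GNA       parms[3]
#define ENA       parms[4]
#define GKD       parms[5]
#define GM        parms[6]
#define EK        parms[7]
#define VT        parms[8]
#define TAUMAX    parms[9]   /* ms */
#define GCHR      parms[10]  /* mS/cm^2 */
#define ECHR      parms[11]
#define DP1       parms[12]
#define DP2       parms[13]
#define DP3       parms[14]
#define HASRECT   parms[15]
#define TAUOI     parms[16]  /* s, irradiance part at the segment intensity */
#define TAURI     parms[17]  /* s */
#define OINF      parms[18]
#define RINF      parms[19]
#define TOV1      parms[20]  /* s */
#define TOV2      parms[21]
#define TOV3      parms[22]
#define TRV1      parms[23]  /* s */
#define TRV2      parms[24]
#define TRV3      parms[25]
#define COMBO     parms[26]  /* 0 = reciprocal sum, 1 = product */
#define COMBR     parms[27]

void rs22_init(void (*odeparms)(int *, double *)) {
  int n = 28;
  odeparms(&n, parms);
}

static double safe_exp(double x) {
  if (x > 700.0) x = 700.0;
  if (x < -700.0) x = -700.0;
  return exp(x);
}

/* x / (exp(x / s) - 1) with the removable singularity at x = 0 */
static double vtrap(double x, double s) {
  if (fabs(x / s) < 1e-6) return s * (1.0 - x / (2.0 * s));
  return x / (safe_exp(x / s) - 1.0);
}

void rs22_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip) {
  double V = y[0], m = y[1], h = y[2], n = y[3], p = y[4];
  double O = y[5], Rg = y[6];

  double vm = V - VT;
  double am = 0.32 * vtrap(-(vm - 13.0), 4.0);
  double bm = 0.28 * vtrap(vm - 40.0, 5.0);
  double ah = 0.128 * safe_exp(-(vm - 17.0) / 18.0);
  double bh = 4.0 / (1.0 + safe_exp(-(vm - 40.0) / 5.0));
  double an = 0.032 * vtrap(-(vm - 15.0), 5.0);
  double bn = 0.5 * safe_exp(-(vm - 10.0) / 40.0);
  double pinf = 1.0 / (1.0 + safe_exp(-(V + 35.0) / 10.0));
  double taup = TAUMAX / (3.3 * safe_exp((V + 35.0) / 20.0) +
                          safe_exp(-(V + 35.0) / 20.0));

  /* opsin time constants (s): voltage logistic combined with the
     precomputed irradiance part */
  double tov = TOV1 / (1.0 + safe_exp(-(V - TOV2) / TOV3));
  double trv = TRV1 / (1.0 + safe_exp(-(V - TRV2) / TRV3));
  double tauo = (COMBO > 0.5) ? TAUOI * tov
                              : 1.0 / (1.0 / TAUOI + 1.0 / tov);
  double taur = (COMBR > 0.5) ? TAURI * trv
                              : 1.0 / (1.0 / TAURI + 1.0 / trv);
  if (tauo < 1e-9) tauo = 1e-9;
  if (taur < 1e-9) taur = 1e-9;

  double d = (HASRECT > 0.5)
    ? DP1 * (1.0 - DP2 * safe_exp(-(V - ECHR) / DP3))
    : (V - ECHR);
  double ichr = GCHR * d * O * Rg;

  double iion = GLEAK * (V - ELEAK) + GNA * m * m * m * h * (V - ENA) +
    GKD * n * n * n * n * (V - EK) + GM * p * (V - EK);

  ydot[0] = (-iion - ichr) / CM;
  ydot[1] = am * (1.0 - m) - bm * m;
  ydot[2] = ah * (1.0 - h) - bh * h;
  ydot[3] = an * (1.0 - n) - bn * n;
  ydot[4] = (pinf - p) / taup;
  ydot[5] = (OINF - O) / (tauo * 1000.0);  /* per ms */
  ydot[6] = (RINF - Rg) / (taur * 1000.0);

  if (ip[0] >= 1) yout[0] = ichr;
}
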