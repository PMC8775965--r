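/* Tumor PBPK compartment: vascular / endosomal (endothelial) / interstitial
 * sub-compartments with FcRn recycling and quasi-equilibrium EGFR binding.
 *
 * States (amounts, mol):
 *   y[0] systemic plasma amount (used only in the closed configuration)
 *   y[1] tumor vascular amount
 *   y[2] tumor endosomal amount (free + FcRn-bound)
 *   y[3] tumor interstitial amount (free + EGFR-bound)
 *
 * All sub-compartment volumes grow as V0 * exp(kgrowth * t); working in
 * amounts makes the dilution implicit in the amount->concentration map.
 */
#include <R.h>
#include <math.h>

static double parms[22];

#define Q_TU     parms[0]   /* tumor plasma flow, L/min            */
#define L_TU     parms[1]   /* tumor lymph flow, L/min             */
#define CLUP     parms[2]   /* endosomal uptake clearance, L/min   */
#define SIGMA_V  parms[3]   /* vascular reflection coefficient     */
#define SIGMA_L  parms[4]   /* lymph reflection coefficient        */
#define CL_TU    parms[5]   /* endosomal catabolic clearance, L/min*/
#define FR       parms[6]   /* recycled fraction to vascular       */
#define F_FCRN   parms[7]   /* FcRn-bound fraction in endosome     */
#define CL_TMD   parms[8]   /* EGFR-complex clearance, L/min       */
#define KGROWTH  parms[9]   /* tumor growth rate, 1/min            */
#define VV0      parms[10]  /* initial vascular volume, L          */
#define VE0      parms[11]  /* initial endosomal volume, L         */
#define VI0      parms[12]  /* initial interstitial volume, L      */
#define R_EGFR   parms[13]  /* total EGFR concentration, M         */
#define KD_EGFR  parms[14]  /* mAb-EGFR dissociation constant, M   */
#define CO_A     parms[15]  /* biexponential plasma coefficient, M */
#define CO_ALPHA parms[16]  /* fast disposition rate, 1/min        */
#define CO_B     parms[17]  /* biexponential plasma coefficient, M */
#define CO_BETA  parms[18]  /* slow disposition rate, 1/min        */
#define CLOSED   parms[19]  /* 1 = plasma is a state, lymph returns*/
#define V_PLASMA parms[20]  /* plasma volume in closed mode, L     */
#define TABULATED parms[21] /* 1 = plasma taken from forcing data  */

static double forc[1];
#define CP_FORC forc[0]

void tumor_initmod(void (*odeparms)(int *, double *))
{
    int n = 22;
    odeparms(&n, parms);
}

void tumor_initforc(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, forc);
}

/* quasi-equilibrium bound concentration from totals; stable quadratic root */
static double bound_qe(double ctot, double rtot, double kd)
{
    double s, disc;
    if (ctot <= 0.0 || rtot <= 0.0)
        return 0.0;
    s = ctot + rtot + kd;
    disc = s * s - 4.0 * ctot * rtot;
    if (disc < 0.0)
        disc = 0.0;
    return 2.0 * ctot * rtot / (s + sqrt(disc));
}

void tumor_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double ev, vv, ve, vi, cp, cv, ce, ci_tot, b_egfr, ci_free, cb_fcrn,
        cu, influx, efflux, extrav, lymph, up_v, up_i, rec_v, rec_i;

    ev = exp(KGROWTH * (*t));
    vv = VV0 * ev;
    ve = VE0 * ev;
    vi = VI0 * ev;

    if (CLOSED > 0.5)
        cp = y[0] / V_PLASMA;
    else if (TABULATED > 0.5)
        cp = CP_FORC;
    else
        cp = CO_A * exp(-CO_ALPHA * (*t)) + CO_B * exp(-CO_BETA * (*t));

    cv = y[1] / vv;
    ce = y[2] / ve;
    ci_tot = y[3] / vi;

    b_egfr = bound_qe(ci_tot, R_EGFR, KD_EGFR);
    ci_free = ci_tot - b_egfr;
    cb_fcrn = F_FCRN * ce;
    cu = ce - cb_fcrn;

    influx = Q_TU * cp;               /* plasma -> vascular            */
    efflux = (Q_TU - L_TU) * cv;      /* vascular -> plasma            */
    extrav = (1.0 - SIGMA_V) * L_TU * cv;   /* vascular -> interstitial */
    lymph  = (1.0 - SIGMA_L) * L_TU * ci_free; /* interstitial -> lymph */
    up_v   = CLUP * cv;               /* vascular -> endosome          */
    up_i   = CLUP * ci_free;          /* interstitial -> endosome      */
    rec_v  = CLUP * FR * cb_fcrn;     /* endosome -> vascular          */
    rec_i  = CLUP * (1.0 - FR) * cb_fcrn; /* endosome -> interstitial  */

    ydot[0] = (CLOSED > 0.5) ? (efflux + lymph - influx) : 0.0;
    ydot[1] = influx - efflux - extrav - up_v + rec_v;
    ydot[2] = up_v + up_i - rec_v - rec_i - CL_TU * cu;
    ydot[3] = extrav - lymph - up_i + rec_i - CL_TMD * b_egfr;

    if (*ip >= 6) {
        yout[0] = cp;
        yout[1] = (y[1] + y[2] + y[3]) / (vv + ve + vi);
        yout[2] = b_egfr * vi;        /* EGFR-bound amount             */
        yout[3] = cb_fcrn * ve;       /* FcRn-bound endosomal amount   */
        yout[4] = ci_free * vi;       /* free interstitial amount      */
        yout[5] = cu * ve;            /* free endosomal amount         */
    }
}

/* Batched variant for population fitting: n subjects integrated as one
 * block-diagonal system (3 states per subject, plasma-forcing mode only).
 * Blocks are independent, so a banded Jacobian (half-bandwidth 2) applies.
 *
 * Parameter vector: [n, clup, sigma_l, cl_tu, fr, f_fcrn, cl_tmd, kgrowth,
 * vv0, ve0, vi0, kd_egfr, A, alpha, B, beta, then per subject
 * (q_tu, l_tu, sigma_v, c_egfr)].
 */
#define MAX_SUBJ 512
static double bparms[16 + 4 * MAX_SUBJ];

void tumor_batch_initmod(void (*odeparms)(int *, double *))
{
    int n = 16 + 4 * MAX_SUBJ;
    odeparms(&n, bparms);
}

void tumor_batch_derivs(int *neq, double *t, double *y, double *ydot,
                        double *yout, int *ip)
{
    int n = (int) bparms[0], i;
    double clup = bparms[1], sigma_l = bparms[2], cl_tu = bparms[3],
        fr = bparms[4], f_fcrn = bparms[5], cl_tmd = bparms[6],
        kg = bparms[7], vv0 = bparms[8], ve0 = bparms[9], vi0 = bparms[10],
        kd = bparms[11];
    double ev = exp(kg * (*t));
    double vv = vv0 * ev, ve = ve0 * ev, vi = vi0 * ev;
    double cp = bparms[12] * exp(-bparms[13] * (*t)) +
        bparms[14] * exp(-bparms[15] * (*t));

    for (i = 0; i < n; i++) {
        double q = bparms[16 + 4 * i], l = bparms[17 + 4 * i],
            sv = bparms[18 + 4 * i], regfr = bparms[19 + 4 * i];
        double cv = y[3 * i] / vv, ce = y[3 * i + 1] / ve,
            ci_tot = y[3 * i + 2] / vi;
        double b = bound_qe(ci_tot, regfr, kd);
        double ci_free = ci_tot - b;
        double cb = f_fcrn * ce, cu = ce - cb;
        double extrav = (1.0 - sv) * l * cv;
        double lymph = (1.0 - sigma_l) * l * ci_free;
        ydot[3 * i] = q * cp - (q - l) * cv - extrav - clup * cv
            + clup * fr * cb;
        ydot[3 * i + 1] = clup * (cv + ci_free) - clup * cb - cl_tu * cu;
        ydot[3 * i + 2] = extrav - lymph - clup * ci_free
            + clup * (1.0 - fr) * cb - cl_tmd * b;
    }
}
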