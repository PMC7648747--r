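/* Five-compartment perfusion-limited PBPK model with gallbladder
 * (enterohepatic recirculation) and time-dependent oral absorption.
 *
 * States (amounts, ug):
 *   y[0] gut lumen, y[1] gallbladder/bile, y[2] gut tissue, y[3] liver,
 *   y[4] plasma, y[5] richly perfused, y[6] slowly perfused,
 *   y[7] cumulative metabolized.
 *
 * Parameters (order shared with assemble_ode_params() on the R side):
 *   p[0..4]  V_plasma, V_gut, V_liver, V_richly, V_slowly        (L)
 *   p[5..8]  Q_gut, Q_hepatic_arterial, Q_richly, Q_slowly       (L/h)
 *   p[9..12] Kp_gut, Kp_liver, Kp_richly, Kp_slowly              (-)
 *   p[13]    fu (fraction unbound in plasma)
 *   p[14]    CLint (in vivo hepatic intrinsic clearance, L/h, unbound)
 *   p[15]    CL_bile (biliary clearance of unbound drug, L/h)
 *   p[16]    k_empty (gallbladder emptying rate, 1/h)
 *   p[17]    ka_max (1/h), p[18] tau_a (h, dissolution time constant)
 *   p[19]    t_dose (absolute time of the current dose, h)
 *   p[20]    ka_constant flag (1 -> Ka(t) = ka_max)
 */
#include <R.h>
#include <math.h>

static double p[21];

void pbpk_init(void (*odeparms)(int *, double *))
{
    int n = 21;
    odeparms(&n, p);
}

void pbpk_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double Vpl = p[0], Vgu = p[1], Vli = p[2], Vri = p[3], Vsl = p[4];
    double Qgu = p[5], Qha = p[6], Qri = p[7], Qsl = p[8];
    double Kgu = p[9], Kli = p[10], Kri = p[11], Ksl = p[12];
    double fu = p[13], CLint = p[14], CLb = p[15], kemp = p[16];
    double ka;

    if (p[20] > 0.5) {
        ka = p[17];
    } else {
        double ts = *t - p[19];
        if (ts < 0.0) ts = 0.0;
        ka = p[17] * (1.0 - exp(-ts / p[18]));
    }

    /* venous (plasma-equivalent) concentrations leaving each tissue */
    double Cpl = y[4] / Vpl;
    double Cgu = y[2] / (Vgu * Kgu);
    double Cli = y[3] / (Vli * Kli);
    double Cri = y[5] / (Vri * Kri);
    double Csl = y[6] / (Vsl * Ksl);
    double Cliu = fu * Cli; /* unbound, venous-equilibrium convention */

    ydot[0] = -ka * y[0] + kemp * y[1];
    ydot[1] = CLb * Cliu - kemp * y[1];
    ydot[2] = ka * y[0] + Qgu * (Cpl - Cgu);
    ydot[3] = Qgu * Cgu + Qha * Cpl - (Qgu + Qha) * Cli
              - (CLint + CLb) * Cliu;
    ydot[4] = (Qgu + Qha) * Cli + Qri * Cri + Qsl * Csl
              - (Qgu + Qha + Qri + Qsl) * Cpl;
    ydot[5] = Qri * (Cpl - Cri);
    ydot[6] = Qsl * (Cpl - Csl);
    ydot[7] = CLint * Cliu;
}
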