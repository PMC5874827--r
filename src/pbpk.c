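/* Whole-body PBPK right-hand sides for deSolve's compiled-model interface.
 *
 * One derivative routine serves both CNS variants, selected by p[0]:
 *   mode 1: one-compartment permeability-limited whole brain
 *   mode 2: five-compartment regional CNS block (BB, ROB, HC, FC, CSF)
 *
 * State (amounts, mg):
 *   0 arterial blood, 1 venous blood, 2 lung,
 *   3..12 tissues (adipose, bone, gut, heart, kidney, liver, muscle,
 *                  pancreas, skin, spleen),
 *   mode 1: 13 intracranial blood, 14 brain, 15 depot, 16 eliminated
 *   mode 2: 13 intracranial blood, 14 ROB-ECF, 15 HC-ECF, 16 FC-ECF,
 *           17 CSF, 18 depot, 19 eliminated
 *
 * Parameters (see R/models.R pack_parms for the authoritative layout).
 */
#include <R.h>
#include <R_ext/Rdynload.h>

#define NPAR 65

static double p[NPAR];

void pbpk_init(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, p);
}

void pbpk_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const int mode = (int) p[0];
    const double q_co = p[1], v_art = p[2], v_ven = p[3];
    const double v_lung = p[4], rbkp_lung = p[5];
    const double *Q = p + 6, *V = p + 16, *RBKP = p + 26;
    const double q_ha = p[36], cl_h = p[37], cl_r = p[38];
    const double fu_p = p[39], fu_b = p[40], fu_csf = p[41];
    const double q_brain = p[42], v_bb = p[43];
    const double ka = p[44], f_abs = p[45], rate = p[46];
    const double csf_carry = p[47];

    const double c_art = y[0] / v_art;
    const double c_ven = y[1] / v_ven;
    const double c_lung_out = y[2] / v_lung * rbkp_lung;

    double c_out[10];
    for (int i = 0; i < 10; i++)
        c_out[i] = y[3 + i] / V[i] * RBKP[i];
    /* tissue order: 0 adipose 1 bone 2 gut 3 heart 4 kidney 5 liver
     *               6 muscle 7 pancreas 8 skin 9 spleen */
    const int i_gut = 2, i_kid = 4, i_liv = 5, i_pan = 7, i_spl = 9;

    int i_bb = 13;
    int i_dep = (mode == 1) ? 15 : 18;
    int i_eli = (mode == 1) ? 16 : 19;

    const double abs_flux = ka * y[i_dep];

    /* lung bridges venous -> arterial at cardiac output */
    ydot[2] = q_co * (c_ven - c_lung_out);

    /* arterial pool feeds all tissue draws (liver via hepatic artery) */
    double draw = q_brain;
    for (int i = 0; i < 10; i++) draw += Q[i];
    draw += q_ha - Q[i_liv];   /* liver draws hepatic-artery flow only */
    ydot[0] = q_co * c_lung_out - draw * c_art;

    /* non-portal, non-liver tissues */
    for (int i = 0; i < 10; i++)
        ydot[3 + i] = Q[i] * (c_art - c_out[i]);
    /* portal organs drain into the liver instead of the systemic pool;
     * liver receives hepatic artery + portal inflow + absorbed depot drug */
    ydot[3 + i_liv] = q_ha * c_art
        + Q[i_gut] * c_out[i_gut] + Q[i_pan] * c_out[i_pan]
        + Q[i_spl] * c_out[i_spl]
        + f_abs * abs_flux
        - Q[i_liv] * c_out[i_liv] - cl_h * c_out[i_liv];
    ydot[3 + i_kid] -= cl_r * c_out[i_kid];

    /* venous pool collects systemic tissue outflows */
    double ven_in = rate;
    ven_in += Q[0] * c_out[0] + Q[1] * c_out[1] + Q[3] * c_out[3]
        + Q[i_kid] * c_out[i_kid] + Q[i_liv] * c_out[i_liv]
        + Q[6] * c_out[6] + Q[8] * c_out[8];

    const double c_bb = y[i_bb] / v_bb;

    if (mode == 1) {
        const double ps_in = p[48], ps_out = p[51], v_brain = p[61];
        const double c_br = y[14] / v_brain;
        const double flux = ps_in * fu_p * c_bb - ps_out * fu_b * c_br;
        ydot[i_bb] = q_brain * (c_art - c_bb) - flux;
        ydot[14] = flux;
        ven_in += q_brain * c_bb;
    } else {
        const double *ps_in = p + 48, *ps_out = p + 51;
        const double ps_bt_hc = p[54], ps_bt_fc = p[55];
        const double *q_bulk = p + 56;
        const double q_prod = p[59], q_sink = p[60];
        const double *v_ecf = p + 61;
        const double v_csf = p[64];

        const double c_rob = y[14] / v_ecf[0];
        const double c_hc  = y[15] / v_ecf[1];
        const double c_fc  = y[16] / v_ecf[2];
        const double c_csf = y[17] / v_csf;

        const double f_rob = ps_in[0] * fu_p * c_bb
            - ps_out[0] * fu_b * c_rob;
        const double f_hc = ps_in[1] * fu_p * c_bb
            - ps_out[1] * fu_b * c_hc;
        const double f_fc = ps_in[2] * fu_p * c_bb
            - ps_out[2] * fu_b * c_fc;
        const double prod = (csf_carry > 0.5) ? q_prod * fu_p * c_bb : 0.0;
        const double bt_hc = ps_bt_hc * fu_b * (c_hc - c_rob);
        const double bt_fc = ps_bt_fc * fu_b * (c_fc - c_rob);
        const double blk_rob = q_bulk[0] * fu_b * c_rob;
        const double blk_hc  = q_bulk[1] * fu_b * c_hc;
        const double blk_fc  = q_bulk[2] * fu_b * c_fc;
        const double sink = q_sink * fu_csf * c_csf;

        ydot[i_bb] = q_brain * (c_art - c_bb) - f_rob - f_hc - f_fc - prod;
        ydot[14] = f_rob + bt_hc + bt_fc - blk_rob;
        ydot[15] = f_hc - bt_hc - blk_hc;
        ydot[16] = f_fc - bt_fc - blk_fc;
        ydot[17] = blk_rob + blk_hc + blk_fc + prod - sink;
        ven_in += q_brain * c_bb + sink;
    }

    ydot[1] = ven_in - q_co * c_ven;
    ydot[i_dep] = -abs_flux;
    ydot[i_eli] = cl_h * c_out[i_liv] + cl_r * c_out[i_kid]
        + (1.0 - f_abs) * abs_flux;
}

static const R_CMethodDef cMethods[] = {
    {"pbpk_init",   (DL_FUNC) &pbpk_init,   1},
    {"pbpk_derivs", (DL_FUNC) &pbpk_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_cnspbpk(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
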