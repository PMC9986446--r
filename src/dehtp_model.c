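/* Compiled right-hand side of the DEHTP/MEHTP PBPK model, for use
 * through deSolve's compiled-code interface.  The parameter and state
 * layouts mirror the R reference implementation (R/model.R); the R side
 * is the executable specification, this file is the fast path.
 *
 * Units: amounts mg (second-order metabolites in MEHTP-equivalent mass),
 * volumes L, flows L/h, time h.
 */

#include <R.h>
#include <Rinternals.h>

#define NPARMS 54
#define NG 5   /* gut-1 Erlang stages (Gutlag)      */
#define NB 5   /* bile  Erlang stages (liver->gut)  */
#define NEQ (3 + NG + NB + 10 + 10 + 7)

static double p[NPARMS];

/* parameter indices */
#define mwRatio   p[0]
#define fbD       p[1]
#define fbM       p[2]
#define kMetLiD   p[3]
#define kMetGuD   p[4]
#define clIntM    p[5]
#define k1MOH     p[6]
#define k12cx     p[7]
#define k15cx     p[8]
#define fracMOH   p[9]
#define frac2cx   p[10]
#define frac5cx   p[11]
#define escGu     p[12]
#define escLi     p[13]
#define k1Bile    p[14]
#define kBileT    p[15]
#define kGutT     p[16]
#define k1Lymph   p[17]
#define bellyperm p[18]
#define giperm1   p[19]
#define giperm2   p[20]
#define kGE       p[21]
#define k1MKid    p[22]
#define qc        p[23]
#define qHa       p[24]
#define qKi       p[25]
#define qFa       p[26]
#define qGu       p[27]
#define qSt       p[28]
#define qSpd      p[29]
#define qRpd      p[30]
#define vArt      p[31]
#define vVen      p[32]
#define vLi       p[33]
#define vKi       p[34]
#define vFa       p[35]
#define vGu       p[36]
#define vSt       p[37]
#define vSpd      p[38]
#define vRpd      p[39]
#define pLiD      p[40]
#define pKiD      p[41]
#define pFaD      p[42]
#define pGuD      p[43]
#define pStD      p[44]
#define pSpdD     p[45]
#define pRpdD     p[46]
#define pLiM      p[47]
#define pKiM      p[48]
#define pFaM      p[49]
#define pGuM      p[50]
#define pStM      p[51]
#define pSpdM     p[52]
#define pRpdM     p[53]

/* state indices */
#define I_AST   0
#define I_AG1   1              /* NG stages            */
#define I_AG2   (1 + NG)
#define I_ALY   (2 + NG)
#define I_ABI   (3 + NG)       /* NB stages            */
#define I_AART  (3 + NG + NB)
#define I_AVEN  (I_AART + 1)
#define I_ALI   (I_AART + 2)
#define I_AKI   (I_AART + 3)
#define I_AFA   (I_AART + 4)
#define I_AGU   (I_AART + 5)
#define I_ASTT  (I_AART + 6)
#define I_ASPD  (I_AART + 7)
#define I_ARPD  (I_AART + 8)
#define I_AFAEC (I_AART + 9)
#define I_MART  (I_AART + 10)
#define I_MVEN  (I_MART + 1)
#define I_MLI   (I_MART + 2)
#define I_MKI   (I_MART + 3)
#define I_MFA   (I_MART + 4)
#define I_MGU   (I_MART + 5)
#define I_MSTT  (I_MART + 6)
#define I_MSPD  (I_MART + 7)
#define I_MRPD  (I_MART + 8)
#define I_MURN  (I_MART + 9)
#define I_PMOH  (I_MART + 10)
#define I_P2CX  (I_MART + 11)
#define I_P5CX  (I_MART + 12)
#define I_UMOH  (I_MART + 13)
#define I_U2CX  (I_MART + 14)
#define I_U5CX  (I_MART + 15)
#define I_TPA   (I_MART + 16)

void dehtp_initmod(void (* odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, p);
}

void dehtp_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    int i;
    double sumG1 = 0.0;

    if (*neq != NEQ) error("dehtp_derivs: expected %d states, got %d",
                           NEQ, *neq);

    for (i = 0; i < NG; i++) sumG1 += y[I_AG1 + i];

    double qLiTot = qHa + qGu + qSt;

    /* DEHTP lumen and delay chains */
    ydot[I_AST] = -(kGE + bellyperm) * y[I_AST];
    ydot[I_AG1] = kGE * y[I_AST] -
        (kGutT + giperm1 + kMetGuD) * y[I_AG1];
    for (i = 1; i < NG; i++)
        ydot[I_AG1 + i] = kGutT * y[I_AG1 + i - 1] -
            (kGutT + giperm1 + kMetGuD) * y[I_AG1 + i];
    ydot[I_AG2] = kGutT * y[I_AG1 + NG - 1] +
        kBileT * y[I_ABI + NB - 1] - giperm2 * y[I_AG2];
    ydot[I_ALY] = -k1Lymph * y[I_ALY];
    ydot[I_ABI] = k1Bile * y[I_ALI] - kBileT * y[I_ABI];
    for (i = 1; i < NB; i++)
        ydot[I_ABI + i] = kBileT * (y[I_ABI + i - 1] - y[I_ABI + i]);

    double uptake = bellyperm * y[I_AST] + giperm1 * sumG1 +
        giperm2 * y[I_AG2];
    double gutMetD = kMetGuD * sumG1;
    double livMetD = kMetLiD * y[I_ALI];

    /* DEHTP circulation */
    double CartD = y[I_AART] / vArt, CvenD = y[I_AVEN] / vVen;
    double CfD = (1.0 - fbD) * CartD;
    double CvLiD = y[I_ALI] / (vLi * pLiD);
    double CvKiD = y[I_AKI] / (vKi * pKiD);
    double CvFaD = y[I_AFA] / (vFa * pFaD);
    double CvGuD = y[I_AGU] / (vGu * pGuD);
    double CvStD = y[I_ASTT] / (vSt * pStD);
    double CvSpdD = y[I_ASPD] / (vSpd * pSpdD);
    double CvRpdD = y[I_ARPD] / (vRpd * pRpdD);

    ydot[I_AART] = qc * (CvenD - CartD);
    ydot[I_AVEN] = qKi * CvKiD + qFa * CvFaD + qSpd * CvSpdD +
        qRpd * CvRpdD + qLiTot * CvLiD + qc * fbD * CartD -
        qc * CvenD + uptake + k1Lymph * y[I_ALY];
    ydot[I_ALI] = qHa * CfD + qGu * CvGuD + qSt * CvStD -
        qLiTot * CvLiD - livMetD - k1Bile * y[I_ALI];
    ydot[I_AKI] = qKi * (CfD - CvKiD);
    ydot[I_AFA] = qFa * (CfD - CvFaD);
    ydot[I_AGU] = qGu * (CfD - CvGuD);
    ydot[I_ASTT] = qSt * (CfD - CvStD);
    ydot[I_ASPD] = qSpd * (CfD - CvSpdD);
    ydot[I_ARPD] = qRpd * (CfD - CvRpdD);
    ydot[I_AFAEC] = 0.0;

    /* MEHTP formation with molar-mass scaling */
    double G = gutMetD * mwRatio;
    double toVenM = escGu * G;
    double toLivM = (1.0 - escGu) * escLi * G;
    double firstPass = (1.0 - escGu) * (1.0 - escLi) * G;
    double livFormM = livMetD * mwRatio;

    /* MEHTP circulation */
    double CartM = y[I_MART] / vArt, CvenM = y[I_MVEN] / vVen;
    double CfM = (1.0 - fbM) * CartM;
    double CvLiM = y[I_MLI] / (vLi * pLiM);
    double CvKiM = y[I_MKI] / (vKi * pKiM);
    double CvFaM = y[I_MFA] / (vFa * pFaM);
    double CvGuM = y[I_MGU] / (vGu * pGuM);
    double CvStM = y[I_MSTT] / (vSt * pStM);
    double CvSpdM = y[I_MSPD] / (vSpd * pSpdM);
    double CvRpdM = y[I_MRPD] / (vRpd * pRpdM);
    double metM = clIntM * CvLiM;

    ydot[I_MART] = qc * (CvenM - CartM);
    ydot[I_MVEN] = qKi * CvKiM + qFa * CvFaM + qSpd * CvSpdM +
        qRpd * CvRpdM + qLiTot * CvLiM + qc * fbM * CartM -
        qc * CvenM + toVenM;
    ydot[I_MLI] = qHa * CfM + qGu * CvGuM + qSt * CvStM -
        qLiTot * CvLiM - metM + toLivM + livFormM;
    ydot[I_MKI] = qKi * (CfM - CvKiM) - k1MKid * y[I_MKI];
    ydot[I_MFA] = qFa * (CfM - CvFaM);
    ydot[I_MGU] = qGu * (CfM - CvGuM);
    ydot[I_MSTT] = qSt * (CfM - CvStM);
    ydot[I_MSPD] = qSpd * (CfM - CvSpdM);
    ydot[I_MRPD] = qRpd * (CfM - CvRpdM);
    ydot[I_MURN] = k1MKid * y[I_MKI];

    /* second-order metabolite pools and cumulative urine */
    double totMet = metM + firstPass;
    ydot[I_PMOH] = fracMOH * totMet - k1MOH * y[I_PMOH];
    ydot[I_P2CX] = frac2cx * totMet - k12cx * y[I_P2CX];
    ydot[I_P5CX] = frac5cx * totMet - k15cx * y[I_P5CX];
    ydot[I_UMOH] = k1MOH * y[I_PMOH];
    ydot[I_U2CX] = k12cx * y[I_P2CX];
    ydot[I_U5CX] = k15cx * y[I_P5CX];
    ydot[I_TPA] = (1.0 - fracMOH - frac2cx - frac5cx) * totMet;

    /* instantaneous bladder deposition rates, MEHTP-equivalent mg/h */
    if (ip[0] >= 3) {
        yout[0] = k1MOH * y[I_PMOH];
        yout[1] = k12cx * y[I_P2CX];
        yout[2] = k15cx * y[I_P5CX];
    }
}
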