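/* Banded symmetric positive-definite solve via LAPACK dpbtrf / dpbtrs.
 *
 * The backward-Euler system matrix diag(C) + dt*L (L the conductance
 * Laplacian) is SPD whenever the mesh is connected and some vertex carries
 * capacitance, so a banded Cholesky factorisation is used: storage
 * (kd+1) x n in LAPACK upper band layout, factor once per (G, dt) pair,
 * then one cheap back-substitution per timestep.
 */
#define USE_FC_LEN_T
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Lapack.h>
#include <R_ext/Rdynload.h>
#ifndef FCONE
#define FCONE
#endif

SEXP tv_band_factor(SEXP ab, SEXP kd_)
{
    SEXP abf = PROTECT(duplicate(ab));
    int kd = asInteger(kd_);
    int n = Rf_ncols(abf);
    int ldab = Rf_nrows(abf);
    int info = 0;
    if (ldab != kd + 1)
        error("band storage must have kd+1 rows");
    F77_CALL(dpbtrf)("U", &n, &kd, REAL(abf), &ldab, &info FCONE);
    if (info != 0)
        error("banded Cholesky failed (dpbtrf info=%d): matrix not positive definite", info);
    UNPROTECT(1);
    return abf;
}

SEXP tv_band_solve(SEXP abf, SEXP kd_, SEXP b)
{
    SEXP x = PROTECT(duplicate(b));
    int kd = asInteger(kd_);
    int n = Rf_ncols(abf);
    int ldab = Rf_nrows(abf);
    int nrhs = 1, info = 0;
    if (LENGTH(x) != n)
        error("right-hand side length %d does not match system size %d",
              LENGTH(x), n);
    F77_CALL(dpbtrs)("U", &n, &kd, &nrhs, REAL(abf), &ldab, REAL(x), &n,
                     &info FCONE);
    if (info != 0)
        error("banded back-substitution failed (dpbtrs info=%d)", info);
    UNPROTECT(1);
    return x;
}

static const R_CallMethodDef CallEntries[] = {
    {"tv_band_factor", (DL_FUNC) &tv_band_factor, 2},
    {"tv_band_solve",  (DL_FUNC) &tv_band_solve,  3},
    {NULL, NULL, 0}
};

void R_init_tetvolt(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
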