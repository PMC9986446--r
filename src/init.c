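#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* Symbols are looked up dynamically by deSolve (dllname/func/initfunc),
 * so registration stays permissive. */
void R_init_dehtpk(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
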