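#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP msh5_write_vlen(SEXP, SEXP, SEXP, SEXP, SEXP);
SEXP msh5_read_vlen(SEXP, SEXP);
SEXP msh5_read_vlen_row(SEXP, SEXP, SEXP);
SEXP msh5_is_vlen(SEXP, SEXP);

static const R_CallMethodDef CallEntries[] = {
    {"msh5_write_vlen",    (DL_FUNC) &msh5_write_vlen,    5},
    {"msh5_read_vlen",     (DL_FUNC) &msh5_read_vlen,     2},
    {"msh5_read_vlen_row", (DL_FUNC) &msh5_read_vlen_row, 3},
    {"msh5_is_vlen",       (DL_FUNC) &msh5_is_vlen,       2},
    {NULL, NULL, 0}
};

void R_init_msh5(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
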