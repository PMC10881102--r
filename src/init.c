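#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP wf_sha512_file(SEXP path);

static const R_CallMethodDef call_entries[] = {
    {"wf_sha512_file", (DL_FUNC) &wf_sha512_file, 1},
    {NULL, NULL, 0}
};

void R_init_wftest(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
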