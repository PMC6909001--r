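.fluxcom <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  # The HiGHS backend is reached through reticulate; point it at the python
  # on PATH unless the user has already pinned an interpreter.
  if (!nzchar(Sys.getenv("RETICULATE_PYTHON"))) {
    py <- Sys.which("python")
    if (!nzchar(py)) py <- Sys.which("python3")
    if (nzchar(py)) Sys.setenv(RETICULATE_PYTHON = py)
  }
  invisible()
}
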