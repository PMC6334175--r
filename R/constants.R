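#' Gyromagnetic constants
#'
#' Proton gyromagnetic ratio used throughout: gamma/2pi = 42.577 kHz/mT.
#' `gamma_bar()` returns it in kHz per mT; `gamma_rad()` returns the angular
#' form 2*pi*42.577e-3, which conveniently is both the precession rate in
#' rad/ms per (mT/m * mm) and the nutation rate in rad/ms per microtesla.
#'
#' @return A numeric scalar.
#' @export
gamma_bar <- function() 42.577

#' @rdname gamma_bar
#' @export
gamma_rad <- function() 2 * pi * 42.577e-3

# internal shorthand
.GAMMA <- 2 * pi * 42.577e-3
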