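# Internal unit system: SI (seconds, meters, tesla). All user-facing
# arguments are in the conventional MRI units (ms, mT/m, s/mm2, mm/s,
# um2/ms) and converted at the API boundary.

#' Gyromagnetic ratio of the proton
#'
#' The 1H gyromagnetic ratio in rad s^-1 T^-1, used throughout for the
#' dephasing factor q(t) and all b-/c-value computations.
#'
#' @format A length-one numeric.
#' @export
GAMMA_1H <- 2.6752218744e8

.ms  <- function(x) x * 1e-3          # ms      -> s
.mTm <- function(x) x * 1e-3          # mT/m    -> T/m
.mms <- function(x) x * 1e-3          # mm/s    -> m/s
.b_si   <- function(b) b * 1e6        # s/mm2   -> s/m2
.b_user <- function(b) b * 1e-6       # s/m2    -> s/mm2
.c_user <- function(c) c * 1e-3       # s/m     -> s/mm
.D_si   <- function(D) D * 1e-9       # um2/ms  -> m2/s

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
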