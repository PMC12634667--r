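# Internal unit helpers. User-facing lengths are in micrometres (the units the
# device is specified in); solvers work in SI. Conversions are centralised here
# so no literal factors leak into solver code.

um_to_m <- function(x) x * 1e-6
m_to_um <- function(x) x * 1e6
um2_to_m2 <- function(x) x * 1e-12
um3_to_m3 <- function(x) x * 1e-18
ulh_to_m3s <- function(q) q * 1e-9 / 3600   # uL/h -> m^3/s
cm2s_to_m2s <- function(d) d * 1e-4
hours_to_s <- function(t) t * 3600
s_to_hours <- function(t) t / 3600
nM_to_molm3 <- function(c) c * 1e-6          # 1 nmol/L = 1e-6 mol/m^3

deg_to_rad <- function(x) x * pi / 180

stopifnot_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}
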