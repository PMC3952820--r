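# Unit conventions used throughout:
#   length mm, time s (kinetic rate constants are accepted in 1/min and
#   converted), volume mm^3, flow mm^3/s, concentration umol/L, mass umol.
# 1 mm^3 = 1e-6 L, so mass [umol] = concentration [umol/L] * volume [mm^3] * L_PER_MM3.
L_PER_MM3 <- 1e-6

#' @keywords internal
.per_min_to_per_s <- function(x) x / 60
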