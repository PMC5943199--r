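# shared fixtures: small schemas and curves built in code

uniform_schema <- function(n, dt_s = 5) {
  frame_schema(seq(0, by = dt_s, length.out = n), rep(dt_s, n))
}

# triangle test curve: 0,0,5,10,5,2,1,1,... on a 5-s grid
triangle_tac <- function(n = 20) {
  v <- c(0, 0, 5, 10, 5, 2, rep(1, n - 6))
  tac(uniform_schema(n), v, label = "triangle")
}

# rectangular pulse with one-frame linear edges on a 5-s grid:
# zero up to frame `first - 1`, plateau `h` on frames first..(first+m-1)
rect_pulse_tac <- function(h = 12, first = 7, m = 6, n = 48) {
  v <- numeric(n)
  v[first:(first + m - 1)] <- h
  tac(uniform_schema(n), v, label = "pulse")
}

# default-range midpoint kinetic truth for single-subject checks
mid_truth <- function(Ki = 0.4, ...) {
  kinetic_truth(Ki, vb = 0.42, flow_scale = 1000, loss_rate = 0.18,
                ve = 0.13, k_ex = 1.5, drain_frac = 0.22, ...)
}
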