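# Independent reference implementation: classical (first-order) Hodgkin-Huxley
# integrated by plain forward Euler in base R.  Deliberately written without
# any package machinery so it can serve as an oracle for the alpha = 1
# reduction of the Grunwald-Letnikov scheme.
ref_hh_euler <- function(stim_fun, dt, t_end,
                         gNa = 120, gK = 36, gL = 0.3,
                         ENa = 115, EK = -12, EL = 10.6) {
  rates <- function(v) {
    vt <- function(x, y) if (abs(x / y) < 1e-6) y * (1 - x / (2 * y)) else x / (exp(x / y) - 1)
    list(am = 0.1 * vt(25 - v, 10), bm = 4 * exp(-v / 18),
         ah = 0.07 * exp(-v / 20), bh = 1 / (exp((30 - v) / 10) + 1),
         an = 0.01 * vt(10 - v, 10), bn = 0.125 * exp(-v / 80))
  }
  r0 <- rates(0)
  m <- r0$am / (r0$am + r0$bm)
  h <- r0$ah / (r0$ah + r0$bh)
  nn <- r0$an / (r0$an + r0$bn)
  n_steps <- ceiling(t_end / dt)
  v <- 0
  out <- numeric(n_steps + 1L)
  for (i in seq_len(n_steps)) {
    t <- (i - 1L) * dt
    INa <- gNa * m^3 * h * (v - ENa)
    IK <- gK * nn^4 * (v - EK)
    IL <- gL * (v - EL)
    dv <- stim_fun(t) - INa - IK - IL
    r <- rates(v)
    m <- m + dt * (r$am * (1 - m) - r$bm * m)
    h <- h + dt * (r$ah * (1 - h) - r$bh * h)
    nn <- nn + dt * (r$an * (1 - nn) - r$bn * nn)
    v <- v + dt * dv
    out[i + 1L] <- v
  }
  list(times = (0:n_steps) * dt, v = out)
}

# Frozen high-precision Mittag-Leffler values (200-term arbitrary-precision
# series, 40 significant digits, truncated to double).
ml_oracle <- list(
  list(a = 0.5, b = 1.0, z = -1,  val = 0.427583576155807),
  list(a = 0.6, b = 1.0, z = -2,  val = 0.23557103111182496),
  list(a = 0.4, b = 1.0, z = -5,  val = 0.12462707110373716),
  list(a = 0.8, b = 1.0, z = -10, val = 0.024902819761976537),
  list(a = 0.6, b = 0.6, z = -3,  val = 0.031693926561557028),
  list(a = 0.5, b = 1.5, z = -7,  val = 0.1314571350958353),
  list(a = 0.7, b = 1.7, z = -20, val = 0.049130215085419801),
  list(a = 0.4, b = 1.0, z = -50, val = 0.013341638451394955))
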