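# independent numerical oracles, deliberately not sharing code with the
# implementation under test

# transit time across [x1, x2] under v(x) = v1 + A (x - x1), by RK4
# integration of the trajectory plus bisection on the crossing time
rk4_transit <- function(xp, x1, x2, v1, v2, n_steps = 4000) {
  A <- (v2 - v1) / (x2 - x1)
  v_at <- function(x) v1 + A * (x - x1)
  pos_at <- function(t) {
    h <- t / n_steps
    x <- xp
    for (i in seq_len(n_steps)) {
      k1 <- v_at(x)
      k2 <- v_at(x + h / 2 * k1)
      k3 <- v_at(x + h / 2 * k2)
      k4 <- v_at(x + h * k3)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    x
  }
  target <- if (v_at(xp) > 0) x2 else x1
  # bracket the crossing by doubling
  t_hi <- (x2 - x1) / max(abs(v1), abs(v2))
  for (i in 1:60) {
    reached <- if (target == x2) pos_at(t_hi) >= target else
      pos_at(t_hi) <= target
    if (reached) break
    t_hi <- t_hi * 2
  }
  f <- function(t) pos_at(t) - target
  stats::uniroot(f, c(0, t_hi), tol = 1e-10)$root
}
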