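# shared fixtures and independent oracles

# clean logistic time course
make_logistic_tc <- function(N0 = 2000, g = 0.025, theta = 50000,
                             times = seq(0, 500, 4), replicate_id = "r1",
                             condition = list()) {
  time_course(times, logistic_closed_form(N0, g, theta, times),
              replicate_id = replicate_id, condition = condition)
}

# default single-dose world used across fitting tests
default_world <- function(C = 75) {
  list(params = true_params_at(C),
       schedule = treatment_schedule(48, C),
       horizon = 504, cadence = 3)
}

as_named_truth <- function(p) {
  c(g0 = p$g0, gs = p$gs, gd = p$gd, kd = p$kd,
    fs1 = p$fs[1], gamma_d1 = p$gamma_d[1],
    N0 = p$N0, theta_dox = p$theta_dox)
}

# independent fixed-step classic RK4 integrator for the logistic ODE
rk4_logistic <- function(N0, g, theta, t_end, n_steps = 20000) {
  f <- function(N) g * N * (1 - N / theta)
  h <- t_end / n_steps
  N <- N0
  for (i in seq_len(n_steps)) {
    k1 <- f(N); k2 <- f(N + h / 2 * k1)
    k3 <- f(N + h / 2 * k2); k4 <- f(N + h * k3)
    N <- N + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  N
}

# brute-force metric oracles, written straight from the definitions
bf_nrmse <- function(obs, pred)
  100 * sqrt(sum((pred - obs)^2) / length(obs)) / (sum(obs) / length(obs))
bf_ccc <- function(obs, pred) {
  n <- length(obs)
  mo <- sum(obs) / n; mp <- sum(pred) / n
  so <- sum((obs - mo)^2) / n; sp <- sum((pred - mp)^2) / n
  sop <- sum((obs - mo) * (pred - mp)) / n
  2 * sop / (so + sp + (mo - mp)^2)
}
bf_r2 <- function(obs, pred)
  1 - sum((obs - pred)^2) / sum((obs - sum(obs) / length(obs))^2)
bf_pcc <- function(obs, pred) {
  n <- length(obs)
  mo <- sum(obs) / n; mp <- sum(pred) / n
  sum((obs - mo) * (pred - mp)) /
    sqrt(sum((obs - mo)^2) * sum((pred - mp)^2))
}

# exact two-sided rank-sum p by enumeration of all rank assignments
enum_ranksum_p <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  U_all <- apply(combos, 2, function(idx) sum(r[idx])) - m * (m + 1) / 2
  p_lo <- mean(U_all <= U_obs)
  p_hi <- mean(U_all >= U_obs)
  min(1, 2 * min(p_lo, p_hi))
}
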