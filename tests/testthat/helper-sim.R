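# Shared helpers: small configurations and synthetic data used across the
# unit tests. All fixtures are built in code.

tiny_config <- function(L = 100, n_walkers = 2, t_burn = 20, t_sample = 100,
                        seed = 11, dt = 0.05, tau = 1, tau_t = 0,
                        response = "linear") {
  sim_config(v = 10, tau = tau, dt = dt, p_r = 0.5, L = L, tau_t = tau_t,
             response = response, n_walkers = n_walkers, t_burn = t_burn,
             t_sample = t_sample, seed = seed)
}

std_field <- function(L = 100) conc_field(5, 45 / L)

# positions drawn from the linear density P(x) = (1 + s (x - L/2)) / L
draw_linear_positions <- function(n, L, s, seed) {
  set.seed(seed)
  u <- runif(n)
  a <- s / 2
  if (abs(a) < 1e-12) return(u * L)
  (-(1 - a * L) + sqrt((1 - a * L)^2 + 4 * a * L * u)) / (2 * a)
}

# synthetic run table with planted drift v_d = bias * v
draw_runs <- function(n, tau = 1, v = 10, bias = 0, L = 200, seed = 1) {
  set.seed(seed)
  dur <- rexp(n, 1 / tau)
  dirs <- ifelse(runif(n) < (1 + bias) / 2, 1, -1)
  data.frame(walker = rep_len(1:8, n),
             t_start = cumsum(dur) - dur,
             x_start = runif(n, 0, L),
             duration_s = dur,
             displacement_um = dirs * v * dur)
}
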