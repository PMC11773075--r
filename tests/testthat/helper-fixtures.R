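# Shared fixtures: benchmark parameter sets and synthetic series builders.

benchmarks <- oman_benchmarks()
rk <- benchmarks$R_kanagurta   # Indian mackerel
ta <- benchmarks$T_albacares   # yellowfin tuna
sc_fish <- benchmarks$S_commerson  # kingfish
sl <- benchmarks$S_longiceps   # Indian oil sardine

# Noise-free synthetic series for a benchmark stock under a contrast-rich
# one-way-trip effort history.
noise_free_series <- function(bench, n_years = 31, seed = 11) {
  e_msy <- bench$bio$r / (2 * bench$bio$q)
  path <- make_effort_path(n_years, "one_way_trip", e_start = 0.15 * e_msy,
                           e_end = 1.5 * e_msy, seed = seed)
  cfg <- simulation_config(bench$bio, initial_depletion = bench$ip,
                           obs_sigma = 0, seed = seed)
  list(series = simulate_fishery(cfg, path), config = cfg, path = path)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
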