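# shared fixtures; expensive scans are computed once per test run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

two_state_w_scan <- function() cached("two_state_w", suppressWarnings(
  critical_peaks(two_state_problem(2), abscissa = "w", n_grid = 400)))

berger_w_scan <- function() cached("berger_w", suppressWarnings(
  critical_peaks(berger_problem(1 / 13), abscissa = "w",
                 w_min = 0.018, w_max = 0.951, n_grid = 400)))

# golden critical values
w_star_two_state <- (sqrt(5) - 1) / 2
w_star_berger <- (6 - sqrt(23)) / 13

# small deterministic problem set for property tests
random_problem_set <- function() cached("prob_set", {
  specs <- expand.grid(n = c(2, 3, 5), seed = c(101, 202))
  lapply(seq_len(nrow(specs)), function(i)
    random_rd_problem(specs$n[i], seed = specs$seed[i]))
})
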