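# shared fixtures, computed lazily and cached for the whole test run
.cache <- new.env()

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

test_params <- function() cached("params", default_params())
test_alloc <- function() cached("alloc", batch_allocation())

# chemostat steady state at D = 0.1 with the default calibration
test_ss01 <- function() {
  cached("ss01", find_steady_state(test_alloc(), 0.1, test_params()))
}

# a reproducible random state generator within physiological ranges
random_state <- function() {
  default_state(Glc_ex = runif(1, 0, 60), G6P = runif(1, 0, 10),
                FBP = runif(1, 0, 10), PYR = runif(1, 0, 10),
                ATP = runif(1, 0.1, 5), ADP = runif(1, 0.05, 2),
                AMP = runif(1, 0.001, 1), NAD = runif(1, 0.1, 3),
                NADH = runif(1, 0.01, 1), Pi = runif(1, 0.5, 30),
                Tre = runif(1, 0, 40), EtOH = runif(1, 0, 40),
                Glyc = runif(1, 0, 10), X = runif(1, 0.01, 0.3))
}
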