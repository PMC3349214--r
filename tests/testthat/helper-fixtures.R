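# Small phantom fixtures shared across test files. Built once per test run
# and cached in this environment; all deterministic.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

tiny_ct_spec <- function(seed = 11) {
  phantom_spec("ct", dims = c(48, 48, 14), seed = seed)
}

tiny_pet_spec <- function(seed = 12) {
  phantom_spec("pet", dims = c(48, 48, 14), seed = seed)
}

tiny_ct <- function() fixture("tiny_ct", function() make_ct_phantom(tiny_ct_spec()))
tiny_pet <- function() fixture("tiny_pet", function() make_pet_phantom(tiny_pet_spec()))

# mid-size pair used by profile/artifact tests: big enough for clear MI
# structure, small enough to keep profiles fast
mid_ct <- function() fixture("mid_ct", function() {
  make_ct_phantom(phantom_spec("ct", dims = c(96, 96, 24), seed = 21))
})
mid_pet <- function() fixture("mid_pet", function() {
  make_pet_phantom(phantom_spec("pet", dims = c(96, 96, 24), seed = 22))
})

# count of strict interior local maxima of a profile, the artifact measure
n_local_maxima <- function(y) {
  n <- length(y)
  sum(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n])
}
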