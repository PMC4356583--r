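# Shared fixtures, built once per test run and cached. Everything is
# generated in code at fixed seeds; no data files are read.

.fx <- new.env(parent = emptyenv())

fx_cached <- function(key, builder) {
  if (!exists(key, envir = .fx, inherits = FALSE)) {
    assign(key, builder(), envir = .fx)
  }
  get(key, envir = .fx, inherits = FALSE)
}

# Proportional-hazards cohort: one planted binary effect (HR 2 on vad),
# everything else null.
fx_ph_config <- function(n, seed = 11, log_hr = log(2)) {
  generator_config(
    n = n,
    true_log_hr = list(vad = log_hr),
    time_varying = list(),
    seed = seed
  )
}

fx_ph_cohort <- function() {
  fx_cached("ph_cohort", function() generate_cohort(fx_ph_config(3000))$cohort)
}

# A small trained ensemble (2 members, complete data) shared by the model,
# hazard and serialization tests.
fx_small_model <- function() {
  fx_cached("small_model", function() {
    co <- fx_ph_cohort()
    train_ensemble(list(co, co),
      variables = c("vad", "recipient_age", "creatinine", "icu"),
      K = 5, hidden = 3, decay = 1e-4,
      control = rprop_control(epochs = 250), seed = 21
    )
  })
}

# Brute-force O(n^2) oracles used to pin the pair-counting metrics.
brute_harrell_c <- function(scores, times, events) {
  n <- length(scores)
  conc <- tied <- comp <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (times[i] == times[j]) next
      shorter <- if (times[i] < times[j]) i else j
      longer <- if (times[i] < times[j]) j else i
      if (events[shorter] != 1) next
      comp <- comp + 1
      if (scores[longer] > scores[shorter]) {
        conc <- conc + 1
      } else if (scores[longer] == scores[shorter]) {
        tied <- tied + 1
      }
    }
  }
  (conc + 0.5 * tied) / comp
}

brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) {
    for (b in neg) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(pos) * length(neg))
}

# Minimal hand-rolled cohort for design / targets checks.
fx_tiny_cohort <- function(n = 8, seed = 5) {
  generate_cohort(generator_config(n = n, seed = seed))$cohort
}
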