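# Brute-force equilibrium oracle: enumerate the promoter states explicitly
# (weight, initiation rate) and average initiation over the normalized
# weights. Deliberately independent of the package's closed-form rate
# expressions.

oracle_states <- function(mechanism, P, F, alpha = 1, beta = 1, tsat) {
  switch(mechanism,
    minus = list(w = c(1, P), r = c(0, tsat)),
    repression = list(w = c(1, F, P), r = c(0, 0, tsat)),
    stabilization = list(w = c(1, F, P, alpha * F * P),
                         r = c(0, 0, tsat, tsat)),
    acceleration = list(w = c(1, F, P, alpha * F * P),
                        r = c(0, 0, tsat, beta * tsat)))
}

oracle_rate <- function(mechanism, P, F = 0, alpha = 1, beta = 1,
                        tsat, tbg) {
  vapply(P, function(p) {
    s <- oracle_states(mechanism, p, F, alpha, beta, tsat)
    sum(s$w * s$r) / sum(s$w) + tbg
  }, 0)
}

# relative error helper
rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# standard noiseless fixture parameters (the repression demonstration's
# fitted values; also used as generator defaults)
TSAT <- 15.1
TBG <- 0.0023
F_CRP <- 23.9
ALPHA_I <- 712
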