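# shared fixtures: the two all-exponential study models (group rates from
# the 90-day readmission setting) and small builders

scen1_rates1 <- c(0.001, 0.0011, 0.0004)
scen1_rates2 <- c(0.0008, 0.0017, 0.0009)

exp_model <- function(rates, tau = 90) {
  crm_model(lapply(rates, crm_intensity, family = "exponential"), tau = tau)
}

scen1_m1 <- exp_model(scen1_rates1)
scen1_m2 <- exp_model(scen1_rates2)

two_group <- function(d1, d2) {
  rbind(data.frame(id = seq_len(nrow(d1)), time = d1$time,
                   status = d1$status, group = 1L),
        data.frame(id = nrow(d1) + seq_len(nrow(d2)), time = d2$time,
                   status = d2$status, group = 2L))
}

# brute-force sup-distance oracle on a dense grid (independent of the
# grid+refinement path under test)
brute_sup <- function(a, b, lo, hi, n = 1e6) {
  tt <- seq(lo, hi, length.out = n)
  max(abs(intensity(a, tt) - intensity(b, tt)))
}
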