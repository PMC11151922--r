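# Brute-force reference implementation of the variance partition, written
# independently of R/partition.R: explicit loops over every series and a
# from-scratch sample SD, no shared code. Used to pin down expected values
# for the worked examples and for randomized equivalence checks.

oracle_sample_sd <- function(v) {
  v <- unname(v)
  n <- length(v)
  m <- sum(v) / n
  acc <- 0
  for (i in seq_len(n)) acc <- acc + (v[i] - m)^2
  sqrt(acc / (n - 1))
}

oracle_partition <- function(x) {
  stopifnot(is.array(x), length(dim(x)) == 3)
  U <- dim(x)[1]; K <- dim(x)[2]; TT <- dim(x)[3]

  total <- numeric(TT)
  for (t in seq_len(TT)) {
    s <- 0
    for (u in seq_len(U)) for (k in seq_len(K)) s <- s + x[u, k, t]
    total[t] <- s
  }
  mu <- sum(total) / TT

  sum_sd_pop <- 0
  for (u in seq_len(U)) for (k in seq_len(K)) {
    sum_sd_pop <- sum_sd_pop + oracle_sample_sd(x[u, k, ])
  }
  sum_sd_patch <- 0
  for (k in seq_len(K)) {
    tot <- numeric(TT)
    for (t in seq_len(TT)) {
      s <- 0
      for (u in seq_len(U)) s <- s + x[u, k, t]
      tot[t] <- s
    }
    sum_sd_patch <- sum_sd_patch + oracle_sample_sd(tot)
  }
  sum_sd_unit <- 0
  for (u in seq_len(U)) {
    tot <- numeric(TT)
    for (t in seq_len(TT)) {
      s <- 0
      for (k in seq_len(K)) s <- s + x[u, k, t]
      tot[t] <- s
    }
    sum_sd_unit <- sum_sd_unit + oracle_sample_sd(tot)
  }

  cv_s_l <- sum_sd_pop / mu
  cv_c_l <- sum_sd_patch / mu
  cv_s_r <- sum_sd_unit / mu
  cv_c_r <- oracle_sample_sd(total) / mu
  safe_ratio <- function(a, b) if (b == 0) 1 else a / b
  list(cv_s_l = cv_s_l, cv_c_l = cv_c_l, cv_s_r = cv_s_r, cv_c_r = cv_c_r,
       phi_s2c_l = safe_ratio(cv_c_l, cv_s_l),
       phi_c_l2r = safe_ratio(cv_c_r, cv_c_l),
       phi_s_l2r = safe_ratio(cv_s_r, cv_s_l),
       phi_s2c_r = safe_ratio(cv_c_r, cv_s_r))
}
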