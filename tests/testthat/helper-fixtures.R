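# In-code fixtures shared across test files.

# A positive random tensor of modest size, wrapped in the package's class.
random_tensor <- function(n_units = sample(1:4, 1), n_patches = sample(1:3, 1),
                          n_times = sample(2:6, 1), variable = "flower_availability") {
  vals <- array(runif(n_units * n_patches * n_times, 0.1, 10),
                dim = c(n_units, n_patches, n_times),
                dimnames = list(unit = paste0("u", seq_len(n_units)),
                                patch = paste0("k", seq_len(n_patches)),
                                time = paste0("t", seq_len(n_times))))
  pollistab:::new_metacommunity_tensor(vals, variable)
}

make_tensor <- function(vals, variable = "flower_availability") {
  d <- dim(vals)
  dimnames(vals) <- list(unit = paste0("u", seq_len(d[1])),
                         patch = paste0("k", seq_len(d[2])),
                         time = paste0("t", seq_len(d[3])))
  pollistab:::new_metacommunity_tensor(vals, variable)
}

# The 2 units x 2 patches x 3 times worked micro-example.
micro_tensor <- function() {
  vals <- array(0, c(2, 2, 3))
  vals[1, 1, ] <- c(1, 2, 3)
  vals[1, 2, ] <- c(2, 2, 2)
  vals[2, 1, ] <- c(3, 1, 2)
  vals[2, 2, ] <- c(1, 3, 2)
  make_tensor(vals)
}

flowers_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(year = r[[1]], round = r[[2]], site = r[[3]], subplot = r[[4]],
               plant = r[[5]], count = r[[6]])
  }))
}
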