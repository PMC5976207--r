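# shared fixtures: maps and hand-built tetrad datasets

two_map <- function(len = 10) marker_map(c("A", "B"), c("C", "Y"), c(0, len))

three_map <- function(l1 = 10, l2 = 10)
  marker_map(c("A", "B", "C"), c("C", "Y", "R"), c(0, l1, l1 + l2))

# build a tetrad_data frame from a list of 4-grain character vectors
tetrads_from_grains <- function(grain_list, map,
                                genotype = "WT", temperature = "20C") {
  gm <- do.call(rbind, grain_list)
  out <- data.frame(tetrad = seq_len(nrow(gm)), genotype = genotype,
                    temperature = temperature,
                    grain1 = gm[, 1], grain2 = gm[, 2],
                    grain3 = gm[, 3], grain4 = gm[, 4],
                    stringsAsFactors = FALSE)
  class(out) <- c("tetrad_data", "data.frame")
  attr(out, "marker_map") <- map
  out
}

# brute-force Perkins oracle: accumulate the per-tetrad score explicitly
perkins_oracle <- function(PD, T, NPD) {
  s <- rep(c(0, 0.5, 3), times = c(PD, T, NPD))
  n <- length(s)
  list(X = 100 * mean(s),
       SE = 100 * sqrt(mean((s - mean(s))^2) / n))
}
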