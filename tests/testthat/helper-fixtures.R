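# Independent oracles and fixture builders shared across tests.

# brute-force Theil-Sen: exhaustive double-loop enumeration of pairwise slopes
brute_theil_sen <- function(x, y) {
  slopes <- c()
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (x[j] != x[i]) slopes <- c(slopes, (y[j] - y[i]) / (x[j] - x[i]))
    }
  }
  slope <- median(slopes)
  list(slope = slope, intercept = median(y - slope * x))
}

# independent percentile: linear interpolation between order statistics
brute_percentile <- function(v, p) {
  v <- sort(v)
  h <- (length(v) - 1) * p
  lo <- floor(h)
  if (lo + 1 >= length(v)) return(v[length(v)])
  v[lo + 1] + (h - lo) * (v[lo + 2] - v[lo + 1])
}

# ground-truth elbow warp: y = x below 50, y = 2x - 50 above
elbow_fn <- function(x) ifelse(x < 50, x, 2 * x - 50)

# replicate observations for calibration-set construction: each precursor
# observed in each of 3 runs at rt_mean + c(-d, 0, d), so its sample SD is d
make_replicates <- function(ids, rt_means, sds, runs = c("r1", "r2", "r3"),
                            modseq = ids) {
  offsets <- c(-1, 0, 1)
  do.call(rbind, lapply(seq_along(runs), function(k) {
    data.frame(run_id = runs[k], precursor_id = ids,
               modified_sequence = modseq,
               rt_apex = rt_means + offsets[k] * sds,
               stringsAsFactors = FALSE)
  }))
}

kit_table <- function() {
  data.frame(sequence = c("KIT_B", "KIT_L"), irt = c(0, 100),
             stringsAsFactors = FALSE)
}

# fragment rows guaranteed to pass the library filters
passing_fragments <- function(pid, n = 4, run_id = NULL) {
  out <- data.frame(precursor_id = pid,
                    series = rep(c("y", "b"), length.out = n),
                    ordinal = 3:(2 + n),
                    fragment_charge = 1L,
                    mz = seq(400, 800, length.out = n),
                    intensity = seq(1000, 400, length.out = n),
                    stringsAsFactors = FALSE)
  if (!is.null(run_id)) out$run_id <- run_id
  out
}
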