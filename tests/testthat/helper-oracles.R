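# Independent, naive transcriptions of the feature definitions. These share
# no code with the package implementation: every statistic is written out
# directly from its defining formula and computed channel by channel.

oracle_corr <- function(rec, nbhd, i) {
  nb <- nbhd$neighbors[[i]]
  vals <- numeric(0)
  for (j in nb) {
    x <- rec$signals[i, ]; y <- rec$signals[j, ]
    if (sd(x) == 0 || sd(y) == 0) next
    vals <- c(vals, sum((x - mean(x)) * (y - mean(y))) /
                ((length(x) - 1) * sd(x) * sd(y)))
  }
  if (!length(vals)) return(0)
  sum(vals) / length(vals)
}

oracle_varn <- function(rec, nbhd, i) {
  nb <- nbhd$neighbors[[i]]
  v <- function(x) sum((x - mean(x))^2) / (length(x) - 1)
  num <- v(rec$signals[i, ])
  if (!length(nb)) return(if (num <= 0) 0 else 1e6)
  den <- median(sapply(nb, function(j) v(rec$signals[j, ])))
  if (den <= 0) return(if (num <= 0) 0 else 1e6)
  num / den
}

oracle_devn <- function(rec, nbhd, i) {
  nb <- nbhd$neighbors[[i]]
  if (!length(nb)) return(0)
  mean(rec$signals[i, ]) - mean(sapply(nb, function(j) mean(rec$signals[j, ])))
}

oracle_ampl <- function(rec, nbhd, i) {
  nb <- nbhd$neighbors[[i]]
  num <- max(rec$signals[i, ]) - min(rec$signals[i, ])
  if (!length(nb)) return(if (num <= 0) 0 else 1e6)
  den <- median(sapply(nb, function(j) max(rec$signals[j, ]) - min(rec$signals[j, ])))
  if (den <= 0) return(if (num <= 0) 0 else 1e6)
  num / den
}

oracle_grad <- function(rec, nbhd, i) {
  g <- function(x) {
    d <- abs(x[-1] - x[-length(x)])
    sum(d) / length(d)
  }
  nb <- nbhd$neighbors[[i]]
  num <- g(rec$signals[i, ])
  if (!length(nb)) return(if (num <= 0) 0 else 1e6)
  den <- median(sapply(nb, function(j) g(rec$signals[j, ])))
  if (den <= 0) return(if (num <= 0) 0 else 1e6)
  num / den
}

oracle_kurt <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m4 <- sum((x - mu)^4) / n
  if (m2 == 0) return(0)
  m4 / m2^2
}

oracle_hurst <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  y <- x - mu
  z <- numeric(n)
  acc <- 0
  for (t in seq_len(n)) {
    acc <- acc + y[t]
    z[t] <- acc
  }
  rn <- max(z) - min(z)
  sn <- sqrt(sum((x - mu)^2) / n)
  if (sn == 0 || rn == 0) return(0)
  log(rn / sn) / log(n / 2)
}
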