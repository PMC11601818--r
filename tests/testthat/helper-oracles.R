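# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately share no code with R/.

# explicit triple-loop weighted-mean GMD
loopGMD <- function(gmArr, wArr) {
  d <- dim(gmArr)
  num <- 0; den <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    num <- num + gmArr[i, j, k] * wArr[i, j, k]
    den <- den + wArr[i, j, k]
  }
  num / den
}

# hand O-E/V log-rank tabulation over distinct event times (1 df)
logrankOE <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  OE <- 0; V <- 0
  for (t in sort(unique(time[event]))) {
    atRisk <- time >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & group == g1)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & group == g1)
    OE <- OE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- OE^2 / V
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# grid-search maximization of the (untied) Cox partial likelihood
coxGridSearch <- function(time, event, x, grid = seq(-6, 6, by = 1e-4)) {
  logpl <- vapply(grid, function(beta) {
    ll <- 0
    for (t in time[event]) {
      i <- which(event & time == t)
      risk <- which(time >= t)
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    ll
  }, numeric(1))
  grid[which.max(logpl)]
}

# Kruskal-Wallis H from the rank formula, with tie correction
kwOracle <- function(groups) {
  pooled <- unlist(groups)
  r <- rank(pooled)
  N <- length(pooled)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, idx, sum)^2 / lengths(groups)) - 3 * (N + 1)
  ties <- table(pooled)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# exact permutation p-value of the KW statistic for two groups
kwExactP <- function(x1, x2) {
  pooled <- c(x1, x2)
  n1 <- length(x1)
  Hobs <- kwOracle(list(x1, x2))
  combs <- utils::combn(length(pooled), n1)
  Hs <- apply(combs, 2, function(i)
    kwOracle(list(pooled[i], pooled[-i])))
  mean(Hs >= Hobs - 1e-12)
}

# exact label probabilities by enumerating the 16 exceedance-flag
# combinations, each axis exceeding independently with probability p
enumSubtypeProbs <- function(p = 0.25) {
  pr <- c(mild = 0, intermediate = 0, malignant = 0)
  for (motor in 0:1) for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    nm <- a + b + cc
    w <- prod(ifelse(c(motor, a, b, cc) == 1, p, 1 - p))
    lab <- if ((motor == 1 && nm >= 1) || nm == 3) "malignant"
           else if (motor == 0 && nm == 0) "mild" else "intermediate"
    pr[lab] <- pr[lab] + w
  }
  pr
}

# product-limit survival by hand
kmOracle <- function(time, event) {
  s <- 1
  out <- NULL
  for (t in sort(unique(time[event]))) {
    n <- sum(time >= t)
    d <- sum(event & time == t)
    s <- s * (1 - d / n)
    out <- rbind(out, c(time = t, surv = s))
  }
  as.data.frame(out)
}

# small valid visit table for one subject
toyVisits <- function(months, moca = 25, i11 = 0, i12 = 0, i15 = 0,
                      dem = FALSE, demc = FALSE) {
  n <- length(months)
  rec <- function(x) rep(x, length.out = n)
  data.frame(visit_month = months, moca = rec(moca),
             updrs_1_1 = rec(i11), updrs_1_2 = rec(i12),
             updrs_1_5 = rec(i15), dementia_clinical = rec(dem),
             dementia_composite = rec(demc))
}
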