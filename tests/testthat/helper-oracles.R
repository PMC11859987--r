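# Independent brute-force oracles for the transfer-entropy functionals.
# Deliberately naive: transition tuples are enumerated as strings and
# probabilities computed with table()/mean(), sharing no code with the
# package's integer-encoded array path.

oracle_tuples <- function(x, y, m = 1, n = 1) {
  k <- max(m, n)
  stopifnot(length(x) == length(y))
  t_idx <- (k + 1):length(y)
  tibble::tibble(
    yn = y[t_idx],
    yh = vapply(t_idx, function(t) paste(y[(t - 1):(t - n)], collapse = ","), ""),
    xh = vapply(t_idx, function(t) paste(x[(t - 1):(t - m)], collapse = ","), "")
  )
}

# Direct evaluation of the STE triple sum:
# sum p(y+, yh, xh) log2[ p(y+|yh,xh) / p(y+|yh) ]
oracle_ste <- function(x, y, m = 1, n = 1) {
  tup <- oracle_tuples(x, y, m, n)
  big <- nrow(tup)
  total <- 0
  combos <- unique(tup)
  for (i in seq_len(nrow(combos))) {
    yn_i <- combos$yn[i]
    yh_i <- combos$yh[i]
    xh_i <- combos$xh[i]
    p3 <- mean(tup$yn == yn_i & tup$yh == yh_i & tup$xh == xh_i)
    p_cond_full <- sum(tup$yn == yn_i & tup$yh == yh_i & tup$xh == xh_i) /
      sum(tup$yh == yh_i & tup$xh == xh_i)
    p_cond_y <- sum(tup$yn == yn_i & tup$yh == yh_i) / sum(tup$yh == yh_i)
    total <- total + p3 * log2(p_cond_full / p_cond_y)
  }
  total
}

# Direct evaluation of the escort-weighted Renyi TE:
# 1/(1-q) log2[ sum_yh phi_q(yh) sum_y+ p^q(y+|yh) /
#               sum_(yh,xh) phi_q(yh,xh) sum_y+ p^q(y+|yh,xh) ]
oracle_rte <- function(x, y, q, m = 1, n = 1) {
  tup <- oracle_tuples(x, y, m, n)
  big <- nrow(tup)
  yh_tab <- table(tup$yh) / big
  phi_y <- yh_tab^q / sum(yh_tab^q)
  num <- 0
  for (ctx in names(yh_tab)) {
    sub <- tup$yn[tup$yh == ctx]
    cond <- table(sub) / length(sub)
    num <- num + phi_y[[ctx]] * sum(cond^q)
  }
  joint_key <- paste(tup$yh, tup$xh, sep = "|")
  jx_tab <- table(joint_key) / big
  phi_jx <- jx_tab^q / sum(jx_tab^q)
  den <- 0
  for (ctx in names(jx_tab)) {
    sub <- tup$yn[joint_key == ctx]
    cond <- table(sub) / length(sub)
    den <- den + phi_jx[[ctx]] * sum(cond^q)
  }
  log2(num / den) / (1 - q)
}

# Conditional-entropy decomposition H(Y+|Yh) - H(Y+|Yh,Xh) from the tuples.
oracle_ste_decomposition <- function(x, y, m = 1, n = 1) {
  tup <- oracle_tuples(x, y, m, n)
  cond_entropy <- function(outcome, context) {
    total <- 0
    for (ctx in unique(context)) {
      sub <- outcome[context == ctx]
      p_ctx <- length(sub) / length(outcome)
      p <- table(sub) / length(sub)
      total <- total + p_ctx * (-sum(p * log2(p)))
    }
    total
  }
  cond_entropy(tup$yn, tup$yh) -
    cond_entropy(tup$yn, paste(tup$yh, tup$xh, sep = "|"))
}
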