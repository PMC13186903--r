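# independent Mann-Whitney oracle: U by pair counting (not rank sums),
# null distribution by explicit enumeration of group assignments
oracle_mwu_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  mu <- n1 * length(y) / 2
  u_obs <- u_of(x, y)
  splits <- utils::combn(length(pool), n1)
  u_all <- apply(splits, 2, function(idx) u_of(pool[idx], pool[-idx]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# independent Fisher oracle: explicit hypergeometric enumeration via choose()
oracle_fisher_p <- function(tab) {
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - m2):min(k, m1)
  prob <- choose(m1, support) * choose(m2, k - support) / choose(m1 + m2, k)
  p_obs <- prob[support == tab[1, 1]]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}
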